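# Literal brute-force enumeration of the scoring definition, kept
# deliberately naive (explicit loops, no shared code with the package
# internals) so it can serve as an independent oracle.

oracle_score <- function(tab, cfg) {
  baits <- setdiff(tab$sample_order, tab$control)
  rows <- vector("list", length(tab$accession))
  for (i in seq_along(tab$accession)) {
    ctrl <- as.numeric(tab$counts[i, tab$samples == tab$control])
    excluded <- FALSE
    for (v in ctrl) {
      if (v > cfg$control_exclusion_threshold) excluded <- TRUE
    }
    agg <- 0
    if (cfg$denominator_policy == "mean") agg <- sum(ctrl) / length(ctrl)
    if (cfg$denominator_policy == "sum") agg <- sum(ctrl)
    if (cfg$denominator_policy == "max") agg <- max(ctrl)
    if (agg == 0) agg <- cfg$zero_substitute
    s <- 0
    for (b in baits) {
      for (v in tab$counts[i, tab$samples == b]) s <- s + v / agg
    }
    rows[[i]] <- data.frame(accession = tab$accession[i],
                            denom = agg, S = s, excluded = excluded,
                            selected = !excluded && s > cfg$candidate_threshold,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

oracle_candidates <- function(tab, cfg) {
  sc <- oracle_score(tab, cfg)
  sel <- sc[sc$selected, , drop = FALSE]
  sel$accession[order(-sel$S, sel$accession)]
}
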