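# Random valid inputs for property-style tests. Callers set the RNG seed.

random_spectral_counts <- function(max_proteins = 8, max_reps = 3,
                                   max_count = 5, n_baits = NULL) {
  n <- sample.int(max_proteins, 1)
  if (is.null(n_baits)) n_baits <- sample(1:2, 1)
  baits <- paste0("bait", seq_len(n_baits))
  reps <- sample.int(max_reps, n_baits + 1, replace = TRUE)
  cols <- c(
    unlist(lapply(seq_len(n_baits), function(b)
      paste0(baits[b], "_rep", seq_len(reps[b])))),
    paste0("ctrl_rep", seq_len(reps[n_baits + 1]))
  )
  counts <- matrix(sample(0:max_count, n * length(cols), replace = TRUE),
                   nrow = n, dimnames = list(NULL, cols))
  acc <- sprintf("P%03d", sample.int(999, n))
  spectral_counts(acc, paste0("G", seq_len(n)), counts, control = "ctrl")
}

random_cq_table <- function() {
  transcripts <- c("target", "ref")
  grid <- expand.grid(sample = c("input", "elution"),
                      transcript = transcripts,
                      tech_rep = 1:3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cq_table(grid$sample, grid$transcript,
           is_reference = grid$transcript == "ref",
           tech_rep = grid$tech_rep,
           cq = round(runif(nrow(grid), 10, 35), 3))
}

random_fraction_table <- function(max_fractions = 12) {
  n <- sample(2:max_fractions, 1)
  transcripts <- paste0("t", seq_len(sample(1:3, 1)))
  do.call(rbind, lapply(transcripts, function(tr) {
    data.frame(fraction = seq_len(n), transcript = tr,
               quantity = round(runif(n, 0, 10), 4),
               stringsAsFactors = FALSE)
  })) -> df
  fraction_table(df$fraction, df$transcript, df$quantity)
}

random_enrichment_config <- function() {
  enrichment_config(
    control_exclusion_threshold = sample(c(0, 1, 2, 3, 11), 1),
    zero_substitute = sample(c(0.5, 0.9, 1), 1),
    candidate_threshold = sample(c(0, 1, 1.5, 3, 9), 1),
    highlight_threshold = sample(c(1, 2, 10), 1),
    denominator_policy = sample(c("mean", "sum", "max"), 1)
  )
}
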