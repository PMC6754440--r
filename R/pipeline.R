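#' @importFrom jsonlite write_json read_json
NULL

config_echo <- function(config) {
  unclass(config)
}

json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the enrichment stage and write result files
#'
#' Reads (or takes) a spectral-count table, scores every protein, and writes
#' `enrichment_results.tsv` (all proteins, rank order, scores to one
#' decimal), `candidates.tsv` (selected proteins only) and
#' `enrichment_summary.json` (counts, config echo and full-precision
#' candidate scores) into `out_dir`.
#'
#' @param input A [spectral_counts()] table or a path to a spectral-count TSV.
#' @param control Control sample name (required when `input` is a path).
#' @param config An [enrichment_config()].
#' @param out_dir Output directory (created if absent).
#' @param fill_missing Passed to [read_spectral_counts()].
#' @return Invisibly, a list with `results` (the `enrichment_result`),
#'   `summary` and `files`.
#' @export
run_enrichment <- function(input, control = NULL,
                           config = enrichment_config(),
                           out_dir = ".", fill_missing = FALSE) {
  tab <- if (inherits(input, "spectral_counts")) input else {
    if (is.null(control)) stop("`control` is required when reading from a file")
    read_spectral_counts(input, control = control, fill_missing = fill_missing)
  }
  res <- score_table(tab, config)
  cand <- select_candidates(res)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ord <- order(is.na(res$rank), res$rank, res$accession)
  files <- c(
    results = file.path(out_dir, "enrichment_results.tsv"),
    candidates = file.path(out_dir, "candidates.tsv"),
    summary = file.path(out_dir, "enrichment_summary.json")
  )
  write_enrichment_results(res[ord, , drop = FALSE], files[["results"]])
  write_enrichment_results(cand, files[["candidates"]])

  s_cols <- grep("^S_", names(res), value = TRUE)
  summary <- list(
    n_proteins = nrow(res),
    n_excluded_by_control = sum(res$excluded),
    n_selected = sum(res$selected),
    n_highlighted_candidates = sum(res$selected & res$highlighted),
    config = config_echo(config),
    candidates = cand[, c("accession", "gene", s_cols, "S_combined",
                          "highlighted", "rank")]
  )
  json_out(summary, files[["summary"]])
  invisible(list(results = res, summary = summary, files = files))
}

#' Run the qPCR recovery stage
#'
#' Computes percent-of-input recovery for every non-reference transcript
#' present in both the input and elution samples and writes `recovery.tsv`.
#'
#' @param input A [cq_table()] or path to a Cq TSV.
#' @param reference Reference transcript (default: the flagged one).
#' @param out_dir Output directory.
#' @param input_sample,elution_sample Sample labels.
#' @return Invisibly, a list with `recovery` (data.frame) and `files`.
#' @export
run_qpcr <- function(input, reference = NULL, out_dir = ".",
                     input_sample = "input", elution_sample = "elution") {
  tab <- if (inherits(input, "cq_table")) input else read_cq_table(input)
  if (is.null(reference)) reference <- reference_transcript(tab)
  targets <- setdiff(unique(tab$transcript), reference)
  if (length(targets) == 0) stop("no non-reference transcripts in Cq table")
  recovery <- do.call(rbind, lapply(targets, function(tr)
    percent_of_input(tab, tr, reference, input_sample, elution_sample)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(recovery = file.path(out_dir, "recovery.tsv"))
  write_tsv_(as.data.frame(recovery), files[["recovery"]])
  invisible(list(recovery = recovery, files = files))
}

#' Run the polysome distribution stage
#'
#' Computes the per-fraction percent distribution for every transcript and
#' writes `fraction_percents.tsv` (fraction-level) and `pool_shares.tsv`
#' (per transcript and pool).
#'
#' @param input A [fraction_table()] or path to a fraction TSV.
#' @param pools Named list of fraction-index pools.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `profiles`, `shares` and `files`.
#' @export
run_polysome <- function(input, pools = default_pools(), out_dir = ".") {
  tab <- if (inherits(input, "fraction_table")) input else read_fraction_table(input)
  transcripts <- unique(tab$transcript)
  profiles <- lapply(transcripts, function(tr) fraction_percents(tab, tr, pools))
  names(profiles) <- transcripts
  long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(transcript = p$transcript,
               fraction = seq_along(p$percent),
               quantity = p$quantity, percent = p$percent,
               pool = pool_of(seq_along(p$percent), p$pools),
               stringsAsFactors = FALSE)))
  shares <- do.call(rbind, lapply(profiles, function(p)
    data.frame(transcript = p$transcript,
               pool = names(p$pools),
               share_percent = vapply(names(p$pools), pool_share,
                                      numeric(1), profile = p),
               stringsAsFactors = FALSE)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(percents = file.path(out_dir, "fraction_percents.tsv"),
             shares = file.path(out_dir, "pool_shares.tsv"))
  write_tsv_(long, files[["percents"]])
  write_tsv_(shares, files[["shares"]])
  invisible(list(profiles = profiles, shares = shares, files = files))
}

pool_of <- function(fractions, pools) {
  out <- rep("", length(fractions))
  for (nm in names(pools)) out[fractions %in% pools[[nm]]] <- nm
  out
}

#' Simulate all three input tables with planted truth
#'
#' Writes `spectral_counts.tsv`, `cq.tsv`, `fractions.tsv` and `truth.json`
#' into `out_dir`. The Cq table plants the target-mRNA recovery, and the
#' fraction table contains one profile per planted transcript.
#'
#' @param seed Integer seed governing all three simulations.
#' @param out_dir Output directory.
#' @param params A [sim_params()] for the spectral counts.
#' @param recovery Planted percent-of-input recovery for the bait capture.
#' @param cq_noise_sd Cq noise (cycles).
#' @param pool_weights Named list: per transcript, named pool-weight vector.
#' @param polysome_noise_sd Multiplicative noise SD for fraction quantities.
#' @return Invisibly, a list with the simulated objects and `files`.
#' @export
run_simulate <- function(seed, out_dir = ".", params = sim_params(),
                         recovery = 40, cq_noise_sd = 0.1,
                         pool_weights = list(
                           Tnp1 = c(inactive = 0.5, active = 0.5),
                           Tnp2 = c(inactive = 0.5, active = 0.5),
                           Actin = c(inactive = 0.1, active = 0.9)),
                         polysome_noise_sd = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_spectral_counts(params, seed = seed)
  cq <- simulate_cq(recovery, noise_sd = cq_noise_sd, seed = seed + 1,
                    transcript = params$baits[1], reference = params$control)
  frac <- do.call(rbind, lapply(seq_along(pool_weights), function(i)
    simulate_polysome(pool_weights[[i]], noise_sd = polysome_noise_sd,
                      seed = seed + 1 + i,
                      transcript = names(pool_weights)[i])))
  class(frac) <- c("fraction_table", "data.frame")

  files <- c(counts = file.path(out_dir, "spectral_counts.tsv"),
             cq = file.path(out_dir, "cq.tsv"),
             fractions = file.path(out_dir, "fractions.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_spectral_counts(sim$table, files[["counts"]])
  write_cq_table(cq, files[["cq"]])
  write_fraction_table(frac, files[["fractions"]])
  json_out(list(seed = seed,
                classes = as.list(stats::setNames(sim$truth$class,
                                                  sim$truth$accession)),
                planted_recovery = recovery,
                pool_weights = pool_weights),
           files[["truth"]])
  invisible(list(table = sim$table, truth = sim$truth, cq = cq,
                 fractions = frac, files = files))
}

#' Run every stage whose input is present
#'
#' Orchestrates the enrichment, qPCR and polysome stages over whichever
#' inputs the config provides and writes a single `manifest.json` linking
#' the outputs, the config echo and the package version.
#'
#' @param config A list with any of `spectral_counts` (+ `control`), `cq`,
#'   `fractions` (each an object or file path), plus optional `enrichment`
#'   (an [enrichment_config()]), `pools`, `fill_missing` and `out_dir`.
#' @return Invisibly, a list of stage outputs plus `manifest`.
#' @export
run_all <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  files <- list()
  if (!is.null(config$spectral_counts)) {
    stages$enrichment <- run_enrichment(
      config$spectral_counts, control = config$control,
      config = config$enrichment %||% enrichment_config(),
      out_dir = out_dir, fill_missing = isTRUE(config$fill_missing))
    files$enrichment <- as.list(stages$enrichment$files)
  }
  if (!is.null(config$cq)) {
    stages$qpcr <- run_qpcr(config$cq, reference = config$reference,
                            out_dir = out_dir)
    files$qpcr <- as.list(stages$qpcr$files)
  }
  if (!is.null(config$fractions)) {
    stages$polysome <- run_polysome(config$fractions,
                                    pools = config$pools %||% default_pools(),
                                    out_dir = out_dir)
    files$polysome <- as.list(stages$polysome$files)
  }
  if (length(stages) == 0) stop("no stage input present in config")
  manifest <- list(
    package = "rnacap",
    version = as.character(utils::packageVersion("rnacap")),
    stages = names(stages),
    config = list(
      control = config$control,
      enrichment = config_echo(config$enrichment %||% enrichment_config()),
      pools = config$pools %||% default_pools(),
      fill_missing = isTRUE(config$fill_missing),
      out_dir = out_dir
    ),
    files = files
  )
  json_out(manifest, file.path(out_dir, "manifest.json"))
  invisible(c(stages, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
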