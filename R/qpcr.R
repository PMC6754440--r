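#' Mean Cq over technical replicates
#'
#' Technical replicates are averaged on the Cq (cycle) scale, the standard
#' practice for replicate spreads well below one cycle.
#'
#' @param x A [cq_table()].
#' @param sample Sample-fraction label (e.g. `"input"`).
#' @param transcript Transcript name.
#' @return Arithmetic mean Cq (cycles).
#' @export
mean_cq <- function(x, sample, transcript) {
  validate_cq_table(x)
  rows <- x$sample == sample & x$transcript == transcript
  if (!any(rows)) {
    stop("no Cq rows for sample '", sample, "', transcript '", transcript, "'")
  }
  mean(x$cq[rows])
}

#' Percent-of-input mRNA recovery by the delta-delta-Cq method
#'
#' Capture efficiency of an mRNA isolation: the eluted amount of the target
#' transcript relative to the input extract, normalized to a reference
#' (housekeeping) transcript in both samples. With
#' `dCq = Cq(target) - Cq(reference)` per sample and
#' `ddCq = dCq(elution) - dCq(input)`, the recovery is `100 * 2^(-ddCq)`
#' percent, assuming perfect base-2 amplification.
#'
#' @param x A [cq_table()].
#' @param transcript Target transcript.
#' @param reference Reference transcript (defaults to the transcript flagged
#'   `is_reference` in the table, if unique).
#' @param input,elution Sample labels of the input and elution fractions.
#' @return A one-row `data.frame` of class `recovery_result` with columns
#'   `transcript`, `reference`, `dcq_input`, `dcq_elution`, `ddcq`,
#'   `percent_of_input`.
#' @export
percent_of_input <- function(x, transcript, reference = NULL,
                             input = "input", elution = "elution") {
  validate_cq_table(x)
  if (is.null(reference)) reference <- reference_transcript(x)
  dcq_in <- mean_cq(x, input, transcript) - mean_cq(x, input, reference)
  dcq_el <- mean_cq(x, elution, transcript) - mean_cq(x, elution, reference)
  ddcq <- dcq_el - dcq_in
  out <- data.frame(transcript = transcript, reference = reference,
                    dcq_input = dcq_in, dcq_elution = dcq_el, ddcq = ddcq,
                    percent_of_input = 100 * 2^(-ddcq),
                    stringsAsFactors = FALSE)
  class(out) <- c("recovery_result", "data.frame")
  out
}

reference_transcript <- function(x) {
  ref <- unique(x$transcript[x$is_reference])
  if (length(ref) != 1) {
    stop("reference transcript not unique in table; pass `reference` explicitly")
  }
  ref
}

#' Cross-transcript specificity of an mRNA isolation
#'
#' For each transcript, its reference-normalized abundance in the elution
#' relative to the selected (captured) transcript, via the delta-delta-Cq
#' method; the selected transcript maps to exactly 1. Values near zero for
#' off-target transcripts indicate a specific capture.
#'
#' @param x A [cq_table()].
#' @param selected_transcript The transcript targeted by the capture.
#' @param transcripts Transcripts to evaluate; defaults to all non-reference
#'   transcripts in the table.
#' @param reference,input,elution See [percent_of_input()].
#' @return A `data.frame` with columns `transcript` and `rel_abundance`.
#' @export
specificity_matrix <- function(x, selected_transcript, transcripts = NULL,
                               reference = NULL, input = "input",
                               elution = "elution") {
  validate_cq_table(x)
  if (is.null(reference)) reference <- reference_transcript(x)
  if (is.null(transcripts)) {
    transcripts <- setdiff(unique(x$transcript), reference)
  }
  if (!selected_transcript %in% transcripts) {
    stop("selected transcript '", selected_transcript,
         "' not among transcripts to evaluate")
  }
  poi <- vapply(transcripts, function(tr)
    percent_of_input(x, tr, reference, input, elution)$percent_of_input,
    numeric(1))
  data.frame(transcript = transcripts,
             rel_abundance = unname(poi / poi[transcripts == selected_transcript]),
             stringsAsFactors = FALSE)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of mean Cq against log10 relative template
#' input over a dilution series. The amplification efficiency is
#' `10^(-1/slope) - 1`; a slope of `-1/log10(2) = -3.32` corresponds to
#' perfect doubling per cycle (efficiency 1, i.e. 100%).
#'
#' @param log10_dilution Numeric vector of log10 relative input amounts.
#' @param cq Numeric vector of mean Cq values, same length.
#' @return An object of class `standard_curve`: list with `slope`
#'   (cycles per log10 unit), `intercept`, `r_squared`, `efficiency`
#'   (fraction) and the fitted `points`.
#' @export
fit_standard_curve <- function(log10_dilution, cq) {
  stopifnot(length(log10_dilution) == length(cq))
  if (length(cq) < 3) stop("need at least 3 dilution points")
  if (stats::var(log10_dilution) == 0) stop("zero variance in dilution levels")
  span <- diff(range(log10_dilution))
  if (span < 3) {
    warning("dilution series spans only ", format(span),
            " log10 units; standard practice is a 3-4 log dynamic range")
  }
  fit <- stats::lm(cq ~ log10_dilution)
  slope <- unname(stats::coef(fit)[2])
  # R^2 computed directly; summary.lm warns on exact (zero-residual) fits
  r_squared <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  if (slope >= 0) {
    warning("non-negative slope: not a valid amplification curve; ",
            "efficiency undefined")
  }
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r_squared,
         efficiency = if (slope < 0) 10^(-1 / slope) - 1 else NA_real_,
         points = data.frame(log10_dilution = log10_dilution, cq = cq)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f cycles/log10, R^2 %.4f, efficiency %.1f%%\n",
              x$slope, x$r_squared, 100 * x$efficiency))
  invisible(x)
}
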