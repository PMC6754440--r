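#' Default translational-state pools
#'
#' Fraction index sets for a 12-fraction sucrose gradient: light fractions
#' 2-4 hold translationally inactive mRNPs/monosomes, heavy fractions 9-12
#' hold actively translated polysomes. Fraction numbering depends on the
#' collection scheme, so pools are configurable everywhere they are used.
#'
#' @return Named list of integer fraction-index vectors.
#' @export
default_pools <- function() list(inactive = 2:4, active = 9:12)

#' Per-fraction percent distribution of a transcript
#'
#' Converts gradient quantities to the percentage of the transcript's total
#' signal in each fraction: `p_f = 100 * q_f / sum(q)`. Percentages sum to
#' 100 by construction.
#'
#' @param x A [fraction_table()].
#' @param transcript Transcript to profile.
#' @param pools Named list of disjoint fraction-index sets (default
#'   [default_pools()]).
#' @return An object of class `polysome_profile`: list with `transcript`,
#'   `quantity`, `percent` (both length n, fraction order), `pools`.
#' @export
fraction_percents <- function(x, transcript, pools = default_pools()) {
  validate_fraction_table(x)
  rows <- x[x$transcript == transcript, , drop = FALSE]
  if (nrow(rows) == 0) stop("transcript '", transcript, "' not in table")
  rows <- rows[order(rows$fraction), , drop = FALSE]
  total <- sum(rows$quantity)
  if (total == 0) {
    stop("all-zero quantities for transcript '", transcript,
         "': percent distribution undefined")
  }
  new_polysome_profile(transcript, quantity = rows$quantity,
                       percent = 100 * rows$quantity / total, pools = pools)
}

new_polysome_profile <- function(transcript, quantity, percent, pools,
                                 sem = NULL, n_replicates = 1L) {
  idx <- unlist(pools, use.names = FALSE)
  if (anyDuplicated(idx)) stop("pools must be disjoint fraction sets")
  structure(
    list(transcript = transcript, quantity = quantity, percent = percent,
         sem = sem, n_replicates = n_replicates, pools = pools),
    class = "polysome_profile"
  )
}

#' @export
print.polysome_profile <- function(x, ...) {
  cat("polysome_profile: '", x$transcript, "', ", length(x$percent),
      " fractions", if (x$n_replicates > 1)
        paste0(" (mean of ", x$n_replicates, " replicates)"), "\n", sep = "")
  print(round(stats::setNames(x$percent, seq_along(x$percent)), 2))
  invisible(x)
}

#' Share of a transcript's signal in a fraction pool
#'
#' Sum of the per-fraction percentages over a named pool of fractions.
#'
#' @param profile A `polysome_profile` from [fraction_percents()] or
#'   [mean_profile()].
#' @param pool_name Name of a pool defined in the profile, or `"all"` for
#'   every fraction.
#' @return Percent of the transcript's total signal in the pool.
#' @export
pool_share <- function(profile, pool_name) {
  stopifnot(inherits(profile, "polysome_profile"))
  if (identical(pool_name, "all")) return(sum(profile$percent))
  if (!pool_name %in% names(profile$pools)) {
    stop("unknown pool '", pool_name, "'; defined pools: ",
         paste(names(profile$pools), collapse = ", "))
  }
  idx <- profile$pools[[pool_name]]
  n <- length(profile$percent)
  if (length(idx) && (min(idx) < 1 || max(idx) > n)) {
    stop("pool '", pool_name, "' indices outside 1..", n)
  }
  sum(profile$percent[idx])
}

#' Mean profile with SEM over biological replicates
#'
#' Per-fraction mean of the percent distributions of replicate profiles and
#' the standard error of the mean (`sd/sqrt(k)` with the sample, k-1
#' denominator, standard deviation; 0 when k = 1). Percentages are computed
#' per replicate and then averaged, so the mean still sums to 100.
#'
#' @param profiles List of `polysome_profile`s of the same transcript with
#'   the same number of fractions.
#' @return A `polysome_profile` whose `percent` is the per-fraction mean and
#'   with `sem` filled in.
#' @export
mean_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "polysome_profile")))
  n <- length(profiles[[1]]$percent)
  tr <- profiles[[1]]$transcript
  for (p in profiles) {
    if (length(p$percent) != n) {
      stop("profiles have different numbers of fractions (", n, " vs ",
           length(p$percent), ")")
    }
    if (!identical(p$transcript, tr)) {
      stop("profiles are for different transcripts ('", tr, "' vs '",
           p$transcript, "')")
    }
  }
  k <- length(profiles)
  pmat <- do.call(rbind, lapply(profiles, `[[`, "percent"))
  qmat <- do.call(rbind, lapply(profiles, `[[`, "quantity"))
  sem <- if (k > 1) apply(pmat, 2, stats::sd) / sqrt(k) else rep(0, n)
  new_polysome_profile(tr, quantity = colMeans(qmat),
                       percent = colMeans(pmat),
                       pools = profiles[[1]]$pools,
                       sem = sem, n_replicates = k)
}
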