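#' Simulation parameters for spectral-count tables with planted truth
#'
#' Defines the protein classes, per-class mean counts per pulldown sample,
#' the count model and the replicate layout. Defaults emulate the count
#' structure an oligo-capture experiment produces: sporadic low-level resin
#' background in every sample; abundant pan RNA-binding proteins (DDX4-like)
#' that dominate the housekeeping control pulldown; and bait-specific
#' proteins (including splicing-factor-like proteins shared by both baits)
#' that are absent from the control. Counts are negative binomial with
#' variance `mu + dispersion * mu^2` (so `dispersion = 0` is Poisson),
#' thinned by a zero-dropout probability that mimics the sparsity of
#' spectral counting near the detection limit.
#'
#' @param n_per_class Named integer vector: proteins per class.
#' @param class_means Numeric matrix, one row per class and one column per
#'   sample (baits then control): mean spectral count per replicate.
#' @param dispersion Negative-binomial overdispersion (>= 0; 0 = Poisson).
#' @param dropout Probability in \[0, 1\] that any count is zeroed.
#' @param baits Bait sample names.
#' @param bait_replicates Replicates per bait sample.
#' @param control Control sample name.
#' @param control_replicates Replicates of the control sample.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_per_class = c(background = 50, pan_rbp = 50,
                                       bait1_specific = 50,
                                       bait2_specific = 50,
                                       shared_specific = 50),
                       class_means = default_class_means(),
                       dispersion = 0.2,
                       dropout = 0.05,
                       baits = c("Tnp1", "Tnp2"),
                       bait_replicates = 2,
                       control = "Actin",
                       control_replicates = 3) {
  samples <- c(baits, control)
  class_means <- as.matrix(class_means)
  if (is.null(rownames(class_means))) rownames(class_means) <- names(n_per_class)
  if (is.null(colnames(class_means))) colnames(class_means) <- samples
  stopifnot(all(names(n_per_class) %in% rownames(class_means)),
            all(samples %in% colnames(class_means)),
            all(class_means >= 0),
            dispersion >= 0,
            dropout >= 0, dropout <= 1,
            bait_replicates >= 1, control_replicates >= 1,
            length(baits) >= 1)
  structure(
    list(n_per_class = n_per_class, class_means = class_means,
         dispersion = dispersion, dropout = dropout,
         baits = baits, bait_replicates = as.integer(bait_replicates),
         control = control, control_replicates = as.integer(control_replicates)),
    class = "sim_params"
  )
}

#' @rdname sim_params
#' @export
default_class_means <- function() {
  m <- rbind(
    background      = c(0.5, 0.5, 0.5),
    pan_rbp         = c(20,  20,  30),
    bait1_specific  = c(25,  1,   0),
    bait2_specific  = c(1,   25,  0),
    shared_specific = c(25,  25,  0)
  )
  colnames(m) <- c("Tnp1", "Tnp2", "Actin")
  m
}

rcount <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a spectral-count table with planted class labels
#'
#' Draws every (protein, replicate) count from the class/sample-specific
#' negative-binomial model of `params`, then zeroes counts independently
#' with the dropout probability. Deterministic given `seed`.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return A list with `table` (a [spectral_counts()]) and `truth`
#'   (data.frame `accession`, `gene`, `class` — the planted ground truth).
#' @export
simulate_spectral_counts <- function(params = sim_params(), seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  classes <- rep(names(params$n_per_class), params$n_per_class)
  n <- length(classes)
  if (n == 0) stop("no proteins to simulate")
  cols <- c(
    unlist(lapply(params$baits, function(b)
      paste0(b, "_rep", seq_len(params$bait_replicates)))),
    paste0(params$control, "_rep", seq_len(params$control_replicates))
  )
  col_sample <- sub("_rep[0-9]+$", "", cols)
  counts <- matrix(0L, nrow = n, ncol = length(cols),
                   dimnames = list(NULL, cols))
  for (j in seq_along(cols)) {
    mu <- params$class_means[classes, col_sample[j]]
    counts[, j] <- rcount(n, mu, params$dispersion)
  }
  if (params$dropout > 0) {
    drop <- matrix(stats::runif(n * length(cols)) < params$dropout,
                   nrow = n)
    counts[drop] <- 0L
  }
  accession <- sprintf("SYN%05d", seq_len(n))
  gene <- toupper(paste0(abbreviate_class(classes), ave(classes, classes,
                                                        FUN = seq_along)))
  table <- spectral_counts(accession, gene, counts, control = params$control)
  truth <- data.frame(accession = accession, gene = gene, class = classes,
                      stringsAsFactors = FALSE)
  class(truth) <- c("planted_truth", "data.frame")
  list(table = table, truth = truth)
}

abbreviate_class <- function(cl) {
  map <- c(background = "BG", pan_rbp = "PAN", bait1_specific = "B1S",
           bait2_specific = "B2S", shared_specific = "SHS")
  out <- unname(map[cl])
  out[is.na(out)] <- toupper(substr(cl[is.na(out)], 1, 3))
  out
}

#' Simulate a Cq table with a planted percent-of-input recovery
#'
#' Builds an input/elution Cq table in which the target transcript's
#' elution Cq is offset by `log2(100 / planted_recovery)` cycles from its
#' input Cq while the reference transcript is held constant, so that
#' [percent_of_input()] on the noiseless output returns the planted
#' recovery exactly. Gaussian noise (cycles) is added per technical
#' replicate.
#'
#' @param planted_recovery Planted percent-of-input recovery (> 0).
#' @param base_cq Input Cq of the target transcript (cycles).
#' @param noise_sd Per-replicate Gaussian Cq noise (cycles).
#' @param seed Integer seed.
#' @param transcript,reference Target and reference transcript names.
#' @param reference_cq Input/elution Cq of the reference transcript.
#' @param n_tech Technical replicates per (sample, transcript).
#' @return A [cq_table()].
#' @export
simulate_cq <- function(planted_recovery, base_cq = 20, noise_sd = 0, seed,
                        transcript = "Tnp1", reference = "Actin",
                        reference_cq = 15, n_tech = 3) {
  if (planted_recovery <= 0) stop("planted recovery must be > 0")
  set.seed(seed)
  elution_cq <- base_cq + log2(100 / planted_recovery)
  grid <- expand.grid(sample = c("input", "elution"),
                      transcript = c(transcript, reference),
                      tech_rep = seq_len(n_tech),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- ifelse(grid$transcript == reference, reference_cq,
                 ifelse(grid$sample == "input", base_cq, elution_cq))
  cq_table(grid$sample, grid$transcript,
           is_reference = grid$transcript == reference,
           tech_rep = grid$tech_rep,
           cq = base + stats::rnorm(nrow(grid), 0, noise_sd))
}

#' Simulate a polysome fraction table with planted pool weights
#'
#' Distributes each pool's weight uniformly (or per a supplied within-pool
#' shape) over its fractions; fractions outside every pool get quantity 0.
#' Optional multiplicative log-normal noise perturbs each fraction. On the
#' noiseless output, [pool_share()] recovers the planted weight shares
#' exactly.
#'
#' @param pool_weights Named non-negative weights, one per pool, sum > 0.
#' @param n_fractions Number of gradient fractions.
#' @param pools Named list of disjoint fraction-index sets.
#' @param shape `"uniform"`, or a named list of per-fraction weight vectors
#'   (one per pool, same length as the pool) for non-uniform within-pool
#'   distributions.
#' @param noise_sd SD of the log-normal multiplicative noise (0 = none).
#' @param seed Integer seed.
#' @param transcript Transcript label for the output table.
#' @return A [fraction_table()] for one transcript.
#' @export
simulate_polysome <- function(pool_weights = c(inactive = 0.5, active = 0.5),
                              n_fractions = 12, pools = default_pools(),
                              shape = "uniform", noise_sd = 0, seed,
                              transcript = "Tnp1") {
  stopifnot(all(pool_weights >= 0), sum(pool_weights) > 0,
            all(names(pool_weights) %in% names(pools)))
  idx_all <- unlist(pools[names(pool_weights)], use.names = FALSE)
  if (min(idx_all) < 1 || max(idx_all) > n_fractions) {
    stop("pool indices outside 1..", n_fractions)
  }
  set.seed(seed)
  q <- numeric(n_fractions)
  for (pool in names(pool_weights)) {
    idx <- pools[[pool]]
    w <- if (identical(shape, "uniform")) rep(1, length(idx)) else {
      stopifnot(length(shape[[pool]]) == length(idx))
      shape[[pool]]
    }
    q[idx] <- pool_weights[[pool]] * w / sum(w)
  }
  if (noise_sd > 0) {
    q <- q * exp(stats::rnorm(n_fractions, 0, noise_sd))
  }
  fraction_table(seq_len(n_fractions), transcript, q)
}

#' Score candidate detection against the planted truth
#'
#' Positives are the selected candidates of an enrichment result; the
#' condition-positive proteins are those whose planted class is any
#' `*_specific` label. Standard confusion-matrix ratios; ratios with a zero
#' denominator are reported as `NA`, never as 0.
#'
#' @param results An `enrichment_result` from [score_table()].
#' @param truth A `planted_truth` data.frame from
#'   [simulate_spectral_counts()] over the same proteins.
#' @return A list with `confusion` (named counts tp/fp/tn/fn),
#'   `sensitivity`, `specificity`, `precision`.
#' @export
evaluate_detection <- function(results, truth) {
  stopifnot(inherits(results, "enrichment_result"))
  if (!setequal(results$accession, truth$accession)) {
    stop("results and truth cover different protein sets")
  }
  cl <- truth$class[match(results$accession, truth$accession)]
  positive <- results$selected
  condition <- grepl("_specific$", cl)
  tp <- sum(positive & condition)
  fp <- sum(positive & !condition)
  fn <- sum(!positive & condition)
  tn <- sum(!positive & !condition)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       precision = ratio(tp, tp + fp))
}
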