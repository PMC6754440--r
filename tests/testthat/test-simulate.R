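test_that("simulators are bit-reproducible under a fixed seed", {
  a <- simulate_spectral_counts(sim_params(), seed = 99)
  b <- simulate_spectral_counts(sim_params(), seed = 99)
  expect_identical(a, b)
  expect_false(identical(a$table$counts,
                         simulate_spectral_counts(sim_params(), seed = 100)$table$counts))

  expect_identical(simulate_cq(40, noise_sd = 0.2, seed = 5),
                   simulate_cq(40, noise_sd = 0.2, seed = 5))
  expect_identical(simulate_polysome(noise_sd = 0.2, seed = 5),
                   simulate_polysome(noise_sd = 0.2, seed = 5))
})

test_that("every simulated protein carries exactly one planted class label", {
  sim <- simulate_spectral_counts(sim_params(), seed = 3)
  expect_equal(nrow(sim$truth), length(sim$table$accession))
  expect_setequal(sim$truth$accession, sim$table$accession)
  expect_true(all(sim$truth$class %in%
                    c("background", "pan_rbp", "bait1_specific",
                      "bait2_specific", "shared_specific")))
})

test_that("zero dispersion reduces to Poisson counts concentrated at the mean", {
  m <- 1000
  params <- sim_params(
    n_per_class = c(background = 2500),
    class_means = matrix(m, 1, 2, dimnames = list("background", c("b", "c"))),
    dispersion = 0, dropout = 0,
    baits = "b", bait_replicates = 2, control = "c", control_replicates = 2
  )
  sim <- simulate_spectral_counts(params, seed = 17)
  cells <- as.numeric(sim$table$counts)  # 10^4 cells
  expect_equal(length(cells), 1e4)
  expect_lt(mean(abs(cells - m) / m), 0.05)
})

test_that("bait-specific proteins score near the expectation 2 * mu / 0.9", {
  params <- sim_params(
    n_per_class = c(bait1_specific = 1000),
    class_means = matrix(c(30, 0), 1, 2,
                         dimnames = list("bait1_specific", c("b", "c"))),
    dispersion = 0.2, dropout = 0,
    baits = "b", bait_replicates = 2, control = "c", control_replicates = 3
  )
  sim <- simulate_spectral_counts(params, seed = 23)
  res <- score_table(sim$table)
  expect_equal(mean(res$S_combined), 2 * 30 / 0.9, tolerance = 0.05)
})

test_that("planted Cq recovery round-trips exactly without noise", {
  expect_equal(percent_of_input(simulate_cq(100, noise_sd = 0, seed = 1),
                                "Tnp1")$percent_of_input, 100)
  noiseless <- simulate_cq(25, noise_sd = 0, seed = 1)
  expect_equal(percent_of_input(noiseless, "Tnp1")$ddcq, 2)
  expect_equal(percent_of_input(noiseless, "Tnp1")$percent_of_input, 25)
  expect_error(simulate_cq(0, seed = 1), "must be > 0")
  expect_error(simulate_cq(-4, seed = 1), "must be > 0")
})

test_that("noisy Cq simulations recover the planted recovery on average", {
  rec <- vapply(1:100, function(s)
    percent_of_input(simulate_cq(12, noise_sd = 0.1, seed = s),
                     "Tnp1")$percent_of_input, numeric(1))
  expect_lt(abs(mean(rec) - 12) / 12, 0.03)
})

test_that("polysome simulation plants pool weights recoverable by pool_share", {
  all_active <- simulate_polysome(c(active = 1, inactive = 0), seed = 2)
  pa <- fraction_percents(all_active, "Tnp1")
  expect_equal(pool_share(pa, "active"), 100, tolerance = 1e-9)

  split <- fraction_percents(
    simulate_polysome(c(active = 0.6, inactive = 0.4), seed = 2), "Tnp1")
  expect_equal(pool_share(split, "active"), 60, tolerance = 1e-9)
  expect_equal(pool_share(split, "inactive"), 40, tolerance = 1e-9)

  shares <- vapply(1:200, function(s)
    pool_share(fraction_percents(
      simulate_polysome(c(active = 0.6, inactive = 0.4),
                        noise_sd = 0.1, seed = s), "Tnp1"), "active"),
    numeric(1))
  expect_lt(abs(mean(shares) - 60) / 60, 0.02)
})

test_that("detection metrics match a hand-enumerated confusion matrix", {
  classes <- c("bait1_specific", "shared_specific", "background",
               "background", "pan_rbp", "bait2_specific")
  selected <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  acc <- sprintf("P%d", 1:6)
  res <- data.frame(accession = acc, selected = selected,
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  truth <- data.frame(accession = acc, class = classes,
                      stringsAsFactors = FALSE)
  ev <- evaluate_detection(res, truth)
  # by hand: TP = {P1, P6}, FN = {P2}, FP = {P3}, TN = {P4, P5}
  expect_equal(ev$confusion, c(tp = 2L, fp = 1L, tn = 2L, fn = 1L))
  expect_equal(ev$sensitivity, 2 / 3)
  expect_equal(ev$specificity, 2 / 3)
  expect_equal(ev$precision, 2 / 3)

  none <- res; none$selected <- FALSE
  ev0 <- evaluate_detection(none, truth)
  expect_equal(ev0$sensitivity, 0)
  expect_true(is.na(ev0$precision))

  exact <- res; exact$selected <- grepl("_specific$", classes)
  ev1 <- evaluate_detection(exact, truth)
  expect_equal(ev1$sensitivity, 1)
  expect_equal(ev1$precision, 1)
})

test_that("default simulation detects planted specific proteins with high power", {
  sens <- spec <- numeric(10)
  for (s in seq_len(10)) {
    sim <- simulate_spectral_counts(sim_params(), seed = 4000 + s)
    ev <- evaluate_detection(score_table(sim$table), sim$truth)
    sens[s] <- ev$sensitivity
    spec[s] <- ev$specificity
  }
  expect_gte(mean(sens), 0.9)
  expect_gte(mean(spec), 0.95)
})

test_that("abundant pan RNA-binding proteins are excluded by the control filter", {
  rate <- vapply(seq_len(10), function(s) {
    sim <- simulate_spectral_counts(sim_params(), seed = 7000 + s)
    pan <- sim$truth$accession[sim$truth$class == "pan_rbp"]
    mean(pan %in% control_filter(sim$table))
  }, numeric(1))
  expect_gte(mean(rate), 0.99)
})
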