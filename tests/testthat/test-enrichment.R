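test_that("control denominator aggregates by policy and substitutes 0.9 at zero", {
  for (policy in c("mean", "sum", "max")) {
    cfg <- enrichment_config(denominator_policy = policy)
    expect_equal(control_denominator(c(0, 0, 0), cfg), 0.9)
  }
  expect_equal(control_denominator(c(2, 2, 2), enrichment_config()), 2.0)
  expect_equal(control_denominator(c(1, 2, 6),
                                   enrichment_config(denominator_policy = "mean")), 3.0)
  expect_equal(control_denominator(c(1, 2, 6),
                                   enrichment_config(denominator_policy = "sum")), 9.0)
  expect_equal(control_denominator(c(1, 2, 6),
                                   enrichment_config(denominator_policy = "max")), 6.0)
  expect_error(control_denominator(numeric(0)), "no control replicate counts")
})

test_that("control filter applies a strict >11 rule per replicate", {
  mk <- function(ctrl) {
    counts <- matrix(c(1L, ctrl), nrow = 1,
                     dimnames = list(NULL, c("b_rep1",
                                             paste0("c_rep", seq_along(ctrl)))))
    spectral_counts("P1", "G1", counts, "c")
  }
  expect_equal(control_filter(mk(c(5L, 12L, 0L))), "P1")
  expect_equal(control_filter(mk(c(11L, 11L, 11L))), character(0))
  expect_equal(control_filter(mk(c(0L, 0L, 0L)),
                              enrichment_config(control_exclusion_threshold = 0)),
               character(0))
})

test_that("bait score is the weighted sum over replicates", {
  expect_equal(bait_score(c(20, 15), 0.9), 35 / 0.9, tolerance = 1e-12)
  expect_equal(bait_score(c(0, 0), 3.7), 0)
  expect_equal(bait_score(7, 1), 7)
  expect_error(bait_score(c(1, 2), 0), "positive")
  expect_error(bait_score(c(1, 2), -1), "positive")
})

test_that("score_table combines components and ranks deterministically", {
  counts <- matrix(
    c(20L, 15L, 0L, 1L, 0L, 0L, 0L,    # zero control -> 0.9 denominator
      3L, 2L, 5L, 4L, 0L, 14L, 0L),    # excluded: 14 > 11
    nrow = 2, byrow = TRUE,
    dimnames = list(NULL, c("Tnp1_rep1", "Tnp1_rep2", "Tnp2_rep1",
                            "Tnp2_rep2", "Actin_rep1", "Actin_rep2",
                            "Actin_rep3")))
  tab <- spectral_counts(c("Q91W50", "P11111"), c("CSDE1", "X"), counts, "Actin")
  res <- score_table(tab)

  expect_equal(res$S_Tnp1[1], 35 / 0.9, tolerance = 1e-9)
  expect_equal(res$S_Tnp2[1], 1 / 0.9, tolerance = 1e-9)
  expect_equal(res$S_combined[1], 40, tolerance = 1e-9)
  expect_equal(res$S_combined[1], res$S_Tnp1[1] + res$S_Tnp2[1])
  expect_true(res$selected[1])
  expect_true(res$highlighted[1])  # raw Tnp1 counts 20, 15 > 10

  expect_true(res$excluded[2])
  expect_false(res$selected[2])
  expect_true(is.na(res$rank[2]))
  expect_equal(res$rank[1], 1L)
})

test_that("a single all-zero protein scores 0 with rank 1", {
  counts <- matrix(0L, 1, 3,
                   dimnames = list(NULL, c("b_rep1", "b_rep2", "c_rep1")))
  res <- score_table(spectral_counts("P1", "G", counts, "c"))
  expect_equal(res$S_combined, 0)
  expect_false(res$selected)
  expect_equal(res$rank, 1L)
})

test_that("selection threshold is strict and ties break by accession", {
  mk <- function(acc, b1) {
    counts <- matrix(c(b1, rep(1L, length(acc))), ncol = 2,
                     dimnames = list(NULL, c("b_rep1", "c_rep1")))
    spectral_counts(acc, acc, counts, "c")
  }
  # denominator 1 -> S equals the raw bait count
  res <- score_table(mk(c("A", "B"), c(9L, 10L)))
  expect_equal(select_candidates(res)$accession, "B")  # S = 9 exactly rejected
  cfg <- enrichment_config(candidate_threshold = 9.005)
  res <- score_table(mk("A", 10L), cfg)  # S = 10 > 9.005
  expect_true(res$selected)

  res <- score_table(mk(c("B", "A", "C"), c(12L, 12L, 3L)),
                     enrichment_config(candidate_threshold = 5))
  expect_equal(select_candidates(res)$accession, c("A", "B"))
})

test_that("scores scale exactly with bait counts and respond monotonically", {
  set.seed(101)
  for (i in 1:20) {
    tab <- random_spectral_counts()
    cfg <- random_enrichment_config()
    res <- score_table(tab, cfg)
    k <- sample(2:5, 1)
    tab_k <- tab
    bait_cols <- tab$samples != tab$control
    tab_k$counts[, bait_cols] <- tab_k$counts[, bait_cols] * k
    res_k <- score_table(tab_k, cfg)
    expect_equal(res_k$S_combined, k * res$S_combined, tolerance = 1e-12)
    expect_equal(res_k$control_denominator, res$control_denominator)

    # bumping one bait count never decreases S
    j <- sample(which(bait_cols), 1)
    tab_up <- tab
    tab_up$counts[, j] <- tab_up$counts[, j] + 1L
    expect_true(all(score_table(tab_up, cfg)$S_combined >= res$S_combined))

    # bumping a positive control count never increases S (counts > 0)
    cj <- which(!bait_cols)[1]
    pos <- tab$counts[, cj] > 0
    if (any(pos)) {
      tab_dn <- tab
      tab_dn$counts[pos, cj] <- tab_dn$counts[pos, cj] + 1L
      expect_true(all(score_table(tab_dn, cfg)$S_combined[pos] <=
                        res$S_combined[pos] + 1e-12))
    }
  }
})

test_that("the control filter is idempotent and disjoint from selection", {
  set.seed(202)
  for (i in 1:25) {
    tab <- random_spectral_counts(max_count = 15)
    cfg <- random_enrichment_config()
    excluded <- control_filter(tab, cfg)
    keep <- !(tab$accession %in% excluded)
    if (any(keep)) {
      sub <- spectral_counts(tab$accession[keep], tab$gene[keep],
                             tab$counts[keep, , drop = FALSE], tab$control)
      expect_equal(control_filter(sub, cfg), character(0))
    }
    res <- score_table(tab, cfg)
    expect_false(any(res$excluded & res$selected))
    ranked <- res$rank[!res$excluded]
    expect_setequal(ranked, seq_along(ranked))
  }
})

test_that("the reproduction report computes per-policy candidate counts and deltas", {
  # synthetic stand-in with the published dataset's column layout; scores
  # will not match the published reference, so the report must carry the
  # per-protein deltas and an NA matching policy
  set.seed(404)
  n <- 40
  counts <- matrix(sample(0:30, n * 7, replace = TRUE), nrow = n,
                   dimnames = list(NULL, c("Tnp1_rep1", "Tnp1_rep2",
                                           "Tnp2_rep1", "Tnp2_rep2",
                                           "Actin_rep1", "Actin_rep2",
                                           "Actin_rep3")))
  acc <- c(published_candidate_scores()$accession, sprintf("X%03d", 1:(n - 6)))
  tab <- spectral_counts(acc, acc, counts, "Actin")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectral_counts(tab, f)

  report <- reproduce_published_analysis(f)
  expect_setequal(setdiff(names(report), "matching_policy"),
                  c("mean", "sum", "max"))
  for (policy in c("mean", "sum", "max")) {
    cfg <- enrichment_config(denominator_policy = policy)
    expect_equal(report[[policy]]$n_candidates,
                 sum(score_table(tab, cfg)$selected))
    expect_equal(nrow(report[[policy]]$deltas), 6)
    expect_false(anyNA(report[[policy]]$deltas$delta_S_Tnp1))
  }
  expect_true(is.na(report$matching_policy))
})

test_that("scoring matches a literal brute-force oracle on random tiny tables", {
  set.seed(303)
  n_tables <- 120
  for (i in seq_len(n_tables)) {
    tab <- random_spectral_counts()
    cfg <- random_enrichment_config()
    res <- score_table(tab, cfg)
    orc <- oracle_score(tab, cfg)
    expect_equal(res$S_combined, orc$S, tolerance = 1e-12)
    expect_equal(res$control_denominator, orc$denom)
    expect_equal(res$excluded, orc$excluded)
    expect_equal(select_candidates(res)$accession, oracle_candidates(tab, cfg))
  }
})
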