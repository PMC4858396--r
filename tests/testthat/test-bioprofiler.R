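# bioassay profiling: confusion, CCR/L, selection, RA, chi-squared

test_that("confusion tabulates only definite overlapping calls", {
  calls <- named_calls(rep(1, 10))
  labs <- named_calls(rep(1, 10))
  expect_identical(confusion(calls, labs), list(TP = 10L, TN = 0L, FP = 0L, FN = 0L))

  calls <- named_calls(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  labs <- named_calls(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  expect_identical(confusion(calls, labs), list(TP = 4L, TN = 6L, FP = 0L, FN = 0L))

  calls <- named_calls(c(1, 1, 0, 0, NA))
  labs <- named_calls(c(1, 0, 1, 0, 1))
  expect_identical(confusion(calls, labs), list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))

  # inconclusive (-1) excluded like untested
  calls <- named_calls(c(1, -1, 0))
  labs <- named_calls(c(1, 1, 0))
  expect_identical(confusion(calls, labs), list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  expect_error(confusion(named_calls(1, "x"), named_calls(1, "y")), "overlapping")
})

test_that("CCR and L evaluate the printed formulas", {
  s <- assay_stats(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(ccr(s), 1.0)
  expect_equal(likelihood_param(s), 1.0 * (0 + 10) / (0 + 1))  # = 10
  s <- assay_stats(list(TP = 5, TN = 5, FP = 5, FN = 5))
  expect_equal(ccr(s), 0.5)
  s <- assay_stats(list(TP = 3, TN = 8, FP = 2, FN = 1))
  expect_equal(s$sensitivity, 3 / 4)
  expect_equal(s$specificity, 8 / 10)
  expect_equal(ccr(s), (3 / 4 + 8 / 10) / 2)
  expect_equal(likelihood_param(s), (3 / 4) * (2 + 3) / (2 + 1))
  # absent class flags the statistic undefined
  s <- assay_stats(list(TP = 0, TN = 5, FP = 5, FN = 0))
  expect_false(s$defined)
  expect_true(is.na(ccr(s)))
})

test_that("pearson_chi2 equals the determinant closed form and rejects degeneracy", {
  got <- pearson_chi2(matrix(c(25, 25, 25, 25), 2))
  expect_equal(got$statistic, 0)
  expect_equal(got$p, 1)
  got <- pearson_chi2(matrix(c(30, 10, 10, 30), 2))
  want <- oracle_chi2(30, 10, 10, 30)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  # and agrees with the uncorrected base-R test on one table
  ct <- stats::chisq.test(matrix(c(12, 5, 7, 20), 2), correct = FALSE)
  got <- pearson_chi2(matrix(c(12, 5, 7, 20), 2))
  expect_equal(got$statistic, unname(ct$statistic), tolerance = 1e-10)
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2)), "degenerate")
  expect_error(pearson_chi2(matrix(c(-1, 2, 3, 4), 2)), "negative")
  # Yates toggle reduces the statistic
  expect_lt(pearson_chi2(matrix(c(12, 5, 7, 20), 2), correct = TRUE)$statistic,
            got$statistic)
})

test_that("select_assays enforces all four criteria with strict bounds", {
  mk <- function(TP, TN, FP, FN) assay_stats(list(TP = TP, TN = TN, FP = FP, FN = FN))
  good <- mk(20, 30, 5, 5)       # sens .8 spec .857 ccr .83 L .8*25/6=3.3
  meta <- data.frame(assay_id = c("A", "B", "C", "D"),
                     in_vitro = c(TRUE, TRUE, TRUE, FALSE))
  # appearance in both groups
  expect_identical(select_assays(list(A = good), list(B = good), meta),
                   character(0))
  # strict > 10 matching actives: TP = 10 excluded, TP = 11 included
  ten <- mk(10, 30, 5, 5); eleven <- mk(11, 30, 5, 5)
  expect_identical(select_assays(list(A = ten), list(A = ten), meta), character(0))
  expect_identical(select_assays(list(A = eleven), list(A = eleven), meta), "A")
  # better-than-random: CCR must exceed 0.5 and L at least 1
  random <- mk(15, 15, 15, 15)   # ccr .5, L = .5*30/16 < 1
  expect_identical(select_assays(list(A = random), list(A = random), meta),
                   character(0))
  # in vitro flag
  expect_identical(select_assays(list(D = good), list(D = good), meta),
                   character(0))
  # deterministic order: descending mean CCR then id
  better <- mk(25, 30, 2, 2)
  sel <- select_assays(list(A = good, B = better, C = good),
                       list(A = good, B = better, C = good), meta)
  expect_identical(sel, c("B", "A", "C"))
})

test_that("rate_of_actives reproduces the worked examples and missing-data rule", {
  r <- rate_of_actives(c(1, 0, 0, 0))
  expect_equal(r$ra, 0.25)
  expect_identical(r$call, "nontoxic")
  r <- rate_of_actives(c(1, 0, 0, NA))
  expect_equal(r$ra, 1 / 3, tolerance = 1e-12)
  expect_identical(r$call, "toxic")
  r <- rate_of_actives(c(NA, NA, -1, NA))
  expect_identical(r$call, "no_data")
  expect_true(is.na(r$ra))
  # untested responses never move RA (the design motivation)
  set.seed(3)
  for (i in 1:25) {
    row <- sample(c(1L, 0L, -1L, NA), 6, replace = TRUE)
    r1 <- rate_of_actives(row)
    r2 <- rate_of_actives(c(row, NA, -1L))
    expect_identical(r1$ra, r2$ra)
    expect_identical(r1$call, r2$call)
  }
})

test_that("CCR of a label-permuted assay converges to chance", {
  set.seed(99)
  calls <- named_calls(rbinom(400, 1, 0.3), sprintf("C%03d", 1:400))
  ccrs <- replicate(60, {
    labs <- stats::setNames(sample(rep(0:1, each = 200)), names(calls))
    ccr(assay_stats(confusion(calls, labs)))
  })
  expect_lt(abs(mean(ccrs) - 0.5), 0.02)
})

test_that("build_profile surfaces a perfectly predictive assay and row counts", {
  lib <- make_library(300, seed = 77, missing_rate = 0.2)$lib
  cfg <- sim_config(n_compounds = 300, seed = 77, missing_rate = 0.2)
  am <- generate_assay_matrix(lib, cfg)
  # overwrite one irrelevant assay with the label itself
  am$calls[, "AID0020"] <- as.integer(lib$is_liver_toxic)
  labels <- stats::setNames(as.integer(lib$is_liver_toxic), lib$compound_id)
  half <- seq_len(nrow(lib)) %% 2L == 1L
  bp <- build_profile(am, labels[lib$compound_id[half]],
                      labels[lib$compound_id[!half]], ra_labels = labels)
  expect_identical(bp$selected[1], "AID0020")    # tops the CCR ordering
  # profile table rows = compounds with at least one definite call
  sub <- am$calls[, bp$selected, drop = FALSE]
  n_definite <- sum(apply(sub, 1, function(r) any(r %in% c(0L, 1L))))
  expect_identical(nrow(bp$profile_table), n_definite)
  expect_s3_class(assay_stats_table(bp$stats_a, bp$selected), "data.frame")
})
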