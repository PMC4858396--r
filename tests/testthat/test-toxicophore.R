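# toxicophore matching, fragment IVIVC, enrichment ranking

test_that("match_fragment follows substructure semantics and survives bad input", {
  smi <- c(tol = "Cc1ccccc1", chx = "C1CCCCC1", sulfa = "NS(=O)(=O)c1ccccc1",
           bad = "C1CC(")
  expect_identical(match_fragment("c1ccccc1", smi), c("tol", "sulfa"))
  expect_identical(match_fragment("S(=O)(=O)N", smi), "sulfa")
  expect_identical(match_fragment("C1CCCCC1", smi), "chx")
  expect_error(match_fragment("C1CC(", smi), "invalid fragment")
})

test_that("planted-fragment matching equals generator bookkeeping exactly", {
  lib <- generate_library(sim_config(n_compounds = 500, seed = 41))
  smi <- stats::setNames(lib$smiles, lib$compound_id)
  for (spec in list(c("frag_sulfonamide", "S(=O)(=O)N"),
                    c("frag_allyl", "C=CC"),
                    c("frag_nmf", "N(C)C=O"))) {
    matched <- match_fragment(spec[2], smi)
    expect_setequal(matched, lib$compound_id[lib[[paste0("carries_", spec[1])]]])
  }
})

test_that("fragment_ivivc builds the 2x2 over definite calls only", {
  ids <- sprintf("C%02d", 1:8)
  calls <- stats::setNames(c(1L, 1L, 1L, 0L, 0L, NA, -1L, 1L), ids)
  labs <- stats::setNames(c(1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L), ids)
  fi <- fragment_ivivc(ids, calls, labs)
  expect_identical(fi$n_matched, 8L)
  expect_identical(fi$stats$TP, 4L)
  expect_identical(fi$stats$TN, 2L)
  expect_identical(fi$stats$FP, 0L)
  expect_identical(fi$stats$FN, 0L)
  expect_identical(fi$n_indeterminate, 2L)
  expect_equal(fi$stats$sensitivity, 1.0)
  expect_identical(fi$source, "experimental")
  expect_error(fragment_ivivc(character(0), calls, labs), "empty")
  row <- fragment_ivivc_row("f1", fi)
  expect_identical(row$TP, 4L)
})

test_that("label-independent calls give a null chi-squared (uniform-ish p)", {
  set.seed(12)
  ids <- sprintf("C%03d", 1:200)
  labs <- stats::setNames(rep(0:1, 100), ids)
  ps <- replicate(40, {
    calls <- stats::setNames(rbinom(200, 1, 0.4), ids)
    fragment_ivivc(ids, calls, labs)$stats$chi2_p
  })
  expect_lt(mean(ps < 0.05, na.rm = TRUE), 0.2)
  expect_gt(mean(ps, na.rm = TRUE), 0.3)
})

test_that("rank_fragments handles degenerate inputs", {
  lib <- generate_library(sim_config(n_compounds = 40, seed = 3))
  smi <- stats::setNames(lib$smiles, lib$compound_id)
  flags <- stats::setNames(rep(TRUE, 40), names(smi))
  expect_warning(out <- rank_fragments(smi, flags), "no contrast")
  expect_identical(nrow(out), 0L)
  flags[1:10] <- FALSE
  expect_warning(out <- rank_fragments(smi, flags, min_support = 1000),
                 "min_support")
  expect_identical(nrow(out), 0L)
})

test_that("a planted dual-association fragment is ranked near the top", {
  cfg <- sim_config(n_compounds = 400, seed = 55)
  lib <- generate_library(cfg)
  ids <- lib$compound_id
  smi <- stats::setNames(lib$smiles, ids)
  dual <- stats::setNames(lib$is_are_active & lib$is_liver_toxic, ids)
  rk <- rank_fragments(smi, dual)
  matches <- attr(rk, "matches")
  planted_sets <- lapply(c("S(=O)(=O)N", "N(C)C=O", "C=CC"),
                         function(p) match_fragment(p, smi))
  hit <- vapply(rk$fragment_id[1:3], function(fid) {
    mm <- matches[[fid]]
    length(mm) > 0 && any(vapply(planted_sets,
                                 function(ps) all(mm %in% ps), TRUE))
  }, TRUE)
  expect_true(any(hit))
  expect_true(all(diff(rk$score) <= 1e-12))   # ordered by score
})
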