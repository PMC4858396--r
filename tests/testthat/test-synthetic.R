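# synthetic-data module: determinism, marginal calibration, planted structure

test_that("empty and deterministic generation contracts hold", {
  cfg0 <- sim_config(n_compounds = 0)
  expect_identical(nrow(generate_library(cfg0)), 0L)

  cfg <- sim_config(n_compounds = 150, seed = 33)
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(lib1, lib2)
  expect_identical(generate_curves(lib1, cfg), generate_curves(lib2, cfg))
  am1 <- generate_assay_matrix(lib1, cfg)
  am2 <- generate_assay_matrix(lib2, cfg)
  expect_identical(am1, am2)
})

test_that("config validation rejects bad worlds", {
  expect_error(sim_config(n_relevant_assays = 50, n_assays = 10), "exceed")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  fs <- default_fragment_specs(); fs$prevalence[1] <- 1.2
  expect_error(sim_config(fragment_specs = fs), "prevalence")
  fs <- default_fragment_specs(); fs$pattern[2] <- "C1CC"
  expect_error(sim_config(fragment_specs = fs), "unparseable")
})

test_that("fragment carriage matches prevalence within the exact binomial 99% CI,
           verified by independent substructure matching", {
  lib <- generate_library(sim_config(n_compounds = 2000, seed = 21))
  smi <- stats::setNames(lib$smiles, lib$compound_id)
  # sulfonamide: sulfur is exclusive to this fragment in the vocabulary
  matched <- match_fragment("S(=O)(=O)N", smi)
  expect_setequal(matched, lib$compound_id[lib$carries_frag_sulfonamide])
  n <- nrow(lib); p <- 0.10
  ci <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(length(matched), ci[1])
  expect_lte(length(matched), ci[2])
})

test_that("marginal active/toxic/missing rates track their targets", {
  cfg <- sim_config(n_compounds = 2000, seed = 8)
  lib <- generate_library(cfg)
  expect_lt(abs(mean(lib$is_are_active) - cfg$target_active_rate), 0.03)
  expect_lt(abs(mean(lib$is_liver_toxic) - cfg$target_toxic_rate), 0.04)
  am <- generate_assay_matrix(lib, cfg)
  expect_lt(abs(mean(is.na(am$calls)) - cfg$missing_rate), 0.02)
})

test_that("zero-noise curves honour the Hill contract", {
  cfg <- sim_config(n_compounds = 60, curve_noise_sd = 0, seed = 4)
  lib <- generate_library(cfg)
  cur <- generate_curves(lib, cfg)
  pars <- attr(cur, "params")
  for (id in lib$compound_id[!lib$is_are_active][1:5]) {
    expect_identical(unique(cur$response[cur$compound_id == id]), 0)
  }
  act <- lib$compound_id[lib$is_are_active][1]
  r <- cur[cur$compound_id == act & cur$replicate == 1, ]
  expect_true(all(diff(r$concentration_M) > 0))
  expect_equal(max(r$response), pars$top[pars$compound_id == act])
  expect_equal(which.max(r$response), nrow(r))   # top at highest conc
})

test_that("missing_rate = 0 leaves no untested cells", {
  cfg <- sim_config(n_compounds = 100, missing_rate = 0, seed = 2)
  am <- generate_assay_matrix(generate_library(cfg), cfg)
  expect_false(anyNA(am$calls))
})

test_that("planted assays carry the configured odds ratio (tabulation oracle)", {
  cfg <- sim_config(n_compounds = 600, association_odds = 8,
                    inconclusive_rate = 0, missing_rate = 0, seed = 14)
  lib <- generate_library(cfg)
  am <- generate_assay_matrix(lib, cfg)
  for (aid in am$metadata$assay_id[am$metadata$relevant]) {
    a <- sum(am$calls[lib$is_liver_toxic, aid] == 1L)
    b <- sum(am$calls[lib$is_liver_toxic, aid] == 0L)
    c_ <- sum(am$calls[!lib$is_liver_toxic, aid] == 1L)
    d <- sum(am$calls[!lib$is_liver_toxic, aid] == 0L)
    or <- (a * d) / (b * c_)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    # Wald 95% band around the realized estimate must cover the target
    expect_lt(abs(log(or) - log(8)), 1.96 * se + 1e-12)
  }
})

test_that("association_odds = 1 makes planted assays unremarkable (null safety)", {
  sel_planted <- 0L; sel_other <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_compounds = 400, association_odds = 1, seed = 100 + s)
    lib <- generate_library(cfg)
    am <- generate_assay_matrix(lib, cfg)
    labels <- stats::setNames(as.integer(lib$is_liver_toxic), lib$compound_id)
    half <- seq_len(nrow(lib)) %% 2L == 1L
    sa <- profile_assays(am, labels[lib$compound_id[half]])
    sb <- profile_assays(am, labels[lib$compound_id[!half]])
    sel <- select_assays(sa, sb, am$metadata)
    sel_planted <- sel_planted + sum(sel %in% am$metadata$assay_id[am$metadata$relevant])
    sel_other <- sel_other + sum(!sel %in% am$metadata$assay_id[am$metadata$relevant])
  }
  # planted selection rate indistinguishable from the irrelevant rate
  rate_planted <- sel_planted / (10 * 4)
  rate_other <- sel_other / (10 * 36)
  expect_lt(abs(rate_planted - rate_other), 0.1)
})

test_that("writers emit readable plain-text artifacts", {
  tmp <- withr::local_tempdir()
  lib <- generate_library(sim_config(n_compounds = 20, seed = 3))
  smi_path <- write_smi(lib, file.path(tmp, "lib.smi"))
  lines <- readLines(smi_path)
  expect_length(lines, 20)
  expect_true(all(grepl("\t", lines, fixed = TRUE)))
  sdf_path <- write_sdf(lib, file.path(tmp, "lib.sdf"))
  expect_identical(sum(readLines(sdf_path) == "$$$$"), 20L)

  cfg <- sim_config(n_compounds = 20, seed = 3)
  am <- generate_assay_matrix(lib, cfg)
  mp <- file.path(tmp, "am.csv"); mdp <- file.path(tmp, "meta.csv")
  write_assay_matrix_csv(am, mp, mdp)
  am2 <- read_assay_matrix_csv(mp, mdp)
  expect_identical(am2$calls, am$calls)
  expect_identical(am2$metadata$assay_id, am$metadata$assay_id)
})
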