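# curve processing: range scaling, CurveP filter, Table-2 calls, aggregation

test_that("range_scale maps controls to anchors and stays linear", {
  expect_equal(range_scale(5, 5, 25), 0)
  expect_equal(range_scale(25, 5, 25), 100)
  expect_equal(range_scale(15, 5, 25), 50)
  expect_equal(range_scale(c(-5, 35), 5, 25), c(-50, 150))  # no clipping
  expect_error(range_scale(1, 10, 10), "degenerate")
})

test_that("curvep_filter reproduces the hand-computed fingerprints", {
  fp <- curvep_filter(rep(0, 15))
  expect_equal(fp$curvep, 0)
  expect_equal(fp$max_response, 0)
  expect_equal(fp$n_responses_ge20, 0L)

  fp <- curvep_filter(c(rep(0, 10), 30, 40, 50, 60, 70), noise_threshold = 10)
  expect_equal(fp$curvep, 250)
  expect_equal(fp$n_responses_ge20, 5L)
  expect_equal(fp$max_response, 70)

  # isolated spike: flattening one point beats raising four
  fp <- curvep_filter(c(rep(0, 10), 90, 0, 0, 0, 0), noise_threshold = 10)
  expect_lt(fp$curvep, 90)
  expect_equal(fp$curvep, 0)
  expect_error(curvep_filter(c(0, 1), concentrations = c(2, 1)), "ascending")
})

test_that("monotone repair agrees with the exhaustive enumeration oracle", {
  set.seed(42)
  for (i in 1:60) {
    v <- sample(c(0, 0, 0, 11, 15, 22, 30, 50), size = sample(4:8, 1),
                replace = TRUE)
    got <- toxprofiler:::.monotone_repair(v)
    want <- oracle_monotone_repair(v)
    expect_equal(sum(got), sum(want), label = paste(v, collapse = ","))
    expect_true(all(diff(got) >= 0))
  }
})

test_that("raising the noise threshold never increases CurveP", {
  set.seed(7)
  for (i in 1:40) {
    v <- pmax(0, rnorm(15, mean = sample(0:30, 1), sd = 15))
    cps <- vapply(c(0, 5, 10, 15, 20, 40),
                  function(th) curvep_filter(v, noise_threshold = th)$curvep, 1.0)
    expect_true(all(diff(cps) <= 1e-9), label = paste(round(v), collapse = ","))
  }
})

test_that("the four-category cascade reproduces the activity table", {
  expect_call <- function(cp, mx, n20, category, score) {
    fp <- structure(list(curvep = cp, max_response = mx,
                         n_responses_ge20 = as.integer(n20)),
                    class = "curve_fingerprint")
    call <- classify_replicate(fp)
    expect_identical(call$category, category)
    expect_identical(call$score, score)
  }
  expect_call(250, 70, 5, "active", 1)
  expect_call(20, 20, 1, "potential_active", 0.75)
  expect_call(0, 0, 0, "inactive", 0)
  expect_call(0, 15, 0, "inconclusive", 0.25)   # weak unconfirmed signal
  expect_call(15, 15, 0, "inconclusive", 0.25)  # curvep > 0 but max < 20
  expect_call(0, 9.99, 0, "inactive", 0)
})

test_that("every fingerprint maps to exactly one category (partition)", {
  set.seed(11)
  for (i in 1:200) {
    fp <- curvep_filter(rnorm(15, sample(c(0, 30), 1), 10))
    call <- classify_replicate(fp)
    expect_true(call$category %in% c("active", "potential_active",
                                     "inconclusive", "inactive"))
    expect_identical(call$score,
                     c(active = 1, potential_active = 0.75,
                       inconclusive = 0.25, inactive = 0)[[call$category]])
  }
})

test_that("replicate aggregation averages scores with low-side ties", {
  agg <- function(cats) aggregate_compound(lapply(cats, activity_call))
  expect_identical(agg(c("active", "active", "active"))$category, "active")
  expect_identical(agg(c("inactive", "inactive", "inactive"))$category, "inactive")
  # mean 1/3 is nearest to 0.25
  expect_identical(agg(c("active", "inactive", "inactive"))$category,
                   "inconclusive")
  # exact midpoint 0.125 resolves to the lower score
  expect_identical(agg(c("inconclusive", "inactive"))$category, "inactive")
  # midpoint 0.5 between 0.25 and 0.75 resolves down
  expect_identical(agg(c("active", "inactive"))$category, "inconclusive")
  expect_error(aggregate_compound(list()), "no replicate")
})

test_that("zero-noise classification recovers latent truth for top >= 25", {
  cfg <- sim_config(n_compounds = 250, curve_noise_sd = 0, seed = 19)
  lib <- generate_library(cfg)
  cur <- generate_curves(lib, cfg)
  calls <- process_curves(cur)
  m <- merge(calls, lib[, c("compound_id", "is_are_active")])
  m <- merge(m, attr(cur, "params"))
  sel <- !m$is_are_active | m$top >= 25
  expect_identical(mean((m$category == "active") == m$is_are_active & sel |
                          !sel), 1)
})

test_that("process_curves round-trips through the CSV writer", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  cfg <- sim_config(n_compounds = 30, seed = 6)
  lib <- generate_library(cfg)
  cur <- generate_curves(lib, cfg)
  write_curves_csv(cur, tmp)
  back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  a <- process_curves(back); b <- process_curves(cur)
  expect_identical(a[, c("compound_id", "category", "score")],
                   b[, c("compound_id", "category", "score")])
  # CSV serialization rounds at the 15th digit; calls must be unaffected
  expect_equal(a$curvep_mean, b$curvep_mean, tolerance = 1e-9)
})
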