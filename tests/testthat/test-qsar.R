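# consensus QSAR engine: down-sampling, training, CPTs, AD, external CV

test_that("downsample honours counts, determinism and similarity preference", {
  set.seed(1)
  act <- sprintf("A%02d", 1:10); inact <- sprintf("I%04d", 1:1000)
  Xa <- matrix(rnorm(10 * 4, mean = 2), 10, 4, dimnames = list(act, NULL))
  Xi <- matrix(rnorm(1000 * 4), 1000, 4, dimnames = list(inact, NULL))
  sim <- similarity_from_descriptors(Xa, Xi)
  ds <- downsample(act, inact, sim, ratio = 1)
  expect_identical(ds$n_active, 10L)
  expect_identical(ds$n_inactive, 10L)
  expect_length(ds$left_out_ids, 990)
  expect_identical(ds$modeling_ids, downsample(act, inact, sim, ratio = 1)$modeling_ids)
  # selected inactives are closer to the actives than a random draw
  sel <- setdiff(ds$modeling_ids, act)
  mean_sel <- mean(sim[, sel])
  rand <- replicate(100, mean(sim[, sample(inact, length(sel))]))
  expect_gt(mean_sel, mean(rand))
  expect_gt(mean(mean_sel > rand), 0.95)
  # shortfall warns and uses all inactives
  expect_warning(ds2 <- downsample(act, inact[1:5], sim[, 1:5], ratio = 1),
                 "shortfall")
  expect_identical(ds2$n_inactive, 5L)
  expect_error(downsample(character(0), inact, sim), "nonempty")
})

test_that("cpt_classify applies the printed threshold semantics", {
  got <- cpt_classify(c(0.5, 0.8, 0.3, 0.75, 0.49, 0.0, 1.0))
  expect_identical(got$class_cpt1,
                   c("active", "active", "inactive", "active", "inactive",
                     "inactive", "active"))
  expect_identical(got$class_cpt2,
                   c("inconclusive", "active", "inactive", "inconclusive",
                     "inconclusive", "inactive", "active"))
  expect_error(cpt_classify(1.2), "lie in")
})

test_that("range scaling is idempotent on training data and clips queries", {
  set.seed(5)
  X <- matrix(runif(200, -3, 7), 50, 4,
              dimnames = list(NULL, paste0("d", 1:4)))
  X <- cbind(X, const = 1)
  sc <- fit_range_scaler(X)
  expect_identical(sc$dropped, "const")
  Z <- apply_range_scaler(sc, X)
  expect_true(all(Z >= 0 & Z <= 1))
  expect_identical(apply_range_scaler(sc, X), Z)     # bit-identical
  Zq <- apply_range_scaler(sc, X * 10)
  expect_true(all(Zq >= 0 & Zq <= 1))                # clipped
})

test_that("consensus training recovers separable data and stays bounded", {
  sim <- simulate_descriptor_set(n = 400, effect = 6,
                                 archetype_probs = c(0.5, 0, 0.5),
                                 label_propensity = c(0, 0.5, 1), seed = 2)
  d <- split_descriptor_sets(sim$X)
  bundle <- train_consensus(d, sim$y, specs = model_specs(7))
  pred <- predict_consensus(bundle, d)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  # consensus is the mean of the six individual model scores
  indiv <- as.matrix(pred[, grep("^set", names(pred))])
  expect_equal(unname(pred$score), unname(rowMeans(indiv)), tolerance = 1e-12)
  # near-perfect resubstitution on linearly separable classes
  expect_gt(mean((pred$score >= 0.5) == (sim$y == 1)), 0.95)
  expect_error(train_consensus(d, rep(1L, 400)), "single class")
})

test_that("applicability domain is self-consistent and monotone in z", {
  sim <- simulate_descriptor_set(n = 300, seed = 9)
  d <- split_descriptor_sets(sim$X)
  mids <- rownames(sim$X)[1:200]
  dm <- lapply(d, function(x) x[mids, , drop = FALSE])
  bundle <- train_consensus(dm, sim$y[1:200], specs = model_specs(3))
  expect_gte(mean(ad_check(bundle, dm)), 0.95)      # own compounds in-AD
  # extreme outlier rejected
  out <- lapply(dm, function(x) x[1, , drop = FALSE] * 0 + 1e6)
  expect_false(any(ad_check(bundle, out)))
  # coverage monotone in z
  dq <- lapply(d, function(x) x[201:300, , drop = FALSE])
  covs <- vapply(c(-5, 0, 0.5, 2, 50),
                 function(z) coverage(ad_check(bundle, dq, z = z)), 1.0)
  expect_true(all(diff(covs) >= 0))
  expect_equal(covs[length(covs)], 1.0)
  expect_lt(covs[1], 0.05)
})

test_that("external CV is stratified, leakage-free in shape, and CPT-consistent", {
  sim <- simulate_descriptor_set(n = 600, seed = 13)
  d <- split_descriptor_sets(sim$X)
  cv <- external_cv(d, sim$y, folds = 5, seed = 13)
  expect_identical(nrow(cv), 5L * 2L * 2L)
  # fold sizes differ by at most 1 per class => n_test spread <= 2
  expect_lte(diff(range(cv$n_test)), 2)
  # CPT-2 never classifies more than CPT-1
  wide <- merge(cv[cv$cpt == "CPT-1" & !cv$ad, c("fold", "coverage")],
                cv[cv$cpt == "CPT-2" & !cv$ad, c("fold", "coverage")],
                by = "fold")
  expect_true(all(wide$coverage.y <= wide$coverage.x))
  expect_error(external_cv(d, rep(0:1, c(597, 3)), folds = 5, seed = 1),
               "per class")
})

test_that("label permutation drives CV CCR to chance", {
  sim <- simulate_descriptor_set(n = 500, seed = 21)
  d <- split_descriptor_sets(sim$X)
  set.seed(77)
  yp <- sample(sim$y)
  cv <- external_cv(d, yp, folds = 5, seed = 5)
  ccr1 <- mean(cv$ccr[cv$cpt == "CPT-1" & !cv$ad], na.rm = TRUE)
  expect_gt(ccr1, 0.4)
  expect_lt(ccr1, 0.6)
})
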