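# ---------------------------------------------------------------------------
# Consensus QSAR engine: similarity-guided down-sampling, six
# descriptor-set x algorithm combinations (RF / linear SVM / k-NN on two
# descriptor families), consensus averaging, consensus prediction
# thresholds CPT-1 / CPT-2, a k-NN applicability domain, and stratified
# 5-fold external cross-validation with no leakage of scalers, samplers or
# models across folds.
# ---------------------------------------------------------------------------

#' Similarity-guided down-sampling of the inactive class
#'
#' All actives are retained (up to `max_actives`); inactives are drawn
#' without replacement, cycling over the actives and taking each active's
#' most similar remaining inactive, until the configured active:inactive
#' ratio is met. Compounds not selected form the left-out (external) pool.
#'
#' @param active_ids,inactive_ids compound identifier vectors
#' @param similarity matrix of similarities, rows = actives (named), cols =
#'   inactives (named); build from fingerprints via [tanimoto()] or from
#'   descriptors via [similarity_from_descriptors()]
#' @param ratio target active:inactive ratio (default 750/800, the balance
#'   the original modeling set used)
#' @param max_actives optional cap on retained actives
#' @return list with `modeling_ids` (actives then selected inactives),
#'   `left_out_ids`, `n_active`, `n_inactive`
#' @export
downsample <- function(active_ids, inactive_ids, similarity,
                       ratio = 750 / 800, max_actives = Inf) {
  if (!length(active_ids) || !length(inactive_ids))
    stop("both classes must be nonempty")
  stopifnot(nrow(similarity) == length(active_ids),
            ncol(similarity) == length(inactive_ids))
  acts <- active_ids
  if (length(acts) > max_actives) acts <- acts[seq_len(max_actives)]
  target <- ceiling(length(acts) / ratio)
  if (target > length(inactive_ids)) {
    warning("ratio shortfall: only ", length(inactive_ids),
            " inactives available for a target of ", target)
    target <- length(inactive_ids)
  }
  taken <- logical(length(inactive_ids))
  sel <- integer(0)
  ai <- 1L
  # rank inactives per active once; deterministic ties by column order
  pref <- lapply(seq_along(acts), function(a)
    order(-similarity[match(acts[a], active_ids), ]))
  ptr <- rep(1L, length(acts))
  while (length(sel) < target) {
    a <- ((ai - 1L) %% length(acts)) + 1L
    while (ptr[a] <= length(inactive_ids) && taken[pref[[a]][ptr[a]]])
      ptr[a] <- ptr[a] + 1L
    if (ptr[a] <= length(inactive_ids)) {
      j <- pref[[a]][ptr[a]]
      taken[j] <- TRUE
      sel <- c(sel, j)
    }
    ai <- ai + 1L
  }
  modeling <- c(acts, inactive_ids[sel])
  list(modeling_ids = modeling,
       left_out_ids = setdiff(c(active_ids, inactive_ids), modeling),
       n_active = length(acts), n_inactive = length(sel))
}

#' Split one descriptor matrix into the two consensus descriptor sets
#'
#' Convention used when only a single matrix is available (e.g. the
#' synthetic descriptor generator): odd columns form setA, even columns
#' setB, so planted signal in leading columns reaches both families.
#'
#' @param X descriptor matrix
#' @return named list `list(setA=, setB=)`
#' @export
split_descriptor_sets <- function(X) {
  list(setA = X[, seq(1L, ncol(X), 2L), drop = FALSE],
       setB = X[, seq(2L, ncol(X), 2L), drop = FALSE])
}

#' Similarity matrix from a descriptor matrix (negative Euclidean distance)
#' @param X_active,X_inactive descriptor matrices (rows named by compound)
#' @return similarity matrix, rows = actives, cols = inactives
#' @export
similarity_from_descriptors <- function(X_active, X_inactive) {
  d2 <- outer(rowSums(X_active^2), rowSums(X_inactive^2), "+") -
    2 * X_active %*% t(X_inactive)
  s <- -sqrt(pmax(d2, 0))
  rownames(s) <- rownames(X_active); colnames(s) <- rownames(X_inactive)
  s
}

# ---- individual learners (each returns a score in [0,1]) ------------------

.fit_rf <- function(X, y, seed, ntree = 100L, max_depth = 12L,
                    min_node = 5L) {
  mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- .cpp_forest_fit(X, as.integer(y), as.integer(ntree), mtry,
                           as.integer(min_node), as.integer(max_depth),
                           as.integer(seed))
  structure(list(trees = trees), class = "tp_rf")
}
.predict_rf <- function(model, X) as.numeric(.cpp_forest_predict(model$trees, X))

# linear SVM via Pegasos subgradient descent; the margin is mapped to [0,1]
# by a logistic link (monotone, so consensus averaging stays meaningful)
.fit_svm <- function(X, y, seed, lambda = 1e-3, epochs = 30L) {
  yy <- ifelse(y == 1, 1, -1)
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b <- 0; t <- 0
  ord_rng <- .with_seed(seed, lapply(seq_len(epochs), function(e) sample(n)))
  for (e in seq_len(epochs)) {
    for (i in ord_rng[[e]]) {
      t <- t + 1
      eta <- 1 / (lambda * t)
      margin <- yy[i] * (sum(w * X[i, ]) + b)
      w <- (1 - eta * lambda) * w
      if (margin < 1) {
        w <- w + eta * yy[i] * X[i, ]
        b <- b + eta * yy[i] * 0.1
      }
    }
  }
  structure(list(w = w, b = b), class = "tp_svm")
}
.predict_svm <- function(model, X)
  as.numeric(stats::plogis(X %*% model$w + model$b))

# distance-weighted k-NN neighbour fraction
.fit_knn <- function(X, y, seed, k = 5L) {
  structure(list(X = X, y = y, k = as.integer(min(k, nrow(X)))),
            class = "tp_knn")
}
.predict_knn <- function(model, X) {
  nn <- FNN::get.knnx(model$X, X, k = model$k)
  w <- 1 / (nn$nn.dist + 1e-6)
  lab <- matrix(model$y[nn$nn.index], nrow = nrow(X))
  as.numeric(rowSums(w * lab) / rowSums(w))
}

.ALGORITHMS <- list(
  random_forest = list(fit = .fit_rf, predict = .predict_rf),
  svm = list(fit = .fit_svm, predict = .predict_svm),
  knn = list(fit = .fit_knn, predict = .predict_knn))

#' Enumerate the six descriptor-set x algorithm model specifications
#' @param seed base seed; each spec gets a distinct derived seed
#' @return list of specs (descriptor_set, algorithm, seed)
#' @export
model_specs <- function(seed = 1L) {
  specs <- list()
  i <- 0L
  for (ds in c("setA", "setB")) for (alg in names(.ALGORITHMS)) {
    i <- i + 1L
    specs[[i]] <- list(descriptor_set = ds, algorithm = alg,
                       seed = as.integer(seed + i))
  }
  specs
}

#' Train the six-model consensus QSAR bundle
#'
#' Fits a [0,1] range scaler per descriptor set on the modeling data only,
#' trains RF, linear SVM and k-NN on each scaled set, and retains the
#' scaled modeling matrices for applicability-domain checks.
#'
#' @param descriptors named list `list(setA = X, setB = X)` of modeling-set
#'   descriptor matrices (rows aligned, named by compound)
#' @param y 0/1 vector of modeling-set labels
#' @param specs model specifications from [model_specs()]
#' @param ad_k,ad_z applicability-domain parameters (k nearest modeling
#'   neighbours; cutoff D-bar + z * s)
#' @return object of class `consensus_model`
#' @export
train_consensus <- function(descriptors, y, specs = model_specs(),
                            ad_k = 5L, ad_z = 0.5) {
  stopifnot(is.list(descriptors), all(c("setA", "setB") %in% names(descriptors)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  scalers <- lapply(descriptors, fit_range_scaler)
  scaled <- mapply(function(sc, X) apply_range_scaler(sc, X),
                   scalers, descriptors, SIMPLIFY = FALSE)
  models <- lapply(specs, function(sp) {
    alg <- .ALGORITHMS[[sp$algorithm]]
    X <- scaled[[sp$descriptor_set]]
    list(spec = sp, fit = alg$fit(X, y, sp$seed))
  })
  ad_ref <- do.call(cbind, scaled)
  ad <- .fit_ad(ad_ref, k = ad_k, z = ad_z)
  structure(list(scalers = scalers, models = models, y = y,
                 scaled_training = scaled, ad = ad),
            class = "consensus_model")
}

# AD reference: distribution of mean distance to k nearest neighbours
# (self excluded) over the modeling set
.fit_ad <- function(X, k = 5L, z = 0.5) {
  k <- as.integer(min(k, nrow(X) - 1L))
  nn <- FNN::get.knn(X, k = k)
  d <- rowMeans(nn$nn.dist)
  list(X = X, k = k, z = z, dbar = mean(d), s = stats::sd(d))
}

#' Applicability-domain check for query descriptor rows
#'
#' A query is in-domain iff its mean Euclidean distance to its k nearest
#' modeling-set neighbours is at most D-bar + z * s, where D-bar and s
#' summarize the same quantity (self-excluded) over the modeling set.
#'
#' @param bundle a `consensus_model`
#' @param descriptors named list `list(setA=, setB=)` of query matrices
#' @param z optional override of the trained z cutoff
#' @return logical vector, one entry per query row
#' @export
ad_check <- function(bundle, descriptors, z = NULL) {
  stopifnot(inherits(bundle, "consensus_model"))
  scaled <- mapply(function(sc, X) apply_range_scaler(sc, X),
                   bundle$scalers, descriptors[names(bundle$scalers)],
                   SIMPLIFY = FALSE)
  Q <- do.call(cbind, scaled)
  ad <- bundle$ad
  if (is.null(z)) z <- ad$z
  nn <- FNN::get.knnx(ad$X, Q, k = ad$k)
  rowMeans(nn$nn.dist) <= ad$dbar + z * ad$s
}

#' Fraction of a query set inside the applicability domain
#' @param in_ad logical vector from [ad_check()]
#' @return scalar coverage in [0,1]
#' @export
coverage <- function(in_ad) mean(in_ad)

#' Classify a consensus score under both consensus prediction thresholds
#'
#' CPT-1: score >= 0.5 active, < 0.5 inactive. CPT-2: >= 0.8 active,
#' <= 0.3 inactive, the open band (0.3, 0.8) inconclusive.
#'
#' @param score numeric vector in [0,1]
#' @return data.frame with `class_cpt1` and `class_cpt2`
#' @export
cpt_classify <- function(score) {
  if (any(score < 0 | score > 1 | is.na(score)))
    stop("consensus scores must lie in [0,1]")
  data.frame(
    class_cpt1 = ifelse(score >= 0.5, "active", "inactive"),
    class_cpt2 = ifelse(score >= 0.8, "active",
                        ifelse(score <= 0.3, "inactive", "inconclusive")),
    stringsAsFactors = FALSE)
}

#' Predict with the consensus bundle
#'
#' @param bundle a `consensus_model`
#' @param descriptors named list `list(setA=, setB=)` of query matrices
#' @return data.frame: `compound_id`, per-model scores, `score` (consensus
#'   mean), `class_cpt1`, `class_cpt2`, `in_ad`
#' @export
predict_consensus <- function(bundle, descriptors) {
  stopifnot(inherits(bundle, "consensus_model"))
  scaled <- mapply(function(sc, X) apply_range_scaler(sc, X),
                   bundle$scalers, descriptors[names(bundle$scalers)],
                   SIMPLIFY = FALSE)
  indiv <- vapply(bundle$models, function(m) {
    alg <- .ALGORITHMS[[m$spec$algorithm]]
    alg$predict(m$fit, scaled[[m$spec$descriptor_set]])
  }, numeric(nrow(scaled$setA)))
  indiv <- matrix(indiv, nrow = nrow(scaled$setA))
  colnames(indiv) <- vapply(bundle$models, function(m)
    paste0(m$spec$descriptor_set, "_", m$spec$algorithm), "")
  score <- pmin(pmax(rowMeans(indiv), 0), 1)
  out <- cbind(
    data.frame(compound_id = rownames(descriptors$setA) %||%
                 as.character(seq_along(score)),
               stringsAsFactors = FALSE),
    as.data.frame(indiv),
    score = score,
    cpt_classify(score),
    in_ad = ad_check(bundle, descriptors))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# classification metrics of definite predictions against 0/1 truth
.cv_metrics <- function(pred_class, truth) {
  definite <- pred_class != "inconclusive"
  cov <- mean(definite)
  p <- pred_class[definite]; t <- truth[definite]
  TP <- sum(p == "active" & t == 1); FN <- sum(p == "inactive" & t == 1)
  TN <- sum(p == "inactive" & t == 0); FP <- sum(p == "active" & t == 0)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  c(sensitivity = sens, specificity = spec,
    ccr = (sens + spec) / 2, coverage = cov)
}

#' Stratified 5-fold external cross-validation of the consensus model
#'
#' Splits 80/20 with class stratification; inside each fold the similarity
#' down-sampler, the descriptor scalers and all six models are re-fit on
#' the training portion only. Metrics are reported per fold and CPT, with
#' and without the applicability domain.
#'
#' @param descriptors named list `list(setA=, setB=)` over all compounds
#' @param y 0/1 labels
#' @param folds number of folds (default 5)
#' @param seed RNG seed for fold assignment
#' @param ratio down-sampling ratio, as [downsample()]
#' @param specs_seed base seed for [model_specs()]
#' @param ad_k,ad_z applicability-domain parameters
#' @return data.frame: fold, cpt, ad, sensitivity, specificity, ccr,
#'   coverage, n_test
#' @export
external_cv <- function(descriptors, y, folds = 5L, seed = 1L,
                        ratio = 750 / 800, specs_seed = 100L,
                        ad_k = 5L, ad_z = 0.5) {
  y <- as.integer(y)
  n <- length(y)
  stopifnot(nrow(descriptors$setA) == n, nrow(descriptors$setB) == n)
  if (sum(y == 1) < folds || sum(y == 0) < folds)
    stop("need at least `folds` compounds per class for stratification")
  ids <- rownames(descriptors$setA) %||% as.character(seq_len(n))
  rownames(descriptors$setA) <- ids; rownames(descriptors$setB) <- ids
  fold_of <- integer(n)
  .with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  rows <- list()
  for (f in seq_len(folds)) {
    tr <- fold_of != f; te <- !tr
    act <- ids[tr & y == 1L]; inact <- ids[tr & y == 0L]
    sim <- similarity_from_descriptors(
      descriptors$setA[act, , drop = FALSE],
      descriptors$setA[inact, , drop = FALSE])
    ds <- suppressWarnings(downsample(act, inact, sim, ratio = ratio))
    mids <- ds$modeling_ids
    bundle <- train_consensus(
      list(setA = descriptors$setA[mids, , drop = FALSE],
           setB = descriptors$setB[mids, , drop = FALSE]),
      y[match(mids, ids)],
      specs = model_specs(specs_seed + f), ad_k = ad_k, ad_z = ad_z)
    pred <- predict_consensus(
      bundle, list(setA = descriptors$setA[te, , drop = FALSE],
                   setB = descriptors$setB[te, , drop = FALSE]))
    truth <- y[te]
    for (cpt in c("cpt1", "cpt2")) {
      cls <- pred[[paste0("class_", cpt)]]
      for (ad in c(FALSE, TRUE)) {
        keep <- if (ad) pred$in_ad else rep(TRUE, nrow(pred))
        m <- .cv_metrics(cls[keep], truth[keep])
        if (ad) m[["coverage"]] <- m[["coverage"]] * mean(pred$in_ad)
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, cpt = toupper(sub("cpt", "CPT-", cpt)), ad = ad,
          sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
          ccr = m[["ccr"]], coverage = m[["coverage"]],
          n_test = sum(te), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
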