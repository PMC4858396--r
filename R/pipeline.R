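# ---------------------------------------------------------------------------
# Three-stage workflow orchestration: (1) automated biological response
# profiling, (2) consensus QSAR modeling of ARE activation with gap-filling
# of untested compounds, (3) chemical IVIVC evaluation over toxicophore
# subsets.  Driven by a single JSON config; every stage writes its outputs
# before the next starts and contributes to a machine-readable run report.
# ---------------------------------------------------------------------------

#' Default pipeline run configuration
#'
#' @param out_dir directory all outputs are written into
#' @param seed master RNG seed
#' @return nested list of class `run_config`; every tunable carries its
#'   documented default (noise threshold 10, RA cut 0.25, CPT bounds
#'   0.5 / 0.8 / 0.3, AD k = 5 z = 0.5, 5 CV folds)
#' @export
default_run_config <- function(out_dir = tempfile("toxprofiler_run_"),
                               seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, curves = TRUE, curate = TRUE,
                  profile = TRUE, qsar = TRUE, toxicophore = TRUE),
    simulation = list(n_compounds = 400L, n_assays = 24L,
                      n_relevant_assays = 4L, association_odds = 8,
                      missing_rate = 0.3, curve_noise_sd = 5),
    curves = list(noise_threshold = 10),
    profile = list(ra_threshold = 0.25),
    qsar = list(ratio = 750 / 800, ad_k = 5L, ad_z = 0.5, folds = 5L),
    toxicophore = list(min_support = 5L, top_fragments = 3L),
    inputs = list(smi = NULL, curves_csv = NULL, assay_matrix_csv = NULL,
                  labels_csv = NULL)), class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param path JSON file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config()
  merge_into <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
        merge_into(base[[k]], upd[[k]]) else upd[[k]]
    }
    base
  }
  out <- merge_into(unclass(base), cfg)
  structure(out, class = "run_config")
}

#' @rdname read_run_config
#' @param config a `run_config`
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# stable fingerprint of the scientific config (paths and timestamps
# excluded, so equal runs in different directories fingerprint identically)
.config_fingerprint <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$inputs <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", .hash_string(as.character(s), .Machine$integer.max))
}

# map a per-compound activity category to the call encoding of the assay
# matrix (definite active/inactive only; everything else inconclusive)
.category_to_call <- function(category) {
  ifelse(category == "active", 1L,
         ifelse(category == "inactive", 0L, -1L))
}

#' Run the full profiling pipeline
#'
#' Stage order: synthetic-data generation (optional; real input files can
#' be supplied instead via `config$inputs`), curve processing, structure
#' curation, biological response profiling, consensus QSAR gap-filling of
#' compounds without experimental ARE calls, and toxicophore IVIVC
#' evaluation. Each stage's outputs are written to `config$out_dir` before
#' the next stage starts; any error aborts with a stage-tagged message.
#'
#' @param config a `run_config` (or path to a JSON config)
#' @return the run report (list of class `run_report`), also written to
#'   `run_report.json`
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config_fingerprint = .config_fingerprint(config),
                 stages = list())
  stage <- function(name, expr) {
    if (!isTRUE(config$stages[[name]])) {
      report$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- c(list(status = "completed",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 2)),
                                res$summary)
    res$value
  }
  op <- function(...) file.path(config$out_dir, paste0(...))

  # -- stage: simulate ------------------------------------------------------
  sim <- stage("simulate", {
    sc <- do.call(sim_config, c(config$simulation, list(seed = config$seed)))
    lib <- generate_library(sc)
    curves <- generate_curves(lib, sc)
    am <- generate_assay_matrix(lib, sc)
    write_smi(lib, op("library.smi"))
    write_sdf(lib, op("library.sdf"))
    write_curves_csv(curves, op("curves.csv"))
    write_assay_matrix_csv(am, op("assay_matrix.csv"), op("assay_metadata.csv"))
    write_labels_csv(lib, op("labels.csv"))
    list(value = list(lib = lib, curves = curves, am = am, sc = sc),
         summary = list(n_compounds = nrow(lib),
                        n_assays = ncol(am$calls)))
  })

  smiles <- NULL; labels <- NULL; curves_df <- NULL; am <- NULL
  if (!is.null(sim)) {
    smiles <- stats::setNames(sim$lib$smiles, sim$lib$compound_id)
    labels <- stats::setNames(as.integer(sim$lib$is_liver_toxic),
                              sim$lib$compound_id)
    curves_df <- sim$curves
    am <- sim$am
  } else {
    if (!is.null(config$inputs$smi)) {
      if (!file.exists(config$inputs$smi))
        stop("stage [inputs] failed: missing file: ", config$inputs$smi,
             call. = FALSE)
      tab <- utils::read.table(config$inputs$smi, sep = "\t",
                               col.names = c("smiles", "compound_id"),
                               stringsAsFactors = FALSE)
      smiles <- stats::setNames(tab$smiles, tab$compound_id)
    }
    if (!is.null(config$inputs$labels_csv)) {
      lt <- utils::read.csv(config$inputs$labels_csv)
      labels <- stats::setNames(as.integer(lt$liver_damage), lt$compound_id)
    }
    if (!is.null(config$inputs$curves_csv))
      curves_df <- utils::read.csv(config$inputs$curves_csv,
                                   stringsAsFactors = FALSE)
    if (!is.null(config$inputs$assay_matrix_csv))
      am <- read_assay_matrix_csv(config$inputs$assay_matrix_csv)
  }

  # -- stage: curves --------------------------------------------------------
  are_calls <- stage("curves", {
    if (is.null(curves_df)) stop("no curve data available")
    calls <- process_curves(curves_df, config$curves$noise_threshold)
    utils::write.csv(calls, op("are_calls.csv"), row.names = FALSE)
    list(value = calls,
         summary = list(n_compounds = nrow(calls),
                        n_active = sum(calls$category == "active"),
                        n_inactive = sum(calls$category == "inactive")))
  })

  # -- stage: curate --------------------------------------------------------
  curated <- stage("curate", {
    if (is.null(smiles)) stop("no structures available")
    cl <- curate_library(smiles, ids = names(smiles))
    utils::write.csv(cl$curated, op("curated.csv"), row.names = FALSE)
    utils::write.csv(cl$rejected, op("rejected.csv"), row.names = FALSE)
    list(value = cl,
         summary = list(n_curated = nrow(cl$curated),
                        n_rejected = nrow(cl$rejected)))
  })

  # -- stage: profile -------------------------------------------------------
  profile <- stage("profile", {
    if (is.null(am) || is.null(labels)) stop("no assay matrix or labels")
    ids <- intersect(rownames(am$calls), names(labels))
    half <- seq_along(ids) %% 2L == 1L     # two probe groups, split halves
    bp <- build_profile(am, labels[ids[half]], labels[ids[!half]],
                        ra_threshold = config$profile$ra_threshold,
                        ra_labels = labels)
    utils::write.csv(assay_stats_table(bp$stats_a, bp$selected),
                     op("assay_stats_groupA.csv"), row.names = FALSE)
    utils::write.csv(assay_stats_table(bp$stats_b, bp$selected),
                     op("assay_stats_groupB.csv"), row.names = FALSE)
    if (!is.null(bp$ra))
      utils::write.csv(bp$ra, op("ra.csv"), row.names = FALSE)
    if (!is.null(bp$profile_table))
      utils::write.csv(bp$profile_table, op("profile_matrix.csv"))
    list(value = bp,
         summary = list(n_selected_assays = length(bp$selected),
                        selected = as.list(bp$selected),
                        ivivc_chi2_p = if (!is.null(bp$ivivc)) bp$ivivc$p else NA))
  })

  # -- stage: qsar (gap filling) -------------------------------------------
  qsar <- stage("qsar", {
    if (is.null(smiles) || is.null(are_calls)) stop("need structures and ARE calls")
    exp_call <- stats::setNames(.category_to_call(are_calls$category),
                                are_calls$compound_id)
    train_ids <- names(exp_call)[exp_call %in% c(0L, 1L)]
    train_ids <- intersect(train_ids, names(smiles))
    y <- as.integer(exp_call[train_ids] == 1L)
    if (length(unique(y)) < 2L) stop("single-class training data")
    descA <- descriptor_matrix(smiles[train_ids], "const", train_ids)
    descB <- descriptor_matrix(smiles[train_ids], "circ", train_ids)
    act <- train_ids[y == 1L]; inact <- train_ids[y == 0L]
    fps <- do.call(rbind, lapply(smiles[train_ids], circular_fingerprint))
    rownames(fps) <- train_ids
    sim_mat <- tanimoto(fps[act, , drop = FALSE], fps[inact, , drop = FALSE])
    ds <- suppressWarnings(downsample(act, inact, sim_mat,
                                      ratio = config$qsar$ratio))
    mids <- ds$modeling_ids
    bundle <- train_consensus(
      list(setA = descA[mids, , drop = FALSE],
           setB = descB[mids, , drop = FALSE]),
      as.integer(exp_call[mids] == 1L),
      specs = model_specs(config$seed + 10L),
      ad_k = config$qsar$ad_k, ad_z = config$qsar$ad_z)
    query_ids <- setdiff(names(smiles), train_ids)
    gap <- NULL
    if (length(query_ids)) {
      qA <- descriptor_matrix(smiles[query_ids], "const", query_ids)
      qB <- descriptor_matrix(smiles[query_ids], "circ", query_ids)
      gap <- predict_consensus(bundle, list(setA = qA, setB = qB))
      utils::write.csv(gap, op("qsar_predictions.csv"), row.names = FALSE)
    }
    # gap-filled call vector: experimental wins; out-of-AD predictions are
    # used but flagged low-confidence
    filled <- exp_call
    src <- stats::setNames(rep("experimental", length(filled)), names(filled))
    if (!is.null(gap)) {
      add <- stats::setNames(ifelse(gap$class_cpt1 == "active", 1L, 0L),
                             gap$compound_id)
      filled <- c(filled[!(names(filled) %in% names(add))], add)
      src[gap$compound_id] <- ifelse(gap$in_ad, "predicted",
                                     "predicted_low_confidence")
    }
    utils::write.csv(
      data.frame(compound_id = names(filled), call = as.integer(filled),
                 source = src[names(filled)], row.names = NULL),
      op("are_calls_gapfilled.csv"), row.names = FALSE)
    list(value = list(bundle = bundle, filled = filled, source = src,
                      downsample = ds),
         summary = list(n_modeling = length(mids),
                        n_active_modeling = ds$n_active,
                        n_predicted = length(query_ids),
                        qsar_coverage = if (!is.null(gap)) mean(gap$in_ad) else NA))
  })

  # -- stage: toxicophore ---------------------------------------------------
  stage("toxicophore", {
    if (is.null(smiles) || is.null(labels)) stop("need structures and labels")
    calls <- if (!is.null(qsar)) qsar$filled else {
      if (is.null(are_calls)) stop("no in vitro calls available")
      stats::setNames(.category_to_call(are_calls$category),
                      are_calls$compound_id)
    }
    src <- if (!is.null(qsar)) "predicted" else "experimental"
    ids <- intersect(names(smiles), intersect(names(calls), names(labels)))
    dual <- stats::setNames(calls[ids] == 1L & labels[ids] == 1L, ids)
    ranking <- rank_fragments(smiles[ids], dual,
                              min_support = config$toxicophore$min_support)
    utils::write.csv(ranking, op("fragment_ranking.csv"), row.names = FALSE)
    top <- utils::head(ranking, config$toxicophore$top_fragments)
    rows <- list()
    for (i in seq_len(nrow(top))) {
      matched <- attr(ranking, "matches")[[top$fragment_id[i]]]
      fi <- tryCatch(
        fragment_ivivc(matched, calls[ids], labels[ids],
                       source = if (src == "predicted" &&
                                    any(qsar$source[matched] != "experimental"))
                         "predicted" else "experimental"),
        error = function(e) NULL)
      if (!is.null(fi))
        rows[[length(rows) + 1L]] <- fragment_ivivc_row(top$fragment_id[i], fi)
    }
    ivivc_tab <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(ivivc_tab))
      utils::write.csv(ivivc_tab, op("fragment_ivivc.csv"), row.names = FALSE)
    list(value = ivivc_tab,
         summary = list(n_fragments_ranked = nrow(ranking),
                        top_fragment = if (nrow(top)) top$pattern[1] else NA))
  })

  report$stages <- report$stages[!vapply(report$stages, is.null, TRUE)]
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  class(report) <- "run_report"
  report
}
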