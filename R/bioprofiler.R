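# ---------------------------------------------------------------------------
# Bioassay profile mining: per-assay confusion statistics against a binary
# in vivo endpoint (sensitivity, specificity, CCR, the likelihood parameter
# L), the four-criterion assay selection, the per-compound rate of actives
# (RA), and the Pearson chi-squared IVIVC test.
#
# Assay calls are encoded as in the assay matrix: 1 = active, 0 = inactive,
# -1 = inconclusive, NA = untested.  Only definite calls (1/0) ever enter a
# statistic.
# ---------------------------------------------------------------------------

#' Confusion counts of one assay against a binary endpoint
#'
#' Compounds contribute only when they have a definite assay call (active or
#' inactive) and a label; inconclusive and untested calls are excluded.
#'
#' @param assay_calls named integer vector (1/0/-1/NA), names = compound ids
#' @param endpoint_labels named 0/1 vector (or logical), names = compound ids
#' @return list with `TP`, `TN`, `FP`, `FN`
#' @export
confusion <- function(assay_calls, endpoint_labels) {
  shared <- intersect(names(assay_calls), names(endpoint_labels))
  if (!length(shared))
    stop("no overlapping compounds between assay calls and endpoint labels")
  a <- assay_calls[shared]
  y <- as.integer(endpoint_labels[shared])
  keep <- !is.na(a) & a %in% c(0L, 1L) & !is.na(y)
  a <- a[keep]; y <- y[keep]
  list(TP = sum(a == 1L & y == 1L), TN = sum(a == 0L & y == 0L),
       FP = sum(a == 1L & y == 0L), FN = sum(a == 0L & y == 1L))
}

#' Assay quality statistics: sensitivity, specificity, CCR and L
#'
#' CCR is the mean of sensitivity and specificity (stored as a fraction;
#' multiply by 100 for display). The likelihood parameter is
#' L = sensitivity x (FP + TP) / (FP + 1) and indicates how strongly an
#' assay's active calls track the endpoint. When a class is absent
#' (TP + FN = 0 or TN + FP = 0) the undefined statistics are NA and
#' `defined` is FALSE, which excludes the assay from selection.
#'
#' @param cm confusion list from [confusion()], or an object with
#'   TP/TN/FP/FN fields
#' @return object of class `assay_stats`
#' @export
assay_stats <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  ccr <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  L <- if (!is.na(sens)) sens * (FP + TP) / (FP + 1) else NA_real_
  chi <- tryCatch(pearson_chi2(matrix(c(TP, FN, FP, TN), 2, 2)),
                  error = function(e) list(statistic = NA_real_, p = NA_real_))
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 sensitivity = sens, specificity = spec, ccr = ccr, L = L,
                 chi2_stat = chi$statistic, chi2_p = chi$p,
                 n_matching_actives = TP,
                 defined = !is.na(ccr)),
            class = "assay_stats")
}

#' @rdname assay_stats
#' @param stats an `assay_stats`
#' @return `ccr()`: the CCR as a fraction; `likelihood_param()`: L
#' @export
ccr <- function(stats) stats$ccr

#' @rdname assay_stats
#' @export
likelihood_param <- function(stats) stats$L

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Plain Pearson statistic (no continuity correction by default) with the
#' expected counts derived from the margins; p from the chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param table 2x2 numeric matrix of non-negative counts
#' @param correct apply the Yates continuity correction (default FALSE)
#' @return list with `statistic`, `p`, `df`
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("negative cell count")
  n <- sum(table)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: a margin is zero")
  E <- outer(rs, cs) / n
  d <- abs(table - E)
  if (correct) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / E)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Score every assay of a matrix against one endpoint
#'
#' @param am an `assay_matrix` (or bare calls matrix)
#' @param endpoint_labels named 0/1 vector
#' @return named list of `assay_stats`, one per assay
#' @export
profile_assays <- function(am, endpoint_labels) {
  calls <- if (inherits(am, "assay_matrix")) am$calls else am
  out <- lapply(colnames(calls), function(aid) {
    v <- calls[, aid]; names(v) <- rownames(calls)
    cm <- tryCatch(confusion(v, endpoint_labels), error = function(e) NULL)
    if (is.null(cm)) return(NULL)
    assay_stats(cm)
  })
  names(out) <- colnames(calls)
  out[!vapply(out, is.null, TRUE)]
}

#' Select assays by the four profile criteria
#'
#' An assay is selected when it (a) appears in both profile groups, (b) has
#' more than `min_matching_actives` active responses matching the input
#' (TP > 10) in each, (c) correlates better than random in each (CCR > 0.5
#' and L >= 1), and (d) is an in vitro assay. Returned in deterministic
#' order: descending mean CCR, ties by assay id.
#'
#' @param stats_a,stats_b named lists of `assay_stats` (two profile groups)
#' @param metadata data.frame with `assay_id` and `in_vitro`
#' @param min_matching_actives strict lower bound for criterion (b)
#' @return character vector of selected assay ids (possibly empty)
#' @export
select_assays <- function(stats_a, stats_b, metadata,
                          min_matching_actives = 10L) {
  both <- intersect(names(stats_a), names(stats_b))
  iv <- metadata$assay_id[as.logical(metadata$in_vitro)]
  ok <- vapply(both, function(aid) {
    sa <- stats_a[[aid]]; sb <- stats_b[[aid]]
    if (!isTRUE(sa$defined) || !isTRUE(sb$defined)) return(FALSE)
    sa$n_matching_actives > min_matching_actives &&
      sb$n_matching_actives > min_matching_actives &&
      sa$ccr > 0.5 && sb$ccr > 0.5 && sa$L >= 1 && sb$L >= 1 &&
      aid %in% iv
  }, TRUE)
  sel <- both[ok]
  if (!length(sel)) return(character(0))
  mean_ccr <- vapply(sel, function(aid)
    (stats_a[[aid]]$ccr + stats_b[[aid]]$ccr) / 2, 1.0)
  sel[order(-mean_ccr, sel)]
}

#' Rate of actives (RA) for one compound over the selected assays
#'
#' RA = A / (A + I), where A and I count definite active and inactive
#' responses; untested and inconclusive responses are excluded from both
#' numerator and denominator, so missing data never bias the rate. A
#' compound is called toxic when RA > `threshold` (strict), nontoxic when
#' RA <= threshold, and no_data when it has no definite response.
#'
#' @param compound_row integer vector of calls (1/0/-1/NA) over the
#'   selected assays
#' @param threshold toxicity cut on RA (default 0.25)
#' @return object of class `ra_result`: `A`, `I`, `ra` (NA when undefined),
#'   `call` in \{"toxic", "nontoxic", "no_data"\}
#' @export
rate_of_actives <- function(compound_row, threshold = 0.25) {
  A <- sum(compound_row == 1L, na.rm = TRUE)
  I <- sum(compound_row == 0L, na.rm = TRUE)
  if (A + I == 0L) {
    return(structure(list(A = A, I = I, ra = NA_real_, call = "no_data"),
                     class = "ra_result"))
  }
  ra <- A / (A + I)
  structure(list(A = A, I = I, ra = ra,
                 call = if (ra > threshold) "toxic" else "nontoxic"),
            class = "ra_result")
}

#' Build the biological response profile for two labeled probe sets
#'
#' Runs [profile_assays()] for each probe group, applies [select_assays()],
#' computes RA per compound over the selected assays, and assembles a
#' heatmap-ready profile table (one row per compound with at least one
#' definite call, ordered by descending RA).
#'
#' @param am an `assay_matrix`
#' @param labels_a,labels_b named 0/1 endpoint vectors for the two probe
#'   groups
#' @param ra_threshold RA toxicity cut (default 0.25)
#' @param ra_labels labels used for the RA-based IVIVC chi-squared test;
#'   defaults to `labels_b`
#' @return list of class `bio_profile`: `stats_a`, `stats_b` (per-assay
#'   stats), `selected` (assay ids), `ra` (data.frame compound_id, A, I,
#'   ra, call), `profile_table` (calls over selected assays + ra + label),
#'   `ivivc` (chi-squared of RA call vs label, or NULL when degenerate)
#' @export
build_profile <- function(am, labels_a, labels_b, ra_threshold = 0.25,
                          ra_labels = labels_b) {
  stopifnot(inherits(am, "assay_matrix"))
  if (!length(labels_a) || !length(labels_b)) stop("empty probe set")
  stats_a <- profile_assays(am, labels_a)
  stats_b <- profile_assays(am, labels_b)
  selected <- select_assays(stats_a, stats_b, am$metadata)
  ra_df <- NULL; profile_table <- NULL; ivivc <- NULL
  if (length(selected)) {
    sub <- am$calls[, selected, drop = FALSE]
    ras <- lapply(seq_len(nrow(sub)), function(i)
      rate_of_actives(sub[i, ], ra_threshold))
    ra_df <- data.frame(
      compound_id = rownames(sub),
      A = vapply(ras, function(x) x$A, 1L),
      I = vapply(ras, function(x) x$I, 1L),
      ra = vapply(ras, function(x) x$ra, 1.0),
      call = vapply(ras, function(x) x$call, ""),
      stringsAsFactors = FALSE)
    with_data <- ra_df$call != "no_data"
    lab <- ra_labels[ra_df$compound_id]
    profile_table <- cbind(
      as.data.frame(sub),
      ra = ra_df$ra,
      endpoint = as.integer(lab))[with_data, , drop = FALSE]
    profile_table <- profile_table[order(-profile_table$ra), , drop = FALSE]
    tab_ok <- with_data & !is.na(lab)
    if (any(tab_ok)) {
      tab <- table(factor(ra_df$call[tab_ok] == "toxic", c(TRUE, FALSE)),
                   factor(lab[tab_ok] == 1, c(TRUE, FALSE)))
      ivivc <- tryCatch(pearson_chi2(unclass(tab)), error = function(e) NULL)
    }
  }
  structure(list(stats_a = stats_a, stats_b = stats_b, selected = selected,
                 ra = ra_df, profile_table = profile_table, ivivc = ivivc),
            class = "bio_profile")
}

#' Export per-assay statistics as a data.frame (CCR formatted as percent)
#' @param stats named list of `assay_stats`
#' @param selected assay ids marked as selected
#' @return data.frame, one row per assay
#' @export
assay_stats_table <- function(stats, selected = character(0)) {
  rows <- lapply(names(stats), function(aid) {
    s <- stats[[aid]]
    data.frame(assay_id = aid, TP = s$TP, TN = s$TN, FP = s$FP, FN = s$FN,
               sensitivity = s$sensitivity, specificity = s$specificity,
               ccr_pct = 100 * s$ccr, L = s$L, chi2_p = s$chi2_p,
               selected = aid %in% selected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
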