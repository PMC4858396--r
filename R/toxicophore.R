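# ---------------------------------------------------------------------------
# Toxicophore evaluation: substructure matching of candidate fragments,
# fragment-subset IVIVC (in vitro call vs in vivo label on the matched
# compounds), and a transparent, simplified enrichment ranking of circular
# fragments as a stand-in for commercial fragment-mining programs.
# ---------------------------------------------------------------------------

#' Fragment-subset in vitro - in vivo correlation
#'
#' Builds the 2x2 table of in vitro activity call against in vivo label
#' over the matched compounds that have definite values in both, and tests
#' independence with the Pearson chi-squared statistic.
#'
#' @param matched_ids compound ids carrying the fragment
#' @param invitro_calls named vector, 1 = active, 0 = inactive,
#'   -1 = inconclusive, NA = untested (inconclusive and untested are
#'   excluded from the table)
#' @param invivo_labels named 0/1 vector
#' @param source `"experimental"` or `"predicted"` -- recorded, not used
#' @return object of class `fragment_ivivc`: `n_matched`, `stats`
#'   (an [assay_stats()]), `source`, `n_indeterminate`
#' @export
fragment_ivivc <- function(matched_ids, invitro_calls, invivo_labels,
                           source = c("experimental", "predicted")) {
  source <- match.arg(source)
  if (!length(matched_ids)) stop("matched compound set is empty")
  calls <- invitro_calls[intersect(matched_ids, names(invitro_calls))]
  labs <- invivo_labels[intersect(matched_ids, names(invivo_labels))]
  cm <- confusion(calls, labs)
  st <- assay_stats(cm)
  definite <- cm$TP + cm$TN + cm$FP + cm$FN
  structure(list(n_matched = length(matched_ids), stats = st,
                 source = source,
                 n_indeterminate = length(matched_ids) - definite),
            class = "fragment_ivivc")
}

#' Rank circular fragments by enrichment in dual-active compounds
#'
#' Simplified, fully transparent stand-in for commercial fragment-mining
#' software: enumerates canonical circular fragments (radius <= `radius`)
#' over the library, keeps those carried by at least `min_support`
#' compounds, and scores each by the Haldane-Anscombe-corrected odds ratio
#' of occurrence in dual-active compounds (in vitro active AND in vivo
#' toxic) versus all others. Ranking uses the lower bound of the Wald 95%
#' confidence interval of the log odds ratio, which keeps rare fragments
#' with noisy, extreme point estimates from crowding out well-supported
#' enrichment. Ordered descending, ties broken by fragment id.
#'
#' @param smiles named character vector of structures (names = compound ids)
#' @param dual_activity_flags named logical vector: TRUE for dual-active
#' @param min_support minimum number of carriers; default
#'   `max(10, 2.5% of the library)`
#' @param radius circular fragment radius (default 2)
#' @return data.frame `fragment_id`, `pattern`, `provenance`, `n_dual`,
#'   `n_other`, `odds_ratio`, `score` (CI lower bound of the log OR), with
#'   attribute `matches`: named list of carrier compound ids per fragment.
#'   Empty (with a warning) when no fragment meets the support threshold.
#' @export
rank_fragments <- function(smiles, dual_activity_flags,
                           min_support = max(10L, ceiling(0.025 * length(smiles))),
                           radius = 2L) {
  ids <- names(smiles)
  stopifnot(!is.null(ids), all(ids %in% names(dual_activity_flags)))
  flags <- as.logical(dual_activity_flags[ids])
  if (length(unique(flags[!is.na(flags)])) < 2L) {
    warning("no contrast: all dual-activity flags identical")
    return(.empty_ranking())
  }
  frag_sets <- lapply(smiles, circular_fragments_memo, radius = radius)
  occ <- table(unlist(frag_sets))
  keep <- names(occ)[occ >= min_support]
  if (!length(keep)) {
    warning("no fragment meets min_support = ", min_support)
    return(.empty_ranking())
  }
  n_dual_tot <- sum(flags, na.rm = TRUE)
  n_other_tot <- sum(!flags, na.rm = TRUE)
  rows <- lapply(keep, function(fr) {
    carrier <- vapply(frag_sets, function(fs) fr %in% fs, TRUE)
    a <- sum(carrier & flags, na.rm = TRUE)        # dual-active carriers
    b <- sum(carrier & !flags, na.rm = TRUE)
    c_ <- n_dual_tot - a
    d <- n_other_tot - b
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (c_ + 0.5) + 1 / (d + 0.5))
    data.frame(fragment_id = fr,
               pattern = sub("^r[0-9]+:", "", fr),
               provenance = "enumerated", n_dual = a, n_other = b,
               odds_ratio = or, score = log(or) - 1.96 * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$fragment_id), , drop = FALSE]
  rownames(out) <- NULL
  matches <- lapply(out$fragment_id, function(fr)
    ids[vapply(frag_sets, function(fs) fr %in% fs, TRUE)])
  names(matches) <- out$fragment_id
  attr(out, "matches") <- matches
  out
}

.empty_ranking <- function() {
  out <- data.frame(fragment_id = character(0), pattern = character(0),
                    provenance = character(0), n_dual = integer(0),
                    n_other = integer(0), odds_ratio = numeric(0),
                    score = numeric(0))
  attr(out, "matches") <- list()
  out
}

#' Export a fragment IVIVC report row
#' @param fid fragment id
#' @param fi a `fragment_ivivc`
#' @return one-row data.frame mirroring the TP/TN/FP/FN panel layout
#' @export
fragment_ivivc_row <- function(fid, fi) {
  s <- fi$stats
  data.frame(fragment_id = fid, n_matched = fi$n_matched,
             TP = s$TP, TN = s$TN, FP = s$FP, FN = s$FN,
             sensitivity = s$sensitivity, specificity = s$specificity,
             ccr_pct = 100 * s$ccr, chi2_p = s$chi2_p,
             source = fi$source, stringsAsFactors = FALSE)
}
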