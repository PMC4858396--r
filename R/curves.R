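# ---------------------------------------------------------------------------
# qHTS concentration-response processing: range scaling, noise-filtered
# curve fingerprints with the CurveP scalar, four-level activity calls, and
# replicate aggregation.
# ---------------------------------------------------------------------------

#' Range-scale raw responses against plate controls
#'
#' Linear map sending the low control to 0 and the high control to 100.
#' Values outside [0, 100] are preserved (not clipped) so the downstream
#' noise filter sees them.
#'
#' @param raw_responses numeric vector, arbitrary units
#' @param low_control,high_control control values on the raw scale
#' @return numeric vector on the 0-100 scale
#' @export
range_scale <- function(raw_responses, low_control, high_control) {
  if (high_control == low_control)
    stop("degenerate scale: high_control equals low_control")
  100 * (raw_responses - low_control) / (high_control - low_control)
}

# Longest non-decreasing subsequence repair.  Kept points form a maximum
# non-decreasing subsequence; every other point is replaced by the value of
# the nearest kept point to its left (0 before the first kept point).
# Among maximum-length kept sets the one minimising the repaired sum is
# chosen, which flattens isolated spikes instead of propagating them.
.monotone_repair <- function(v) {
  n <- length(v)
  if (n == 0L) return(numeric(0))
  # f(i): best (length, repaired-sum) of a kept subsequence starting with i
  len <- integer(n); s <- numeric(n)
  for (i in n:1) {
    best_len <- 1L
    best_sum <- v[i] * (n + 1L - i)     # i is the last kept point
    for (j in (i + 1L):n) {
      if (j > n) break
      if (v[j] < v[i]) next
      cand_len <- 1L + len[j]
      cand_sum <- v[i] * (j - i) + s[j]
      if (cand_len > best_len ||
          (cand_len == best_len && cand_sum < best_sum)) {
        best_len <- cand_len; best_sum <- cand_sum
      }
    }
    len[i] <- best_len; s[i] <- best_sum
  }
  # choose the starting kept point (positions before it repair to 0)
  best_i <- 0L; best_len <- 0L; best_sum <- Inf
  for (i in seq_len(n)) {
    if (len[i] > best_len || (len[i] == best_len && s[i] < best_sum)) {
      best_i <- i; best_len <- len[i]; best_sum <- s[i]
    }
  }
  # reconstruct kept set
  kept <- integer(0); i <- best_i
  remaining <- best_len; cur_sum <- best_sum
  while (remaining > 0L) {
    kept <- c(kept, i)
    if (remaining == 1L) break
    nxt <- NA_integer_
    for (j in (i + 1L):n) {
      if (v[j] < v[i]) next
      if (len[j] == remaining - 1L &&
          isTRUE(all.equal(v[i] * (j - i) + s[j], cur_sum))) { nxt <- j; break }
    }
    if (is.na(nxt)) break   # defensive; cannot happen
    cur_sum <- cur_sum - v[i] * (nxt - i)
    i <- nxt; remaining <- remaining - 1L
  }
  out <- numeric(n)
  if (length(kept)) {
    prev_val <- 0
    ki <- 1L
    for (p in seq_len(n)) {
      if (ki <= length(kept) && p == kept[ki]) { prev_val <- v[p]; ki <- ki + 1L }
      out[p] <- prev_val
    }
  }
  out
}

#' Noise-filter a concentration-response curve into a fingerprint
#'
#' Two-step filter: (1) responses below `noise_threshold` are set to 0
#' (negative responses never survive -- the reporter signal is activation
#' only); (2) a monotone non-decreasing envelope is enforced by flattening
#' the minimal number of violating points, each replaced by the preceding
#' filtered value. The CurveP scalar is the sum of the filtered vector.
#'
#' @param responses numeric vector of range-scaled responses
#' @param concentrations optional molar concentrations; validated strictly
#'   ascending when supplied
#' @param noise_threshold response units; default 10, matching the
#'   "maximum response < 10" bound of the inactive category
#' @return object of class `curve_fingerprint`: list with
#'   `filtered_responses`, `curvep`, `max_response` and `n_responses_ge20`;
#'   both consistency criteria are computed on the filtered vector, so an
#'   isolated noise spike that the monotone repair removes leaves a fully
#'   inactive fingerprint
#' @export
curvep_filter <- function(responses, concentrations = NULL,
                          noise_threshold = 10) {
  stopifnot(is.numeric(responses), all(is.finite(responses)))
  if (!is.null(concentrations)) {
    if (length(concentrations) != length(responses))
      stop("concentrations and responses differ in length")
    if (any(diff(concentrations) <= 0))
      stop("concentrations must be strictly ascending")
  }
  v <- ifelse(responses >= noise_threshold, responses, 0)
  filt <- .monotone_repair(v)
  curve_fingerprint(filtered_responses = filt,
                    max_response = if (length(filt)) max(filt) else 0,
                    n_responses_ge20 = sum(filt >= 20))
}

#' Construct a curve fingerprint directly
#'
#' @param filtered_responses non-negative numeric vector
#' @param max_response pre-filter maximum response
#' @param n_responses_ge20 count of filtered responses >= 20; recomputed
#'   from `filtered_responses` when missing
#' @return a `curve_fingerprint`
#' @export
curve_fingerprint <- function(filtered_responses, max_response,
                              n_responses_ge20 = NULL) {
  stopifnot(all(filtered_responses >= 0))
  if (is.null(n_responses_ge20))
    n_responses_ge20 <- sum(filtered_responses >= 20)
  structure(list(filtered_responses = filtered_responses,
                 curvep = sum(filtered_responses),
                 max_response = max_response,
                 n_responses_ge20 = as.integer(n_responses_ge20)),
            class = "curve_fingerprint")
}

.CATEGORY_SCORE <- c(active = 1, potential_active = 0.75,
                     inconclusive = 0.25, inactive = 0)

#' Classify one replicate curve fingerprint into an activity category
#'
#' Four-rule cascade over (CurveP, maximum response, number of responses
#' >= 20): active (score 1) when CurveP > 0, max >= 20 and more than one
#' qualifying response; potential active (0.75) when exactly one; inactive
#' (0) when CurveP = 0 and max < 10; inconclusive (0.25, the catch-all for
#' inconsistent activation signals) otherwise.
#'
#' @param fp a `curve_fingerprint`
#' @return object of class `activity_call`: list with `category` and `score`
#' @export
classify_replicate <- function(fp) {
  stopifnot(inherits(fp, "curve_fingerprint"))
  cat <- if (fp$curvep > 0 && fp$max_response >= 20 && fp$n_responses_ge20 > 1L) {
    "active"
  } else if (fp$curvep > 0 && fp$max_response >= 20 && fp$n_responses_ge20 == 1L) {
    "potential_active"
  } else if (fp$curvep == 0 && fp$max_response < 10) {
    "inactive"
  } else "inconclusive"
  activity_call(cat)
}

#' Construct an activity call from a category name
#' @param category one of `"active"`, `"potential_active"`,
#'   `"inconclusive"`, `"inactive"`
#' @return an `activity_call` with the Table-2 score attached
#' @export
activity_call <- function(category) {
  category <- match.arg(category, names(.CATEGORY_SCORE))
  structure(list(category = category,
                 score = unname(.CATEGORY_SCORE[category])),
            class = "activity_call")
}

#' Aggregate replicate activity calls into one per-compound call
#'
#' Replicate scores are averaged and mapped to the nearest category score;
#' exact midpoints resolve toward the lower (less active) score.
#'
#' @param calls list of `activity_call` objects (>= 1)
#' @return an `activity_call`
#' @export
aggregate_compound <- function(calls) {
  if (!length(calls)) stop("no replicate calls to aggregate")
  scores <- vapply(calls, function(x) x$score, 1.0)
  m <- mean(scores)
  lv <- sort(unname(.CATEGORY_SCORE))        # 0, 0.25, 0.75, 1
  d <- abs(lv - m)
  # ties toward the smaller score: pick the first minimum in ascending order
  pick <- lv[which.min(d)]
  activity_call(names(.CATEGORY_SCORE)[match(pick, .CATEGORY_SCORE)])
}

#' Process a long-format curve table into per-compound activity calls
#'
#' Applies [curvep_filter()] and [classify_replicate()] to every replicate
#' and aggregates with [aggregate_compound()].
#'
#' @param curves data.frame as written by [generate_curves()] /
#'   [write_curves_csv()]: `compound_id`, `replicate`, `conc_index`,
#'   `concentration_M`, `response`
#' @param noise_threshold passed to [curvep_filter()]
#' @return data.frame: `compound_id`, `category`, `score`, `curvep_mean`
#' @export
process_curves <- function(curves, noise_threshold = 10) {
  need <- c("compound_id", "replicate", "conc_index", "response")
  stopifnot(all(need %in% names(curves)))
  curves <- curves[order(curves$compound_id, curves$replicate,
                         curves$conc_index), ]
  out <- lapply(split(curves, curves$compound_id), function(cc) {
    reps <- split(cc, cc$replicate)
    fps <- lapply(reps, function(r)
      curvep_filter(r$response, r$concentration_M, noise_threshold))
    calls <- lapply(fps, classify_replicate)
    agg <- aggregate_compound(calls)
    data.frame(compound_id = cc$compound_id[1],
               category = agg$category, score = agg$score,
               curvep_mean = mean(vapply(fps, function(f) f$curvep, 1.0)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
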