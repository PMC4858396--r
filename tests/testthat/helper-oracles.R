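# Independent oracles used across the suite.  Each is a deliberately naive
# re-derivation (closed form or exhaustive enumeration) of a quantity the
# package computes by its production path.

# textbook Pearson chi-squared for a 2x2 via the determinant closed form
oracle_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# exhaustive minimal monotone repair for short vectors: over all kept
# subsets forming a non-decreasing subsequence, maximize size then minimize
# the repaired sum (non-kept points take the preceding kept value, 0 before
# the first kept point)
oracle_monotone_repair <- function(v) {
  n <- length(v)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    kept <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(kept) && any(diff(v[kept]) < 0)) next
    out <- numeric(n); prev <- 0
    ki <- 1L
    for (p in seq_len(n)) {
      if (ki <= length(kept) && p == kept[ki]) { prev <- v[p]; ki <- ki + 1L }
      out[p] <- prev
    }
    cand <- list(k = length(kept), s = sum(out), out = out)
    if (is.null(best) || cand$k > best$k ||
        (cand$k == best$k && cand$s < best$s)) best <- cand
  }
  best$out
}

# small synthetic library shared by several tests
make_library <- function(n = 300, seed = 1, ...) {
  cfg <- sim_config(n_compounds = n, seed = seed, ...)
  list(cfg = cfg, lib = generate_library(cfg))
}

named_calls <- function(values, ids = sprintf("C%02d", seq_along(values))) {
  stats::setNames(as.integer(values), ids)
}
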