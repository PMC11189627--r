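#' Continuous Boyce index
#'
#' Measures how well predicted suitability ranks actual presences: the
#' suitability range is covered by `n_windows` overlapping windows of width
#' `window_fraction` of the range; in each window the predicted-to-expected
#' ratio `P/E` compares the fraction of test presences falling in the window
#' (P) with the fraction of evaluation-region cells falling in it (E). The
#' index is the Spearman rank correlation between `P/E` and the window
#' midpoints over windows with `E > 0`, ranging from -1 to 1. A high value
#' means presences concentrate in cells predicted suitable.
#'
#' Because the index is rank-based it is invariant under strictly monotone
#' transforms of suitability (so the raw/cloglog link choice is immaterial).
#' A result is flagged invalid when there are fewer than `min_presences`
#' (default 50) test presences, or when suitability is constant over the
#' evaluation region.
#'
#' @param suitability_eval suitability of every evaluation-region cell.
#' @param suitability_presence suitability at the test presences.
#' @param n_windows number of window midpoints, default 101.
#' @param window_fraction window width as a fraction of the suitability
#'   range, default 0.1.
#' @param min_presences validity floor on test presences, default 50.
#' @return object of class `boyce_result`: list with `bi`, `midpoints`,
#'   `pe` (P/E per retained window), `n_test_presences`, `valid`, `reason`.
#' @export
boyce_index <- function(suitability_eval, suitability_presence,
                        n_windows = 101, window_fraction = 0.1,
                        min_presences = 50) {
  n_pres <- length(suitability_presence)
  res <- function(bi, mids = numeric(0), pe = numeric(0), valid, reason = NA_character_) {
    structure(list(bi = bi, midpoints = mids, pe = pe,
                   n_test_presences = n_pres, valid = valid, reason = reason),
              class = "boyce_result")
  }
  if (n_pres == 0) return(res(NA_real_, valid = FALSE, reason = "no test presences"))
  lo <- min(suitability_eval); hi <- max(suitability_eval)
  if (hi <= lo) return(res(NA_real_, valid = FALSE, reason = "constant suitability"))
  width <- window_fraction * (hi - lo)
  mids <- seq(lo + width / 2, hi - width / 2, length.out = n_windows)
  P <- vapply(mids, function(m) {
    mean(suitability_presence >= m - width / 2 & suitability_presence <= m + width / 2)
  }, numeric(1))
  E <- vapply(mids, function(m) {
    mean(suitability_eval >= m - width / 2 & suitability_eval <= m + width / 2)
  }, numeric(1))
  keep <- E > 0
  if (sum(keep) < 3) return(res(NA_real_, valid = FALSE, reason = "too few populated windows"))
  bi <- suppressWarnings(stats::cor(P[keep] / E[keep], mids[keep],
                                    method = "spearman"))
  if (is.na(bi)) return(res(NA_real_, mids[keep], P[keep] / E[keep],
                            valid = FALSE, reason = "degenerate P/E profile"))
  valid <- n_pres >= min_presences
  res(bi, mids[keep], P[keep] / E[keep], valid = valid,
      reason = if (valid) NA_character_ else sprintf("fewer than %d test presences", min_presences))
}
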