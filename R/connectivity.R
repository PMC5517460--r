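# Channel-pair functional connectivity: Pearson and maximum lagged
# cross-correlation.

new_fc <- function(values, method, window, best_lag = NULL) {
  dimnames(values) <- list(rownames(window$data), rownames(window$data))
  structure(
    list(values = values, method = method, best_lag = best_lag,
         duration_s = window$duration_s, subject_id = window$subject_id,
         run_id = window$run_id),
    class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s | %d x %d | %g s | subject %s run %s\n",
              x$method, nrow(x$values), ncol(x$values), x$duration_s,
              x$subject_id, x$run_id))
  invisible(x)
}

check_window <- function(window) {
  if (inherits(window, "nirs_recording")) window <- as_window(window)
  stopifnot(inherits(window, "duration_window"))
  if (ncol(window$data) < 3) stop("window has fewer than 3 samples")
  v <- apply(window$data, 1, var)
  if (any(v == 0)) {
    stop("zero-variance channel(s): ",
         paste(rownames(window$data)[v == 0], collapse = ", "))
  }
  window
}

#' Pearson functional connectivity
#'
#' Sample Pearson correlation between every channel pair over the window.
#'
#' @param window A `duration_window` (or a full `nirs_recording`).
#' @return A `connectivity_matrix` with `method = "pearson"`.
#' @export
pearson_fc <- function(window) {
  window <- check_window(window)
  r <- cor(t(window$data))
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  new_fc(r, "pearson", window)
}

#' Maximum lagged cross-correlation functional connectivity
#'
#' For every channel pair, the Pearson correlation of the overlapping
#' segments is computed at every integer lag `d` in `[-L, +L]` samples
#' (`L = round(max_lag_s * fs)`), with means and variances recomputed on
#' the overlap; the connectivity value is the maximum over lags and
#' `best_lag` its argmax. Ties go to the smallest `|d|`, negative before
#' positive. The result is symmetric (`best_lag` antisymmetric), since lag
#' `-d` for pair (i, j) equals `+d` for (j, i). Lags whose overlap falls
#' below `min_overlap_frac` of the window are skipped.
#'
#' @param window A `duration_window` (or full `nirs_recording`).
#' @param max_lag_s Maximum absolute lag in seconds (default 20 s, a bound
#'   on physiological delays).
#' @param min_overlap_frac Minimum overlap fraction per lag (default 0.5).
#' @return A `connectivity_matrix` with `method = "crosscorr"` and integer
#'   `best_lag` in samples.
#' @export
crosscorr_fc <- function(window, max_lag_s = 20, min_overlap_frac = 0.5) {
  window <- check_window(window)
  X <- window$data
  ns <- ncol(X)
  fs <- window$sampling_rate_hz
  L <- as.integer(round(max_lag_s * fs))
  tX <- t(X)
  vals <- cor(tX)
  vals <- pmin(pmax(vals, -1), 1)
  if (L >= ns * (1 - min_overlap_frac) + 1) {
    warning("max_lag_s exceeds the usable lag range for this window; long lags will be skipped")
  }
  lags <- matrix(0L, nrow(X), nrow(X))
  if (L > 0) {
    for (l in seq_len(L)) {
      if ((ns - l) / ns < min_overlap_frac || ns - l < 3) next
      # M[i, j] = cor(x_i(t), x_j(t - l)) = r_ij(d = +l)
      M <- cor(tX[(1 + l):ns, , drop = FALSE], tX[1:(ns - l), , drop = FALSE])
      M <- pmin(pmax(M, -1), 1)
      for (cand in list(list(v = t(M), d = -l), list(v = M, d = l))) {
        better <- cand$v > vals
        vals[better] <- cand$v[better]
        lags[better] <- cand$d
      }
    }
  }
  diag(vals) <- 1
  diag(lags) <- 0L
  new_fc(vals, "crosscorr", window, best_lag = lags)
}
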