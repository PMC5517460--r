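# PCA + ICA decomposition and artifact-component rejection.
#
# The environment ships no ICA package, so FastICA (symmetric decorrelation,
# tanh contrast) is implemented here with a fixed internal seed and bounded
# restarts for reproducibility.

#' PCA + ICA decomposition of a recording
#'
#' Reduces the channel-by-time matrix with PCA to the smallest number of
#' components reaching `variance_retained`, then unmixes the reduced data
#' with FastICA. The returned mixing matrix maps sources back to channel
#' space: `mixing %*% sources + channel_means` reconstructs the PCA-retained
#' portion of the input.
#'
#' @param recording A `nirs_recording`.
#' @param variance_retained Fraction of variance the PCA stage must keep
#'   (default 0.99).
#' @param ica_seed Internal seed for the FastICA initialization.
#' @param max_iter,tol FastICA iteration cap and convergence tolerance.
#' @param max_restarts Restarts with fresh initializations before failing.
#' @return An object of class `component_decomposition` with `sources`
#'   (components x samples, unit variance), `mixing`
#'   (channels x components), `channel_means`, `criteria_flags` (NULL until
#'   [classify_components()]), `labels`, and recording metadata.
#' @export
decompose <- function(recording, variance_retained = 0.99, ica_seed = 42L,
                      max_iter = 500L, tol = 1e-4, max_restarts = 3L) {
  stopifnot(inherits(recording, "nirs_recording"),
            variance_retained > 0, variance_retained <= 1)
  X <- recording$data
  ns <- ncol(X)
  means <- rowMeans(X)
  Xc <- X - means
  sv <- svd(Xc, nu = nrow(X), nv = 0)
  ev <- sv$d^2
  frac <- cumsum(ev) / sum(ev)
  k <- which(frac >= variance_retained - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  d <- sv$d[seq_len(k)]
  if (any(d < sqrt(.Machine$double.eps) * sv$d[1])) {
    k <- sum(d >= sqrt(.Machine$double.eps) * sv$d[1])
    d <- sv$d[seq_len(k)]
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  # whitened reduced data: rows have unit variance, zero cross-covariance
  Z <- sqrt(ns - 1) * (t(U) %*% Xc) / d
  W <- fastica_symmetric(Z, ica_seed, max_iter, tol, max_restarts)
  S <- W %*% Z
  # least-squares mixing back to channel space
  A <- Xc %*% t(S) %*% solve(S %*% t(S))
  rownames(A) <- rownames(X)
  residual <- Xc - A %*% S   # PCA-discarded remainder, kept for reconstruction
  structure(
    list(sources = S, mixing = A, channel_means = means, residual = residual,
         n_components = k, variance_retained = frac[k],
         criteria_flags = NULL, labels = NULL,
         sampling_rate_hz = recording$sampling_rate_hz,
         subject_id = recording$subject_id, run_id = recording$run_id,
         species = recording$species, channel_layout = recording$channel_layout),
    class = "component_decomposition")
}

# Symmetric FastICA on whitened data Z (k x N). Returns the k x k unmixing
# matrix. Deterministic for a given seed; restarts with derived seeds. When
# a near-Gaussian pair of components cycles below full convergence (a known
# fixed-point oscillation), the best-effort unmixing is returned with a
# warning, as reference FastICA implementations do; only gross
# non-convergence is an error.
fastica_symmetric <- function(Z, seed, max_iter, tol, max_restarts) {
  k <- nrow(Z)
  if (k == 1) return(matrix(1, 1, 1))
  ns <- ncol(Z)
  best_delta <- Inf
  best_W <- NULL
  for (attempt in 0:max_restarts) {
    W <- with_local_seed(derive_seed(seed, attempt), {
      orthonormalize(matrix(rnorm(k * k), k, k))
    })
    for (it in seq_len(max_iter)) {
      WZ <- W %*% Z
      G <- tanh(WZ)
      gprime <- rowMeans(1 - G^2)
      W1 <- (G %*% t(Z)) / ns - gprime * W
      W1 <- orthonormalize(W1)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < tol) return(W)
    }
    if (delta < best_delta) {
      best_delta <- delta
      best_W <- W
    }
  }
  if (best_delta > 0.5) {   # worse than a half-swapped component pair
    stop(sprintf(
      "FastICA failed to converge (best delta %.3g after %d iterations x %d restarts, k = %d components); try lowering variance_retained",
      best_delta, max_iter, max_restarts + 1, k))
  }
  warning(sprintf(
    "FastICA reached only delta = %.2g (tolerance %g) after %d restarts of %d iterations (k = %d); returning the best-effort unmixing",
    best_delta, tol, max_restarts + 1, max_iter, k))
  best_W
}

# Symmetric decorrelation: W <- (W W^T)^(-1/2) W.
orthonormalize <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% ((1 / sqrt(pmax(e$values, .Machine$double.eps))) *
                   t(e$vectors)) %*% W
}

#' Default thresholds for the three noise-component criteria
#'
#' The rejection criteria are qualitative in origin; these thresholds make
#' them operational and are all overridable.
#'
#' @param jump_sd One-sample change, in robust standard deviations of the
#'   component, above which a sample counts as a sudden jump/spike (in-band
#'   signals cannot exceed a small fraction of an SD per sample when the
#'   sampling rate is well above the band).
#' @param spike_rate_per_min Flag the component when jump-level samples
#'   exceed this rate.
#' @param ushape_r2 Coefficient of determination of a quadratic time trend
#'   above which the component counts as a slow U / inverted-U drift.
#' @param dispersion_kurtosis Spatial kurtosis of the mixing column
#'   (`n * sum(w^4) / sum(w^2)^2`, 1 = perfectly uniform, n = focal) below
#'   which the component counts as globally dispersive.
#' @param nperseg Welch segment length for the dominant-frequency check
#'   (NULL = automatic).
#' @return Named list of thresholds.
#' @export
component_criteria <- function(jump_sd = 1, spike_rate_per_min = 5,
                               ushape_r2 = 0.8, dispersion_kurtosis = 1.5,
                               nperseg = NULL) {
  as.list(environment())
}

#' Classify ICA components as signal or noise
#'
#' Applies the three rejection criteria: (i) temporal artifacts — sudden
#' jumps, numerous quick spikes, or a slowly varying U / inverted-U shape;
#' (ii) dominant power-spectrum frequency outside the hemodynamic band;
#' (iii) a global, spatially dispersive mixing map. A component is labelled
#' noise iff any criterion fires. All criteria are invariant to the sign
#' and scale of a component.
#'
#' @param decomp A `component_decomposition`.
#' @param band Hemodynamic frequency band in Hz (default `c(0.01, 0.1)`).
#' @param params Thresholds from [component_criteria()].
#' @return The decomposition with `criteria_flags` (data frame with logical
#'   columns `temporal_artifact`, `out_of_band`, `spatially_dispersive`,
#'   plus diagnostics `dominant_freq_hz`, `spatial_kurtosis`) and `labels`
#'   (`"signal"` / `"noise"`) filled in.
#' @export
classify_components <- function(decomp, band = c(0.01, 0.1),
                                params = component_criteria()) {
  stopifnot(inherits(decomp, "component_decomposition"),
            decomp$n_components >= 1)
  fs <- decomp$sampling_rate_hz
  k <- decomp$n_components
  ns <- ncol(decomp$sources)
  temporal <- logical(k)
  oob <- logical(k)
  domfreq <- numeric(k)
  for (i in seq_len(k)) {
    s <- decomp$sources[i, ]
    temporal[i] <- temporal_artifact_flag(s, fs, params)
    min_seg <- 64L
    if (ns < 2 * min_seg) {
      warning("component shorter than 2 spectral windows; out_of_band undefined, set FALSE")
      domfreq[i] <- NA_real_
      oob[i] <- FALSE
    } else {
      f <- dominant_frequency(s, fs, params$nperseg)
      domfreq[i] <- f
      df <- welch_bin_width(ns, fs, params$nperseg)
      oob[i] <- f < band[1] - df / 2 || f > band[2] + df / 2
    }
  }
  kurt <- apply(decomp$mixing, 2, spatial_kurtosis)
  dispersive <- kurt < params$dispersion_kurtosis
  flags <- data.frame(
    temporal_artifact = temporal, out_of_band = oob,
    spatially_dispersive = dispersive,
    dominant_freq_hz = domfreq, spatial_kurtosis = kurt)
  decomp$criteria_flags <- flags
  decomp$labels <- ifelse(temporal | oob | dispersive, "noise", "signal")
  decomp
}

welch_bin_width <- function(n, fs, nperseg) {
  if (is.null(nperseg)) nperseg <- min(n, 2^max(6, floor(log2(n / 4))))
  fs / min(nperseg, n)
}

# Criterion (i): jumps, spike showers, or a slow quadratic drift shape.
# Jumps are measured as the one-sample change in units of the component's
# robust SD: a band-limited source can move at most ~2*pi*f_max/fs of a
# peak amplitude per sample (< 0.5 SD at the default band and rates), while
# a motion transient moves by its full amplitude at onset.
temporal_artifact_flag <- function(s, fs, params) {
  scale_s <- mad(s)
  if (scale_s < .Machine$double.eps) scale_s <- sd(s)
  if (scale_s < .Machine$double.eps) return(FALSE)
  z <- abs(diff(s)) / scale_s
  n_jumpy <- sum(z > params$jump_sd)
  if (max(z) > 3 * params$jump_sd) return(TRUE)               # sudden jump
  minutes <- length(s) / fs / 60
  if (n_jumpy / minutes > params$spike_rate_per_min) return(TRUE)  # spike shower
  s <- s / sd(s)
  tau <- seq_along(s) / length(s)
  fit <- lm(s ~ tau + I(tau^2))
  r2 <- 1 - sum(residuals(fit)^2) / sum((s - mean(s))^2)
  r2 > params$ushape_r2
}

# Normalized non-central spatial kurtosis of a mixing column:
# n * sum(w^4) / sum(w^2)^2 in [1, n]; 1 means perfectly uniform loading.
spatial_kurtosis <- function(w) {
  length(w) * sum(w^4) / sum(w^2)^2
}

#' Reconstruct a denoised recording
#'
#' Rebuilds the channel-space recording from a classified decomposition
#' after zeroing the mixing-matrix columns of every component labelled
#' noise; signal components — including the small PCA-discarded residual —
#' pass through untouched, so an all-signal labelling reproduces the input
#' exactly.
#'
#' @param decomp A classified `component_decomposition` (or one with
#'   `labels` set manually).
#' @return A `nirs_recording`.
#' @export
reconstruct_denoised <- function(decomp) {
  stopifnot(inherits(decomp, "component_decomposition"))
  if (is.null(decomp$labels)) {
    stop("components are unlabelled; run classify_components() first")
  }
  keep <- decomp$labels == "signal"
  if (!any(keep)) {
    stop("all ", length(keep), " components are labelled noise; nothing left to reconstruct")
  }
  A <- decomp$mixing
  A[, !keep] <- 0
  X <- A %*% decomp$sources + decomp$residual + decomp$channel_means
  new_recording(X, decomp$sampling_rate_hz, subject_id = decomp$subject_id,
                run_id = decomp$run_id, species = decomp$species,
                channel_layout = decomp$channel_layout)
}

#' @export
print.component_decomposition <- function(x, ...) {
  lab <- if (is.null(x$labels)) "unclassified"
  else sprintf("%d signal / %d noise", sum(x$labels == "signal"),
               sum(x$labels == "noise"))
  cat(sprintf("<component_decomposition> %d components (%.1f%% variance) | %s\n",
              x$n_components, 100 * x$variance_retained, lab))
  invisible(x)
}

#' Denoise a recording by PCA+ICA rejection
#'
#' Convenience wrapper: [decompose()], [classify_components()],
#' [reconstruct_denoised()].
#'
#' @inheritParams decompose
#' @inheritParams classify_components
#' @return A denoised `nirs_recording`.
#' @export
ica_denoise <- function(recording, variance_retained = 0.99,
                        band = c(0.01, 0.1), params = component_criteria(),
                        ica_seed = 42L) {
  d <- decompose(recording, variance_retained, ica_seed = ica_seed)
  d <- classify_components(d, band, params)
  reconstruct_denoised(d)
}
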