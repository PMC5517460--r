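# Cohort specification and ground-truth connectivity construction.

#' Modular (community-structured) ground-truth correlation matrix
#'
#' Builds a connectome-like correlation matrix with block community
#' structure: channels are partitioned into `n_modules` near-equal modules,
#' within-module correlations are `within_r` and between-module correlations
#' `between_r`, optionally jittered and then projected to the nearest
#' positive-semidefinite correlation matrix. Community structure makes
#' clustering and local-efficiency behave non-trivially downstream.
#'
#' @param n_channels Number of channels (nodes).
#' @param n_modules Number of modules; must not exceed `n_channels`.
#' @param within_r,between_r Correlations, `0 <= between_r < within_r < 1`;
#'   `within_r` may be a vector of length `n_modules` (one correlation per
#'   module), giving modules heterogeneous internal coupling and hence a
#'   non-flat true nodal-metric profile.
#' @param jitter_sd Standard deviation of symmetric jitter added to
#'   off-diagonal entries (0 disables jitter).
#' @param seed Integer seed for the jitter.
#' @return A symmetric positive-semidefinite matrix with unit diagonal.
#' @examples
#' S <- make_modular_covariance(8, 2, within_r = 0.6, between_r = 0.1)
#' min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10
#' @export
make_modular_covariance <- function(n_channels, n_modules = 1,
                                    within_r = 0.5, between_r = 0,
                                    jitter_sd = 0.02, seed = 1L) {
  stopifnot(n_channels >= 2, n_modules >= 1, n_modules <= n_channels)
  within_r <- rep_len(within_r, n_modules)
  if (!(between_r >= 0 && all(between_r < within_r) && all(within_r < 1))) {
    stop("require 0 <= between_r < within_r < 1 (for every module)")
  }
  membership <- sort(rep_len(seq_len(n_modules), n_channels))
  same <- outer(membership, membership, "==")
  S <- matrix(between_r, n_channels, n_channels)
  S[same] <- within_r[membership[row(S)[same]]]
  diag(S) <- 1
  if (jitter_sd > 0) {
    set.seed(as.integer(seed))
    J <- matrix(rnorm(n_channels^2, sd = jitter_sd), n_channels)
    J <- (J + t(J)) / 2
    diag(J) <- 0
    S <- S + J
  }
  S <- nearest_psd_corr(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("covariance not positive semidefinite after projection; ",
         "reduce jitter_sd or correlations")
  }
  attr(S, "membership") <- membership
  S
}

#' Hub-gradient factor-model correlation matrix
#'
#' Builds a connectome-like correlation matrix from a two-factor generative
#' model: channel i loads `a_i` on a global factor (a smooth hub gradient,
#' so some nodes are strongly connected hubs and others periphery) and
#' `b` on one of `n_modules` module factors. The result
#' `S_ij = a_i a_j + b^2 [same module]` (unit diagonal) is positive
#' definite by construction, has all-positive entries, and — unlike an
#' equal-block modular matrix — yields a non-flat true nodal-metric
#' profile, which test-retest analyses of nodal maps require.
#'
#' @param n_channels Number of channels (nodes).
#' @param n_modules Number of modules.
#' @param hub_range Range `c(lo, hi)` of global-factor loadings across the
#'   hub gradient (defaults 0.45-0.85).
#' @param module_loading Loading on the module factor (default 0.35).
#' @return Symmetric positive-definite matrix with unit diagonal and
#'   attribute `"membership"`.
#' @export
make_hub_covariance <- function(n_channels, n_modules = 4,
                                hub_range = c(0.45, 0.85),
                                module_loading = 0.35) {
  stopifnot(n_channels >= 2, hub_range[1] > 0, hub_range[2] < 1,
            hub_range[1] < hub_range[2],
            hub_range[2]^2 + module_loading^2 < 1)
  a <- seq(hub_range[1], hub_range[2], length.out = n_channels)
  membership <- sort(rep_len(seq_len(n_modules), n_channels))
  same <- outer(membership, membership, "==")
  S <- outer(a, a) + module_loading^2 * same
  diag(S) <- 1
  attr(S, "membership") <- membership
  S
}

# Eigenvalue clipping followed by rescaling back to unit diagonal.
nearest_psd_corr <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= 0) {
    diag(S) <- 1
    return(S)
  }
  v <- pmax(e$values, 0)
  S2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(S2), .Machine$double.eps))
  S2 <- S2 / outer(d, d)
  (S2 + t(S2)) / 2
}

#' Default artifact parameters for the synthetic generator
#'
#' Amplitudes are expressed in multiples of the clean in-band signal's
#' per-channel standard deviation; setting every amplitude to 0 yields an
#' artifact-free cohort. The four classes mirror the kinds an ICA rejection
#' step is expected to catch: transient spikes/jumps, slow U-shaped drift,
#' out-of-band physiological oscillation (cardiac ~1 Hz, respiratory
#' ~0.3 Hz), and a global spatially dispersive superficial component.
#'
#' @param spike_amplitude,spike_rate_per_min,spike_decay_s Motion spikes:
#'   amplitude, expected events per minute (Poisson), exponential decay (s).
#' @param drift_amplitude,drift_prob Slow quadratic (U / inverted-U) drift
#'   amplitude and per-channel probability.
#' @param cardiac_amplitude,cardiac_freq_hz Cardiac oscillation.
#' @param respiratory_amplitude,respiratory_freq_hz Respiratory oscillation.
#' @param global_amplitude,global_loading_jitter Global superficial
#'   component: amplitude and spatial-profile jitter around uniform loading.
#' @return A named list of artifact parameters.
#' @export
artifact_params <- function(spike_amplitude = 5, spike_rate_per_min = 2,
                            spike_decay_s = 2,
                            drift_amplitude = 1.5, drift_prob = 0.3,
                            cardiac_amplitude = 0.6, cardiac_freq_hz = 1.0,
                            respiratory_amplitude = 0.6,
                            respiratory_freq_hz = 0.3,
                            global_amplitude = 1.5,
                            global_loading_jitter = 0.1) {
  as.list(environment())
}

#' Scale all artifact amplitudes at once
#'
#' @param params Output of [artifact_params()].
#' @param factor Multiplier applied to every `*_amplitude` entry (0 turns
#'   artifacts off).
#' @return Modified parameter list.
#' @export
scale_artifacts <- function(params, factor) {
  amp <- grepl("_amplitude$", names(params))
  params[amp] <- lapply(params[amp], function(a) a * factor)
  params
}

#' Specify a synthetic two-run fNIRS cohort
#'
#' The defaults emulate a whole-head resting-state acquisition: 18 subjects,
#' two scanning runs, 46 measurement channels sampled at 25 Hz for 600 s,
#' with band-limited (0.01-0.1 Hz) correlated fluctuations. Test-retest
#' reliability is controlled by two variance components acting on a
#' subject-level network-coupling scalar: `between_subject_sd` (shared by a
#' subject's runs) and `within_subject_sd` (independent per run), implying a
#' ground-truth intraclass correlation
#' `true_icc = between^2 / (between^2 + within^2)`.
#'
#' @param n_subjects,n_runs,n_channels Cohort dimensions.
#' @param duration_s Record length (s); `duration_s * sampling_rate_hz` must
#'   be an integer sample count.
#' @param sampling_rate_hz Sampling rate in Hz (reducible for speed).
#' @param ground_truth_covariance Optional channel correlation matrix
#'   (symmetric PSD, unit diagonal); defaults to a 4-module
#'   [make_modular_covariance()] structure.
#' @param signal_band Pass band (Hz) of the hemodynamic fluctuations.
#' @param signal_amplitude_um Standard deviation of the clean in-band signal
#'   (micromolar).
#' @param artifacts Output of [artifact_params()].
#' @param between_subject_sd,within_subject_sd Nonnegative variance-component
#'   standard deviations of the coupling scalar.
#' @param coupling_mean Mean of the coupling scalar in (0, 1); the scalar
#'   mixes the ground-truth correlation with the identity.
#' @param rng_seed Master seed; per-(subject, run) streams are derived from
#'   it by counter-based splitting, so cohorts are order-independent.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 18, n_runs = 2, n_channels = 46,
                        duration_s = 600, sampling_rate_hz = 25,
                        ground_truth_covariance = NULL,
                        signal_band = c(0.01, 0.1),
                        signal_amplitude_um = 0.05,
                        artifacts = artifact_params(),
                        between_subject_sd = 0.12,
                        within_subject_sd = 0.06,
                        coupling_mean = 0.6,
                        rng_seed = 1L) {
  stopifnot(n_subjects >= 1, n_runs >= 1, n_channels >= 2,
            duration_s > 0, sampling_rate_hz > 0,
            between_subject_sd >= 0, within_subject_sd >= 0,
            coupling_mean > 0, coupling_mean < 1,
            length(signal_band) == 2, signal_band[1] < signal_band[2],
            sampling_rate_hz > 2 * signal_band[2])
  ns <- duration_s * sampling_rate_hz
  if (abs(ns - round(ns)) > 1e-9) {
    stop("duration_s * sampling_rate_hz must be an integer sample count")
  }
  if (is.null(ground_truth_covariance)) {
    ground_truth_covariance <- make_modular_covariance(
      n_channels, n_modules = min(4, n_channels), within_r = 0.5,
      between_r = 0.15, jitter_sd = 0.02, seed = rng_seed)
  }
  S <- ground_truth_covariance
  stopifnot(nrow(S) == n_channels, ncol(S) == n_channels)
  if (max(abs(S - t(S))) > 1e-10 || max(abs(diag(S) - 1)) > 1e-10) {
    stop("ground_truth_covariance must be symmetric with unit diagonal")
  }
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("ground_truth_covariance must be positive semidefinite")
  }
  structure(
    list(n_subjects = n_subjects, n_runs = n_runs, n_channels = n_channels,
         duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
         n_samples = as.integer(round(ns)),
         ground_truth_covariance = S, signal_band = signal_band,
         signal_amplitude_um = signal_amplitude_um, artifacts = artifacts,
         between_subject_sd = between_subject_sd,
         within_subject_sd = within_subject_sd,
         coupling_mean = coupling_mean, rng_seed = as.integer(rng_seed)),
    class = "cohort_spec"
  )
}

#' Ground-truth intraclass correlation implied by a cohort spec
#'
#' @param spec A `cohort_spec`.
#' @return `between_subject_sd^2 / (between_subject_sd^2 +
#'   within_subject_sd^2)` (NaN when both are 0).
#' @export
true_icc <- function(spec) {
  b2 <- spec$between_subject_sd^2
  w2 <- spec$within_subject_sd^2
  b2 / (b2 + w2)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d subjects x %d runs | %d channels @ %g Hz, %g s | true ICC %.3f | seed %d\n",
    x$n_subjects, x$n_runs, x$n_channels, x$sampling_rate_hz, x$duration_s,
    true_icc(x), x$rng_seed))
  invisible(x)
}
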