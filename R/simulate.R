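# Synthetic cohort generator: band-limited correlated hemodynamics with
# injected artifacts and controllable test-retest reliability.

# Counter-based seed derivation: mixes the master seed with integer counters
# so per-(subject, run) streams are independent of simulation order. Result
# stays below 2^31.
derive_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483629
  for (a in c(...)) h <- (h * 1000003 + as.double(a)) %% 2147483629
  as.integer(h) + 1L
}

# Evaluate expr under a temporary RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Subject-run network coupling scalar
#'
#' The subject-level quantity that carries the cohort's ground-truth
#' reliability: `coupling = coupling_mean + b_s + w_sr`, where `b_s` is a
#' subject effect (sd `between_subject_sd`, shared across the subject's
#' runs) and `w_sr` a run effect (sd `within_subject_sd`), clamped to
#' (0.02, 0.98). The run's generating correlation matrix is
#' `(1 - coupling) * I + coupling * ground_truth_covariance`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index,run_index 1-based indices.
#' @return Scalar coupling value.
#' @export
subject_coupling <- function(spec, subject_index, run_index) {
  b <- with_local_seed(derive_seed(spec$rng_seed, 1L, subject_index),
                       rnorm(1)) * spec$between_subject_sd
  w <- with_local_seed(derive_seed(spec$rng_seed, 2L, subject_index, run_index),
                       rnorm(1)) * spec$within_subject_sd
  min(max(spec$coupling_mean + b + w, 0.02), 0.98)
}

#' Simulate one subject-run recording with ground truth
#'
#' Generates a band-limited correlated Gaussian hemodynamic record: white
#' noise is given the run's target covariance by Cholesky factorization and
#' then passed twice through the same zero-phase band-pass filter used in
#' preprocessing (double pass keeps essentially all power strictly inside
#' the band). Artifacts of four classes (spikes/jumps, slow U-shaped drift,
#' out-of-band cardiac/respiratory oscillation, global spatially dispersive
#' component) are superimposed according to `spec$artifacts`. Deterministic
#' given `(rng_seed, subject_index, run_index)`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index,run_index 1-based indices.
#' @return A list with elements `recording` (a `nirs_recording`) and
#'   `bundle` (a `ground_truth_bundle` with `clean_signal`,
#'   `artifact_total`, `injected_artifacts`, `true_fc`, `true_icc`,
#'   `coupling`); `clean_signal + artifact_total` reproduces the emitted
#'   recording exactly.
#' @export
simulate_run <- function(spec, subject_index, run_index) {
  stopifnot(inherits(spec, "cohort_spec"),
            subject_index >= 1, subject_index <= spec$n_subjects,
            run_index >= 1, run_index <= spec$n_runs)
  fs <- spec$sampling_rate_hz
  ns <- spec$n_samples
  nch <- spec$n_channels
  min_samples <- 2 * (1 / spec$signal_band[1]) * fs
  if (ns < min_samples) {
    stop(sprintf(
      "record of %d samples is shorter than two periods of the slowest in-band component (%d samples)",
      ns, as.integer(ceiling(min_samples))))
  }
  lambda <- subject_coupling(spec, subject_index, run_index)
  Sigma <- (1 - lambda) * diag(nch) + lambda * spec$ground_truth_covariance
  ba <- butter_bandpass(spec$signal_band[1], spec$signal_band[2], fs, 3)
  clean <- with_local_seed(derive_seed(spec$rng_seed, 3L, subject_index, run_index), {
    E <- matrix(rnorm(nch * ns), nch, ns)
    Y <- t(chol(Sigma)) %*% E
    Y <- t(apply(Y, 1, function(ch) filtfilt(ba$b, ba$a, filtfilt(ba$b, ba$a, ch))))
    Y * (spec$signal_amplitude_um / mean(apply(Y, 1, sd)))
  })
  art <- with_local_seed(derive_seed(spec$rng_seed, 4L, subject_index, run_index),
                         inject_artifacts(spec, ba))
  data <- clean + art$total
  rownames(data) <- sprintf("CH%02d", seq_len(nch))
  rec <- new_recording(data, fs, subject_id = sprintf("S%02d", subject_index),
                       run_id = run_index, species = "HbO")
  bundle <- structure(
    list(clean_signal = clean, artifact_total = art$total,
         injected_artifacts = art$events, true_fc = Sigma,
         true_icc = true_icc(spec), coupling = lambda),
    class = "ground_truth_bundle")
  list(recording = rec, bundle = bundle)
}

# Draw every artifact class; returns the summed contribution matrix plus a
# descriptor per injected event. Caller controls the RNG state.
inject_artifacts <- function(spec, ba) {
  p <- spec$artifacts
  fs <- spec$sampling_rate_hz
  ns <- spec$n_samples
  nch <- spec$n_channels
  amp0 <- spec$signal_amplitude_um
  total <- matrix(0, nch, ns)
  events <- list()
  add_event <- function(kind, channels, span, waveform) {
    events[[length(events) + 1L]] <<- list(
      kind = kind, channels = channels, time_span = span, waveform = waveform)
  }
  # transient motion spikes: one spatial profile per run (the cap's motion
  # signature, so the events form a single separable component), sparse
  # exponential-decay transients in time
  if (p$spike_amplitude > 0 && p$spike_rate_per_min > 0) {
    profile <- runif(nch, 0.2, 1)
    n_spk <- rpois(1, p$spike_rate_per_min * ns / fs / 60)
    wave <- numeric(ns)
    for (i in seq_len(n_spk)) {
      t0 <- sample.int(ns, 1)
      len <- min(ns - t0 + 1L, as.integer(ceiling(6 * p$spike_decay_s * fs)))
      w <- sample(c(-1, 1), 1) * p$spike_amplitude * amp0 *
        exp(-(seq_len(len) - 1) / (p$spike_decay_s * fs))
      wave[t0:(t0 + len - 1L)] <- wave[t0:(t0 + len - 1L)] + w
      add_event("spike", which(profile > 0), c(t0, t0 + len - 1L), w)
    }
    if (n_spk > 0) total <- total + outer(profile, wave)
  }
  # slow U / inverted-U drift on a random channel subset
  if (p$drift_amplitude > 0 && p$drift_prob > 0) {
    tau <- seq(0, 1, length.out = ns)
    q <- (tau - 0.5)^2
    q <- (q - mean(q)) / sd(q)
    for (ch in which(runif(nch) < p$drift_prob)) {
      w <- sample(c(-1, 1), 1) * p$drift_amplitude * amp0 * q
      total[ch, ] <- total[ch, ] + w
      add_event("drift", ch, c(1L, ns), w)
    }
  }
  # out-of-band physiological oscillations (shared phase, per-channel gain)
  tt <- (seq_len(ns) - 1) / fs
  for (osc in list(c(p$cardiac_amplitude, p$cardiac_freq_hz, 1),
                   c(p$respiratory_amplitude, p$respiratory_freq_hz, 2))) {
    if (osc[1] <= 0) next
    if (osc[2] >= fs / 2) {
      warning(sprintf("oscillatory artifact at %g Hz exceeds Nyquist (fs = %g Hz); skipped",
                      osc[2], fs))
      next
    }
    src <- sin(2 * pi * osc[2] * tt + runif(1, 0, 2 * pi))
    gain <- runif(nch, 0.5, 1.5)
    contrib <- osc[1] * amp0 * outer(gain, src)
    total <- total + contrib
    add_event(if (osc[3] == 1) "cardiac" else "respiratory",
              seq_len(nch), c(1L, ns), src)
  }
  # global spatially dispersive superficial component: quasi-oscillatory
  # Mayer-wave-like time course (in-band, so only the spatial criterion can
  # catch it) with near-uniform loading across all channels
  if (p$global_amplitude > 0) {
    f0 <- runif(1, 0.07, 0.1)
    env <- 1 + 0.3 * sin(2 * pi * 0.005 * tt + runif(1, 0, 2 * pi))
    src <- env * sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi))
    src <- src / sd(src)
    loading <- 1 + p$global_loading_jitter * rnorm(nch)
    contrib <- p$global_amplitude * amp0 * outer(loading, src)
    total <- total + contrib
    add_event("global", seq_len(nch), c(1L, ns), src)
  }
  list(total = total, events = events)
}

#' Simulate a full cohort
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `nirs_cohort`: a list with `spec`,
#'   `recordings` (nested `[[subject]][[run]]`) and `bundles` (same shape).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- vector("list", spec$n_subjects)
  bundles <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    recs[[s]] <- vector("list", spec$n_runs)
    bundles[[s]] <- vector("list", spec$n_runs)
    for (r in seq_len(spec$n_runs)) {
      sim <- simulate_run(spec, s, r)
      recs[[s]][[r]] <- sim$recording
      bundles[[s]][[r]] <- sim$bundle
    }
  }
  structure(list(spec = spec, recordings = recs, bundles = bundles),
            class = "nirs_cohort")
}

#' @export
print.nirs_cohort <- function(x, ...) {
  cat(sprintf("<nirs_cohort> %d subjects x %d runs (%d recordings)\n",
              x$spec$n_subjects, x$spec$n_runs,
              x$spec$n_subjects * x$spec$n_runs))
  invisible(x)
}

#' Subject-level reliability scalars without time series
#'
#' Draws the coupling scalar for every (subject, run) cell through the same
#' code path as [simulate_run()], letting reliability calibration be checked
#' at large n without simulating signals.
#'
#' @param spec A [cohort_spec()].
#' @return `n_subjects x n_runs` matrix of coupling values.
#' @export
simulate_reliability_scalars <- function(spec) {
  outer(seq_len(spec$n_subjects), seq_len(spec$n_runs),
        Vectorize(function(s, r) subject_coupling(spec, s, r)))
}
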