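# Band-pass filtering and the assembled preprocessing chain.

#' Zero-phase band-pass filter a recording
#'
#' Order-3 Butterworth applied forward and backward ([filtfilt()]), giving
#' zero group delay; the default 0.01-0.1 Hz band isolates low-frequency
#' hemodynamic fluctuations.
#'
#' @param recording A `nirs_recording`.
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @param order Butterworth prototype order (default 3).
#' @return The filtered `nirs_recording`.
#' @export
bandpass <- function(recording, low = 0.01, high = 0.1, order = 3) {
  stopifnot(inherits(recording, "nirs_recording"))
  fs <- recording$sampling_rate_hz
  if (high >= fs / 2) {
    stop(sprintf("upper band edge %g Hz is not below Nyquist (%g Hz)", high, fs / 2))
  }
  ba <- butter_bandpass(low, high, fs, order)
  out <- recording
  out$data <- t(apply(recording$data, 1, function(ch) filtfilt(ba$b, ba$a, ch)))
  rownames(out$data) <- rownames(recording$data)
  out
}

#' Full preprocessing of one recording
#'
#' Runs the artifact-rejection and filtering chain: PCA+ICA denoising
#' (optional), zero-phase band-pass, and optional trimming to the analysis
#' length (first `trim_s` seconds after filtering).
#'
#' @param recording A `nirs_recording` (hemoglobin concentrations; apply
#'   [mbll_convert()] first when starting from optical density).
#' @param denoise Apply ICA artifact rejection (default TRUE).
#' @param band Pass band in Hz.
#' @param variance_retained PCA variance kept before ICA.
#' @param criteria Thresholds from [component_criteria()].
#' @param trim_s Keep only the first `trim_s` seconds after filtering
#'   (NULL = full length).
#' @return The preprocessed `nirs_recording`.
#' @export
preprocess_run <- function(recording, denoise = TRUE, band = c(0.01, 0.1),
                           variance_retained = 0.99,
                           criteria = component_criteria(), trim_s = NULL) {
  stopifnot(inherits(recording, "nirs_recording"))
  rec <- recording
  if (denoise) {
    rec <- ica_denoise(rec, variance_retained, band, criteria)
  }
  rec <- bandpass(rec, band[1], band[2])
  if (!is.null(trim_s)) {
    ns <- as.integer(round(trim_s * rec$sampling_rate_hz))
    if (ns > ncol(rec$data)) {
      stop(sprintf("cannot trim to %g s: only %.1f s available", trim_s,
                   ncol(rec$data) / rec$sampling_rate_hz))
    }
    rec$data <- rec$data[, seq_len(ns), drop = FALSE]
  }
  rec
}
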