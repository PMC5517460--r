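# Core data containers: hemodynamic recordings and duration windows.

#' Construct a hemodynamic recording
#'
#' A recording holds one subject-run channel-by-time matrix of hemoglobin
#' concentration changes (conventionally micromolar), its sampling rate, a
#' 2-D channel layout for spatial maps, and the chromophore species.
#'
#' @param data Numeric matrix, channels x samples; row names are channel ids
#'   (assigned `CH01..` if absent). No missing values; at least 2 channels.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param subject_id,run_id Identifiers.
#' @param species `"HbO"` or `"HbR"`.
#' @param channel_layout Optional channels x 2 matrix of positions; defaults
#'   to a square grid.
#' @return An object of class `nirs_recording`.
#' @export
new_recording <- function(data, sampling_rate_hz, subject_id = "S01",
                          run_id = 1L, species = c("HbO", "HbR"),
                          channel_layout = NULL) {
  species <- match.arg(species)
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("a recording needs at least 2 channels")
  if (anyNA(data)) stop("recording contains missing values")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number")
  }
  if (is.null(rownames(data))) {
    rownames(data) <- sprintf("CH%02d", seq_len(nrow(data)))
  }
  if (is.null(channel_layout)) channel_layout <- default_layout(nrow(data))
  structure(
    list(data = data, sampling_rate_hz = sampling_rate_hz,
         subject_id = subject_id, run_id = run_id, species = species,
         channel_layout = channel_layout),
    class = "nirs_recording"
  )
}

# Square-ish grid positions used when no optode geometry is supplied.
default_layout <- function(n_channels) {
  ncol <- ceiling(sqrt(n_channels))
  i <- seq_len(n_channels) - 1L
  cbind(x = i %% ncol, y = i %/% ncol)
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf(
    "<nirs_recording> subject %s run %s | %d channels x %d samples @ %g Hz | %s\n",
    x$subject_id, x$run_id, nrow(x$data), ncol(x$data),
    x$sampling_rate_hz, x$species))
  invisible(x)
}

#' @export
dim.nirs_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)
channel_ids <- function(rec) rownames(rec$data)

#' Truncate a recording into nested duration windows
#'
#' Produces the prefix windows over which connectivity is recomputed: one
#' window per duration from `min_s` to `max_s` in steps of `step_s`, all
#' anchored at the first sample of the (denoised, filtered) record. With
#' the defaults this yields the 19 bins from 60 s to 600 s in 30-s steps.
#'
#' @param recording A `nirs_recording`.
#' @param min_s,max_s,step_s Window grid in seconds.
#' @return A list of `duration_window` objects ordered by duration.
#' @export
truncate_bins <- function(recording, min_s = 60, max_s = 600, step_s = 30) {
  stopifnot(inherits(recording, "nirs_recording"))
  fs <- recording$sampling_rate_hz
  avail_s <- n_samples(recording) / fs
  if (avail_s < max_s) {
    stop(sprintf("recording is %.1f s long; %g s required (maximum available: %.1f s)",
                 avail_s, max_s, avail_s))
  }
  durations <- seq(min_s, max_s, by = step_s)
  lapply(durations, function(d) {
    ns <- as.integer(round(d * fs))
    structure(
      list(data = recording$data[, seq_len(ns), drop = FALSE],
           duration_s = d, sampling_rate_hz = fs,
           subject_id = recording$subject_id, run_id = recording$run_id,
           species = recording$species),
      class = "duration_window"
    )
  })
}

#' @export
print.duration_window <- function(x, ...) {
  cat(sprintf("<duration_window> %g s | subject %s run %s | %d channels\n",
              x$duration_s, x$subject_id, x$run_id, nrow(x$data)))
  invisible(x)
}

# Coerce a full recording to a window covering its whole extent.
as_window <- function(recording) {
  structure(
    list(data = recording$data,
         duration_s = n_samples(recording) / recording$sampling_rate_hz,
         sampling_rate_hz = recording$sampling_rate_hz,
         subject_id = recording$subject_id, run_id = recording$run_id,
         species = recording$species),
    class = "duration_window"
  )
}
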