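# Digital filter design and zero-phase filtering.
#
# No signal-processing package ships with the target environment, so the
# order-n Butterworth band-pass (analog prototype -> band transform ->
# bilinear transform) and forward-backward filtering are implemented here.

# Polynomial coefficients (descending powers) from roots, complex-safe.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (root in r) p <- c(p, 0) - c(0, p * root)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Returns transfer-function coefficients for an order-`order` Butterworth
#' band-pass filter (so `2 * order` poles) obtained by the standard analog
#' prototype / frequency-transform / bilinear-transform route.
#'
#' @param low,high Band edges in Hz, `0 < low < high < fs / 2`.
#' @param fs Sampling rate in Hz.
#' @param order Filter order of the underlying low-pass prototype (default 3).
#' @return A list with numerator `b` and denominator `a` coefficient vectors.
#' @examples
#' ba <- butter_bandpass(0.01, 0.1, fs = 5)
#' length(ba$b)  # 2 * order + 1
#' @export
butter_bandpass <- function(low, high, fs, order = 3) {
  stopifnot(is.numeric(low), is.numeric(high), low > 0, high > low,
            high < fs / 2, order >= 1)
  # prewarped analog edges
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # low-pass -> band-pass: each pole splits into two
  pb <- bw * p_lp / 2
  p_bp <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
  z_bp <- rep(0 + 0i, order)          # order zeros at s = 0
  k_bp <- bw^order
  # bilinear transform s -> 2 fs (z - 1) / (z + 1)
  fs2 <- 2 * fs
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  z_d <- (fs2 + z_bp) / (fs2 - z_bp)
  k_d <- Re(k_bp * prod(fs2 - z_bp) / prod(fs2 - p_bp))
  # pad zeros at z = -1 to equalize counts
  z_d <- c(z_d, rep(-1 + 0i, length(p_d) - length(z_d)))
  b <- Re(poly_from_roots(z_d)) * k_d
  a <- Re(poly_from_roots(p_d))
  list(b = b, a = a)
}

# One-directional IIR filtering, zero initial conditions. Implemented as an
# FIR convolution followed by the recursive (AR) part, both via stats::filter
# so the loops run in C.
lfilter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb + length(x) - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# Padding long enough for the slowest pole transient to decay below 1e-6.
settle_length <- function(b, a) {
  p <- polyroot(rev(a))
  r <- max(Mod(p))
  if (r >= 1) return(length(a) * 100L)
  as.integer(ceiling(log(1e-6) / log(r)))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter `(b, a)` forward and backward with odd-reflection
#' padding, giving zero group delay and squared magnitude response.
#'
#' @param b,a Transfer-function coefficients, e.g. from [butter_bandpass()].
#' @param x Numeric vector.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  pad <- min(settle_length(b, a), n - 1L)
  if (n < 3 * (max(length(a), length(b)) - 1)) {
    stop("record of length ", n, " is shorter than 3x the filter settling length")
  }
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- lfilter(b, a, ext)
  y <- rev(lfilter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with Hann window and 50% overlap, one-sided.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length in samples; defaults to a power of two near
#'   a quarter of the series (at least 64, at most the series length).
#' @return A list with `freq` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) {
    nperseg <- min(n, 2^max(6, floor(log2(n / 4))))
  }
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  scale <- fs * sum(w^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(seg))^2 / scale
    p <- sp[seq_len(nf)]
    # double the interior one-sided bins
    if (nperseg %% 2 == 0) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = acc / length(starts))
}

# Dominant (peak) frequency of a series, DC bin excluded.
dominant_frequency <- function(x, fs, nperseg = NULL) {
  ps <- welch_psd(x, fs, nperseg)
  idx <- which.max(ps$psd[-1]) + 1L
  ps$freq[idx]
}
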