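# MBLL inversion, PCA+ICA decomposition, noise-component criteria,
# band-pass, duration binning.

test_that("MBLL conversion is the exact inverse of the forward model", {
  set.seed(7)
  hbo <- new_recording(matrix(rnorm(4 * 500), 4), 5, species = "HbO")
  hbr <- new_recording(matrix(rnorm(4 * 500), 4), 5, species = "HbR")
  od <- simulate_optical_density(hbo, hbr)
  back <- mbll_convert(od)
  expect_lt(max(abs(back$HbO$data - hbo$data)) / max(abs(hbo$data)), 1e-9)
  expect_lt(max(abs(back$HbR$data - hbr$data)) / max(abs(hbr$data)), 1e-9)

  # zero in, zero out; linear in the optical densities
  od0 <- od
  od0$od <- lapply(od0$od, function(m) m * 0)
  z <- mbll_convert(od0)
  expect_true(all(z$HbO$data == 0) && all(z$HbR$data == 0))
  odc <- od
  odc$od <- lapply(odc$od, function(m) 3 * m)
  sc <- mbll_convert(odc)
  expect_equal(sc$HbO$data, 3 * back$HbO$data, tolerance = 1e-12)
})

test_that("decompose recovers planted sources and reconstructs the input", {
  set.seed(11)
  n <- 2000
  src <- as.numeric(scale(sin(2 * pi * 0.03 * (1:n) / 5) + 0.2 * rnorm(n)))
  rec1 <- new_recording(outer(runif(6, 0.5, 2), src), 5)
  d1 <- decompose(rec1, 0.99)
  expect_equal(d1$n_components, 1)
  expect_gt(abs(cor(d1$sources[1, ], src)), 0.999)

  # two independent super-Gaussian sources, recovered up to permutation/sign
  s1 <- rexp(n) * sample(c(-1, 1), n, TRUE)
  s2 <- rexp(n) * sample(c(-1, 1), n, TRUE)
  M <- matrix(c(1, 0.6, -0.4, 1, 0.5, 0.8), 3, 2)
  rec2 <- new_recording(M %*% rbind(s1, s2), 5)
  d2 <- decompose(rec2, 0.9999)
  expect_equal(d2$n_components, 2)
  cors <- abs(cor(t(d2$sources), cbind(s1, s2)))
  expect_true(all(apply(cors, 2, max) > 0.99))

  # all-signal labelling reproduces the input
  d2$labels <- rep("signal", d2$n_components)
  expect_equal(reconstruct_denoised(d2)$data, rec2$data, tolerance = 1e-10)

  # mixing %*% sources + means reconstructs the PCA-retained portion
  spec <- cohort_spec(n_subjects = 1, n_runs = 1, n_channels = 10,
                      duration_s = 300, sampling_rate_hz = 5, rng_seed = 13)
  rec3 <- simulate_run(spec, 1, 1)$recording
  d3 <- decompose(rec3, 0.95)
  recon <- d3$mixing %*% d3$sources + d3$channel_means
  resid_var <- sum((rec3$data - recon)^2) / sum((rec3$data - rowMeans(rec3$data))^2)
  expect_lte(resid_var, (1 - 0.95) + 0.01)
})

test_that("classification criteria fire on the right component types", {
  fs <- 25
  n <- 6000
  t <- (1:n) / fs
  focal <- c(2, 1.5, rep(0.05, 6))       # module-confined loading
  uniform <- rep(1, 8) + 0.05 * sin(1:8) # near-uniform (dispersive) loading

  d <- manual_decomposition(
    rbind(sin(2 * pi * 1 * t),          # cardiac tone, out of band
          sin(2 * pi * 0.05 * t),       # in-band oscillation
          sin(2 * pi * 0.05 * t)),      # in-band, dispersive map
    cbind(focal, focal, uniform), fs)
  d <- classify_components(d)
  fl <- d$criteria_flags
  expect_equal(fl$out_of_band, c(TRUE, FALSE, FALSE))
  expect_equal(fl$spatially_dispersive, c(FALSE, FALSE, TRUE))
  expect_equal(unname(d$labels), c("noise", "signal", "noise"))

  # spike train and U-shaped drift trip the temporal criterion
  spike <- as.numeric(scale(sin(2 * pi * 0.05 * t)))
  spike[seq(100, n, by = 150)] <- spike[seq(100, n, by = 150)] + 25
  ushape <- (t / max(t) - 0.5)^2
  d2 <- manual_decomposition(rbind(spike, ushape), cbind(focal, focal), fs)
  d2 <- classify_components(d2)
  expect_true(all(d2$criteria_flags$temporal_artifact))

  # invariance to component sign and scale
  d3 <- manual_decomposition(rbind(-3 * spike, 0.01 * ushape),
                             cbind(-2 * focal, 5 * focal), fs)
  d3 <- classify_components(d3)
  expect_equal(d3$criteria_flags$temporal_artifact,
               d2$criteria_flags$temporal_artifact)
  expect_equal(d3$criteria_flags$spatially_dispersive,
               d2$criteria_flags$spatially_dispersive)
})

test_that("generator-labelled global artifact is flagged dispersive and denoising helps", {
  spec <- cohort_spec(n_subjects = 2, n_runs = 1, n_channels = 46,
                      duration_s = 600, sampling_rate_hz = 5, rng_seed = 25)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  for (s in 1:2) {
    sim <- simulate_run(spec, s, 1)
    d <- classify_components(decompose(sim$recording))
    gl <- sim$bundle$injected_artifacts[[
      which(vapply(sim$bundle$injected_artifacts, `[[`, "", "kind") == "global")]]
    gi <- which.max(abs(apply(d$sources, 1, cor, y = gl$waveform)))
    expect_true(d$criteria_flags$spatially_dispersive[gi])
    den <- reconstruct_denoised(d)
    expect_lt(rmse(den$data, sim$bundle$clean_signal),
              rmse(sim$recording$data, sim$bundle$clean_signal))
    # denoising never alters shape or sampling rate
    expect_identical(dim(den$data), dim(sim$recording$data))
    expect_identical(den$sampling_rate_hz, sim$recording$sampling_rate_hz)
  }
})

test_that("reconstruction requires labels and at least one signal component", {
  spec <- cohort_spec(n_subjects = 1, n_runs = 1, n_channels = 6,
                      duration_s = 300, sampling_rate_hz = 5, rng_seed = 23)
  d <- decompose(simulate_run(spec, 1, 1)$recording)
  expect_error(reconstruct_denoised(d), "unlabelled")
  d$labels <- rep("noise", d$n_components)
  expect_error(reconstruct_denoised(d), "labelled noise")
  # zeroing a column makes the output invariant to that source's waveform
  d$labels <- c("noise", rep("signal", d$n_components - 1))
  out1 <- reconstruct_denoised(d)
  d$sources[1, ] <- rev(d$sources[1, ])
  out2 <- reconstruct_denoised(d)
  expect_equal(out1$data, out2$data, tolerance = 1e-12)
})

test_that("band-pass on recordings preserves structure and rejects bad bands", {
  spec <- cohort_spec(n_subjects = 1, n_runs = 1, n_channels = 4,
                      duration_s = 300, sampling_rate_hz = 5, rng_seed = 3)
  rec <- simulate_run(spec, 1, 1)$recording
  out <- bandpass(rec)
  expect_identical(dim(out$data), dim(rec$data))
  expect_identical(rownames(out$data), rownames(rec$data))
  expect_error(bandpass(rec, 0.01, 3), "Nyquist")
})

test_that("duration bins are the 19 nested prefixes of the record", {
  spec <- tiny_spec(n_subjects = 1, n_runs = 1, n_channels = 4)
  rec <- simulate_run(spec, 1, 1)$recording
  wins <- truncate_bins(rec)
  expect_length(wins, 19)
  expect_equal(vapply(wins, `[[`, 0, "duration_s"), seq(60, 600, 30))
  for (k in seq_len(18)) {
    nk <- ncol(wins[[k]]$data)
    expect_equal(nk, as.integer(wins[[k]]$duration_s * rec$sampling_rate_hz))
    expect_identical(wins[[k]]$data, wins[[k + 1]]$data[, seq_len(nk)])
  }
  short <- rec
  short$data <- short$data[, 1:400]
  expect_error(truncate_bins(short), "maximum available")
})
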