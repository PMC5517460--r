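# Synthetic cohort generator: ground-truth covariance, determinism,
# reliability calculus, spectral content, forward optical model.

test_that("modular covariance produces the stated block structure", {
  S1 <- make_modular_covariance(4, 1, within_r = 0.5, jitter_sd = 0)
  expect_equal(unname(S1[upper.tri(S1)]), rep(0.5, 6))
  expect_equal(diag(S1), rep(1, 4))

  S2 <- make_modular_covariance(4, 2, within_r = 0.6, between_r = 0, jitter_sd = 0)
  expect_equal(S2[1, 2], 0.6)
  expect_equal(S2[3, 4], 0.6)
  expect_equal(S2[1, 3], 0)
  expect_equal(S2[2, 4], 0)
})

test_that("modular covariance is PSD with unit diagonal for varied parameters", {
  for (seed in 1:6) {
    n <- sample(6:46, 1)
    S <- make_modular_covariance(n, sample(1:4, 1),
                                 within_r = runif(1, 0.3, 0.8),
                                 between_r = runif(1, 0, 0.25),
                                 jitter_sd = runif(1, 0, 0.05), seed = seed)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(diag(S), rep(1, n), tolerance = 1e-12)
    expect_equal(S, t(S))
  }
  expect_error(make_modular_covariance(8, 2, within_r = 0.3, between_r = 0.5),
               "between_r")
})

test_that("simulation is deterministic and artifacts sum exactly", {
  spec <- cohort_spec(n_subjects = 2, n_runs = 2, n_channels = 6,
                      duration_s = 300, sampling_rate_hz = 5, rng_seed = 17)
  a <- simulate_run(spec, 1, 2)
  b <- simulate_run(spec, 1, 2)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$bundle$true_fc, b$bundle$true_fc)
  # emitted recording = clean + injected artifacts, exactly
  expect_identical(unname(a$recording$data),
                   a$bundle$clean_signal + a$bundle$artifact_total)
  kinds <- vapply(a$bundle$injected_artifacts, `[[`, "", "kind")
  expect_true(all(kinds %in% c("spike", "drift", "cardiac", "respiratory", "global")))
})

test_that("cohort has n_subjects x n_runs recordings and run-shared truth when within-sd is 0", {
  spec <- tiny_spec(n_subjects = 3, n_runs = 2, n_channels = 5,
                    within_subject_sd = 0)
  coh <- simulate_cohort(spec)
  expect_length(coh$recordings, 3)
  expect_length(unlist(coh$recordings, recursive = FALSE), 6)
  for (s in 1:3) {
    expect_identical(coh$bundles[[s]][[1]]$true_fc, coh$bundles[[s]][[2]]$true_fc)
  }
  # distinct subjects still differ
  expect_false(isTRUE(all.equal(coh$bundles[[1]][[1]]$true_fc,
                                coh$bundles[[2]][[1]]$true_fc)))
})

test_that("ground-truth ICC follows the variance-component ratio", {
  expect_equal(true_icc(tiny_spec(within_subject_sd = 0)), 1)
  s <- cohort_spec(n_subjects = 2, between_subject_sd = 1, within_subject_sd = 1,
                   n_channels = 4, duration_s = 240, sampling_rate_hz = 5)
  expect_equal(true_icc(s), 0.5)
  s2 <- cohort_spec(n_subjects = 2, between_subject_sd = 2, within_subject_sd = 1,
                    n_channels = 4, duration_s = 240, sampling_rate_hz = 5)
  expect_equal(true_icc(s2), 0.8)
})

test_that("empirical ICC of the subject-level coupling converges to the target", {
  errs <- sapply(1:5, function(rep) {
    spec <- cohort_spec(n_subjects = 200, n_runs = 2, n_channels = 4,
                        duration_s = 240, sampling_rate_hz = 5,
                        between_subject_sd = 0.08, within_subject_sd = 0.04,
                        rng_seed = 30 + rep)  # true ICC 0.8
    m <- simulate_reliability_scalars(spec)
    stopifnot(all(dim(m) == c(200, 2)))
    icc(m) - 0.8
  })
  expect_lte(median(abs(errs)), 0.05)
})

test_that("clean-signal spectrum is confined to the pass band", {
  spec <- cohort_spec(n_subjects = 1, n_runs = 1, n_channels = 4,
                      duration_s = 600, sampling_rate_hz = 5,
                      artifacts = scale_artifacts(artifact_params(), 0),
                      rng_seed = 41)
  sim <- simulate_run(spec, 1, 1)
  for (ch in 1:4) {
    ps <- welch_psd(sim$bundle$clean_signal[ch, ], 5, 1024)
    df <- ps$freq[2]  # bins represent +- half a bin width
    inband <- ps$freq >= 0.01 - df / 2 & ps$freq <= 0.1 + df / 2
    expect_gte(sum(ps$psd[inband]) / sum(ps$psd), 0.95)
  }
})

test_that("sample correlation of long clean records approaches the generating FC", {
  base <- list(n_channels = 6, sampling_rate_hz = 1,
               artifacts = scale_artifacts(artifact_params(), 0))
  dev_at <- function(duration) {
    spec <- cohort_spec(n_subjects = 1, n_runs = 1, n_channels = base$n_channels,
                        duration_s = duration, sampling_rate_hz = base$sampling_rate_hz,
                        artifacts = base$artifacts, rng_seed = 53)
    sim <- simulate_run(spec, 1, 1)
    max(abs(cor(t(sim$bundle$clean_signal)) - sim$bundle$true_fc))
  }
  short <- dev_at(600)
  long <- dev_at(6000)   # 10x duration
  expect_lt(long, short)
  expect_lt(long, 0.15)
})

test_that("simulated optical density is linear and round-trips through MBLL", {
  spec <- cohort_spec(n_subjects = 1, n_runs = 1, n_channels = 5,
                      duration_s = 240, sampling_rate_hz = 5, rng_seed = 9)
  sim <- simulate_run(spec, 1, 1)
  hbo <- sim$recording

  zero <- hbo
  zero$data <- zero$data * 0
  od0 <- simulate_optical_density(zero)
  expect_true(all(od0$od[[1]] == 0) && all(od0$od[[2]] == 0))

  od1 <- simulate_optical_density(hbo, separation_cm = 3.2)
  od2 <- simulate_optical_density(hbo, separation_cm = 6.4)
  expect_equal(od2$od[[1]], 2 * od1$od[[1]], tolerance = 1e-12)
  expect_equal(od2$od[[2]], 2 * od1$od[[2]], tolerance = 1e-12)

  back <- mbll_convert(od1)
  rel <- max(abs(back$HbO$data - hbo$data)) / max(abs(hbo$data))
  expect_lt(rel, 1e-9)

  expect_error(simulate_optical_density(hbo, extinction = matrix(1, 2, 2)),
               "singular")
})
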