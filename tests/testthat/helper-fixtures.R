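# Shared fixtures: small, fast cohort specifications and hand-built
# component decompositions.

# Tiny artifact-free cohort at 1 Hz for structural / evaluation tests.
tiny_spec <- function(n_subjects = 2, n_runs = 2, n_channels = 10,
                      duration_s = 600, within_subject_sd = 0.06, seed = 21) {
  # dense, strongly positive ground-truth FC so the full 0.17-0.50 sparsity
  # grid stays feasible even in noisy 60-s windows
  cohort_spec(n_subjects = n_subjects, n_runs = n_runs,
              n_channels = n_channels, duration_s = duration_s,
              sampling_rate_hz = 1,
              ground_truth_covariance = make_modular_covariance(
                n_channels, 2, within_r = 0.6, between_r = 0.35,
                jitter_sd = 0.02, seed = seed),
              coupling_mean = 0.8,
              artifacts = scale_artifacts(artifact_params(), 0),
              within_subject_sd = within_subject_sd, rng_seed = seed)
}

# Hand-built decomposition whose sources and mixing are fully controlled;
# used to unit-test classification criteria in isolation.
manual_decomposition <- function(sources, mixing, fs) {
  sources <- rbind(sources)
  structure(
    list(sources = sources, mixing = mixing,
         channel_means = rep(0, nrow(mixing)),
         residual = matrix(0, nrow(mixing), ncol(sources)),
         n_components = nrow(sources), variance_retained = 1,
         criteria_flags = NULL, labels = NULL,
         sampling_rate_hz = fs, subject_id = "S01", run_id = 1L,
         species = "HbO", channel_layout = NULL),
    class = "component_decomposition")
}
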