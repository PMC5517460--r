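# nirsconn

Scanning-duration stability of resting-state fNIRS functional connectomes.

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
through scalp optodes and, from resting-state recordings, supports functional
connectivity (FC) and graph-theoretical analyses of whole-cortex brain
networks. A practical question for developmental and clinical protocols is
**how much scanning time is enough**: how long must a resting-state record be
before FC matrices and network metrics become stable within a session and
reproducible between repeated runs?

`nirsconn` implements the full analysis chain needed to answer that question,
together with a synthetic-cohort generator that provides ground truth for
every stage, so the whole pipeline is testable without any recordings:

1. **Synthetic cohorts** — two-run, multichannel (default 18 subjects × 2
   runs × 46 channels at 25 Hz), band-limited (0.01–0.1 Hz) correlated
   Gaussian hemodynamics with a known generating correlation matrix,
   controllable test–retest reliability, and four injected artifact classes
   (motion spikes/jumps, slow U-shaped drift, cardiac ≈1 Hz and respiratory
   ≈0.3 Hz oscillation, a global spatially dispersive superficial
   component). An optional forward Beer–Lambert model emits two-wavelength
   optical-density series.
2. **Preprocessing** — modified Beer–Lambert law (MBLL) conversion from
   optical density to ΔHbO/ΔHbR; PCA+ICA decomposition with three noise
   criteria (temporal jumps/spikes/U-drift, dominant frequency outside
   0.01–0.1 Hz, globally dispersive spatial map); reconstruction with noise
   mixing columns zeroed; zero-phase order-3 Butterworth band-pass; and
   truncation into the 19 nested duration bins 60, 90, …, 600 s.
3. **Connectivity** — for each duration window, channel-pair FC by Pearson
   correlation

   r(x_i, x_j) = Σ_t (x_i − x̄_i)(x_j − x̄_j) / √Σ(x_i − x̄_i)² √Σ(x_j − x̄_j)²

   and by maximum lagged cross-correlation (the maximum of r over time
   delays d ∈ [−L, +L], default L = 20 s, recomputed on the overlap).
4. **Network metrics** — FC matrices thresholded at sparsity 0.17–0.50
   (step 0.01, 34 thresholds; binary or weighted), then nodal efficiency
   E_nodal(i) = (N−1)⁻¹ Σ_j 1/d_ij, nodal betweenness (normalized shortest-
   path dependency), clustering coefficient C = n⁻¹ Σ 2t_i/(k_i(k_i−1)),
   global efficiency E_glob = mean nodal efficiency, and local efficiency
   E_loc = N⁻¹ Σ E_glob(G_i) over neighbor subgraphs, each summarized as
   its AUC across the sparsity grid.
5. **Evaluation** — stability of every map/metric against the 600-s
   reference (map–map Pearson r; paired t for global metrics), between-run
   reproducibility (per-subject map correlations; across-subject
   correlations of global AUCs), and test–retest reliability by the
   one-way intraclass correlation ICC = (MS_b − MS_w)/(MS_b + (k−1)MS_w).

## Worked example

```r
library(nirsconn)

spec <- cohort_spec(n_subjects = 3, n_runs = 2, n_channels = 20,
                    duration_s = 600, sampling_rate_hz = 5,
                    ground_truth_covariance = make_hub_covariance(20, 4),
                    rng_seed = 7)
cohort <- simulate_cohort(spec)

rec  <- cohort$recordings[[1]][[1]]
filt <- bandpass(ica_denoise(rec))           # PCA+ICA rejection + band-pass
fc   <- pearson_fc(truncate_bins(filt)[[19]])  # the full 600-s window
prof <- network_metric_profile(fc)             # 34 thresholds x 5 metrics

pre <- lapply(cohort$recordings, function(runs)
  lapply(runs, function(r) bandpass(ica_denoise(r))))
sw <- run_duration_sweep(pre, methods = "pearson", modes = "binary")
```

which prints (abridged):

```
<cohort_spec> 3 subjects x 2 runs | 20 channels @ 5 Hz, 600 s | true ICC 0.800 | seed 7
<connectivity_matrix> pearson | 20 x 20 | 600 s | subject S01 run 1
global efficiency AUC: 0.206
<duration_sweep_result> 19 durations (60-600 s) | methods: pearson | modes: binary
  stability rows: 114 | reliability rows: 114

 metric  method duration_s    mean_r       sd_r
     fc pearson         60 0.6043325 0.04073797
     fc pearson         90 0.6412324 0.04146704
     fc pearson        120 0.6637184 0.05126671
     fc pearson        150 0.6765578 0.05076240
```

`mean_r` is the group-mean correlation between each subject's FC map at the
given duration and their 600-s reference map: already 0.60 at 60 s and
rising monotonically toward 1 at 600 s — the duration-stability pattern the
pipeline is built to quantify. The `reliability` table reports the same
design between runs (per-subject map correlations, elementwise ICC and its
qualitative band); with only 3 subjects and 600 s of signal the FC ICC sits
near zero, illustrating that between-run reliability needs more subjects
and/or duration than within-run stability.

A command-line interface wraps the same functions
(`inst/scripts/nirsconn-cli`): subcommands `simulate`, `preprocess`,
`connect`, `metrics`, `evaluate`, `run-all`, each reading/writing plain TSV
with a `#key<TAB>value` header plus a JSON config.

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline end to end from scratch against
the installed package — it simulates a two-run artifact-bearing cohort,
applies ICA denoising and band-pass filtering, computes duration-binned
connectivity and thresholded network metrics, and evaluates stability and
reliability — then writes its results manifest as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — implementation (generator, preprocessing, connectivity, network
  metrics, evaluation, I/O + CLI)
- `tests/testthat/` — unit, property and acceptance suites, with
  independent brute-force oracles in `helper-oracles.R`
- `vignettes/duration-stability.Rmd` — the methods vignette: model,
  assumptions, parameter defaults, numerical choices, limitations
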