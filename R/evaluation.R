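# Stability across durations, between-run reproducibility, and intraclass
# correlation (test-retest reliability).

#' Vectorize a connectivity or nodal map
#'
#' Symmetric matrices are flattened to their upper triangle excluding the
#' diagonal, in fixed (row < column) lexicographic order; nodal vectors
#' pass through unchanged.
#'
#' @param x Symmetric matrix, `connectivity_matrix`, or numeric vector.
#' @return Numeric vector (length `n(n-1)/2` for an n x n matrix).
#' @export
vectorize_map <- function(x) {
  if (inherits(x, "connectivity_matrix")) x <- x$values
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x) || max(abs(x - t(x))) > 1e-9) {
      stop("matrix maps must be symmetric")
    }
    return(x[upper.tri(x)])
  }
  as.numeric(x)
}

#' Reassemble a vectorized map into a symmetric matrix
#'
#' Inverse of [vectorize_map()] for matrix maps; the diagonal is set to
#' `diag_value`.
#'
#' @param v Vector of length `n(n-1)/2`.
#' @param diag_value Diagonal fill (default 1).
#' @return n x n symmetric matrix.
#' @export
unvectorize_map <- function(v, diag_value = 1) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9) stop("length is not n(n-1)/2 for integer n")
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Map-map stability correlation
#'
#' Pearson correlation (with two-sided p) between a short-duration map and
#' the long-duration reference map.
#'
#' @param short_map,reference_map Equal-length numeric vectors (>= 3
#'   entries), e.g. from [vectorize_map()].
#' @return List with `r` and `p`.
#' @export
stability_correlation <- function(short_map, reference_map) {
  stopifnot(length(short_map) == length(reference_map), length(short_map) >= 3)
  if (sd(short_map) == 0 || sd(reference_map) == 0) {
    stop("zero variance in a map; correlation undefined")
  }
  ct <- suppressWarnings(cor.test(short_map, reference_map))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test of short- vs reference-duration metric values
#'
#' Standard paired t on per-subject differences, two-sided. Degenerate
#' cases are defined explicitly: all-zero differences give `t = 0, p = 1`;
#' zero-variance nonzero differences give infinite `t` and `p = 0`.
#'
#' @param short_values,ref_values Paired per-subject values (n >= 3).
#' @return List with `t` and `p`.
#' @export
stability_ttest <- function(short_values, ref_values) {
  stopifnot(length(short_values) == length(ref_values), length(short_values) >= 3)
  d <- short_values - ref_values
  if (all(d == 0)) return(list(t = 0, p = 1))
  if (sd(d) == 0) return(list(t = sign(mean(d)) * Inf, p = 0))
  tt <- t.test(short_values, ref_values, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Between-run reproducibility correlations
#'
#' Per-subject mode correlates each subject's run-1 and run-2 map vectors,
#' returning one r per subject plus the group mean and sd. Across-subjects
#' mode correlates a subject-indexed scalar (e.g. a global metric AUC)
#' between runs, returning a single r.
#'
#' @param run1_maps,run2_maps For `per_subject`: lists of per-subject map
#'   vectors. For `across_subjects`: numeric vectors with one scalar per
#'   subject.
#' @param level `"per_subject"` or `"across_subjects"`.
#' @return For `per_subject`: list with `r` (per subject), `mean_r`,
#'   `sd_r`. For `across_subjects`: list with `r`.
#' @export
between_run_correlation <- function(run1_maps, run2_maps,
                                    level = c("per_subject", "across_subjects")) {
  level <- match.arg(level)
  if (level == "per_subject") {
    stopifnot(is.list(run1_maps), is.list(run2_maps),
              length(run1_maps) == length(run2_maps))
    r <- mapply(function(a, b) stability_correlation(a, b)$r,
                run1_maps, run2_maps)
    list(r = unname(r), mean_r = mean(r), sd_r = sd(r))
  } else {
    run1_maps <- as.numeric(run1_maps)
    run2_maps <- as.numeric(run2_maps)
    if (length(run1_maps) < 3) stop("across-subjects correlation needs >= 3 subjects")
    list(r = stability_correlation(run1_maps, run2_maps)$r)
  }
}

#' Intraclass correlation coefficient (one-way random effects)
#'
#' `ICC = (MS_b - MS_w) / (MS_b + (k - 1) MS_w)`, with between-subject mean
#' square `MS_b` (df `n - 1`) and within-subject mean square `MS_w`
#' (df `n(k - 1)`) from a one-way ANOVA over subjects. May be negative;
#' negative values are reported as computed.
#'
#' @param measurements n x k numeric matrix: n subjects, k repeated runs;
#'   no missing cells.
#' @return Scalar ICC (0 with a warning when all measurements are
#'   identical).
#' @export
icc <- function(measurements) {
  m <- as.matrix(measurements)
  n <- nrow(m)
  k <- ncol(m)
  stopifnot(n >= 2, k >= 2)
  if (anyNA(m)) stop("measurements contain missing cells")
  rowm <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((rowm - grand)^2) / (n - 1)
  msw <- sum((m - rowm)^2) / (n * (k - 1))
  denom <- msb + (k - 1) * msw
  if (denom == 0) {
    warning("all measurements identical; ICC undefined, returning 0")
    return(0)
  }
  (msb - msw) / denom
}

# Vectorized elementwise ICC for k = 2 runs: x1, x2 are subjects x p.
icc_elementwise <- function(x1, x2) {
  n <- nrow(x1)
  a <- (x1 + x2) / 2
  grand <- colMeans(a)
  msb <- 2 * colSums((a - rep(grand, each = n))^2) / (n - 1)
  msw <- colSums((x1 - x2)^2 / 2) / n
  denom <- msb + msw
  out <- ifelse(denom == 0, 0, (msb - msw) / denom)
  unname(out)
}

#' Qualitative reliability band of an ICC value
#'
#' Cicchetti-style cut-offs: below 0.4 low, 0.4-0.6 fair, 0.6-0.75 good,
#' 0.75 and above excellent (overridable).
#'
#' @param value ICC value(s).
#' @param cuts Named cut-offs `c(fair = 0.4, good = 0.6, excellent = 0.75)`.
#' @return Character vector of band labels.
#' @export
classify_icc <- function(value, cuts = c(fair = 0.4, good = 0.6, excellent = 0.75)) {
  stopifnot(length(cuts) == 3, !is.unsorted(cuts))
  out <- rep("low", length(value))
  out[value >= cuts[1]] <- "fair"
  out[value >= cuts[2]] <- "good"
  out[value >= cuts[3]] <- "excellent"
  out
}

#' Duration sweep: stability, reproducibility, and reliability tables
#'
#' Runs the complete design over a (preprocessed) cohort: for every
#' subject, run, FC method and duration bin it computes connectivity and
#' network-metric AUC profiles, then evaluates (a) stability of each map /
#' global metric against the longest-duration reference of run 1, and (b)
#' between-run reproducibility and ICC reliability at every duration.
#' Deterministic given the cohort and settings.
#'
#' @param cohort A `nirs_cohort` (or a list shaped like
#'   `cohort$recordings`) whose recordings are already preprocessed as
#'   desired.
#' @param methods FC estimators, subset of `c("pearson", "crosscorr")`.
#' @param modes Network modes, subset of `c("binary", "weighted")`.
#' @param min_s,max_s,step_s Duration grid (defaults: 60-600 s by 30 s).
#' @param grid Sparsity grid (default [sparsity_grid()]).
#' @param max_lag_s Lag cap for `crosscorr` (seconds).
#' @param reference_run Run used for the stability analysis (default 1).
#' @return An object of class `duration_sweep_result`: list with long
#'   data frames `stability` and `reliability`, the `durations`, and a
#'   `detail` list of per-subject quantities.
#' @export
run_duration_sweep <- function(cohort, methods = c("pearson", "crosscorr"),
                               modes = "binary", min_s = 60, max_s = 600,
                               step_s = 30, grid = sparsity_grid(),
                               max_lag_s = 20, reference_run = 1L) {
  recs <- if (inherits(cohort, "nirs_cohort")) cohort$recordings else cohort
  methods <- match.arg(methods, c("pearson", "crosscorr"), several.ok = TRUE)
  modes <- match.arg(modes, c("binary", "weighted"), several.ok = TRUE)
  n_sub <- length(recs)
  n_run <- length(recs[[1]])
  durations <- seq(min_s, max_s, by = step_s)
  nd <- length(durations)
  ref_d <- nd  # longest duration is the stability reference

  # fc_vec[[m]][[s]][[r]][[d]]; auc store per metric
  fc_vec <- list()
  nodal_auc <- list()   # [[mode]][[m]][[metric]][[s]][[r]][[d]] vectors
  global_auc <- list()  # [[mode]][[m]][[metric]] array [s, r, d]
  for (m in methods) {
    fc_vec[[m]] <- vector("list", n_sub)
    for (mode in modes) {
      for (met in c("nodal_efficiency", "nodal_betweenness")) {
        nodal_auc[[mode]][[m]][[met]] <- vector("list", n_sub)
      }
      for (met in c("clustering_coefficient", "global_efficiency", "local_efficiency")) {
        global_auc[[mode]][[m]][[met]] <- array(NA_real_, c(n_sub, n_run, nd))
      }
    }
  }
  for (s in seq_len(n_sub)) {
    for (m in methods) fc_vec[[m]][[s]] <- vector("list", n_run)
    for (mode in modes) for (m in methods) {
      for (met in c("nodal_efficiency", "nodal_betweenness")) {
        nodal_auc[[mode]][[m]][[met]][[s]] <- vector("list", n_run)
      }
    }
    for (r in seq_len(n_run)) {
      wins <- truncate_bins(recs[[s]][[r]], min_s, max_s, step_s)
      for (m in methods) {
        fcs <- lapply(wins, function(w) {
          if (m == "pearson") pearson_fc(w) else crosscorr_fc(w, max_lag_s)
        })
        fc_vec[[m]][[s]][[r]] <- lapply(fcs, vectorize_map)
        for (mode in modes) {
          profs <- lapply(fcs, network_metric_profile, grid = grid, mode = mode)
          for (met in c("nodal_efficiency", "nodal_betweenness")) {
            nodal_auc[[mode]][[m]][[met]][[s]][[r]] <-
              lapply(profs, function(p) p$nodal[[met]]$auc)
          }
          for (met in c("clustering_coefficient", "global_efficiency", "local_efficiency")) {
            global_auc[[mode]][[m]][[met]][s, r, ] <-
              vapply(profs, function(p) p$global[[met]]$auc, numeric(1))
          }
        }
      }
    }
  }

  map_metrics <- c("fc", "nodal_efficiency", "nodal_betweenness")
  glob_metrics <- c("clustering_coefficient", "global_efficiency", "local_efficiency")
  get_map <- function(metric, mode, m, s, r, d) {
    if (metric == "fc") fc_vec[[m]][[s]][[r]][[d]]
    else nodal_auc[[mode]][[m]][[metric]][[s]][[r]][[d]]
  }

  stab <- list()
  rel <- list()
  for (mode in modes) for (m in methods) {
    for (met in c(map_metrics, glob_metrics)) {
      if (met == "fc" && mode != modes[1]) next  # FC maps do not depend on mode
      for (d in seq_len(nd)) {
        if (met %in% map_metrics) {
          rs <- vapply(seq_len(n_sub), function(s) {
            stability_correlation(get_map(met, mode, m, s, reference_run, d),
                                  get_map(met, mode, m, s, reference_run, ref_d))$r
          }, numeric(1))
          stab[[length(stab) + 1L]] <- data.frame(
            metric = met, method = m, mode = if (met == "fc") "-" else mode,
            duration_s = durations[d], kind = "map_correlation",
            mean_r = mean(rs), sd_r = sd(rs), t = NA_real_, p = NA_real_)
          if (n_run >= 2) {
            br <- between_run_correlation(
              lapply(seq_len(n_sub), function(s) get_map(met, mode, m, s, 1, d)),
              lapply(seq_len(n_sub), function(s) get_map(met, mode, m, s, 2, d)))
            x1 <- do.call(rbind, lapply(seq_len(n_sub), function(s) get_map(met, mode, m, s, 1, d)))
            x2 <- do.call(rbind, lapply(seq_len(n_sub), function(s) get_map(met, mode, m, s, 2, d)))
            icc_val <- mean(icc_elementwise(x1, x2))
            rel[[length(rel) + 1L]] <- data.frame(
              metric = met, method = m, mode = if (met == "fc") "-" else mode,
              duration_s = durations[d], kind = "per_subject_r",
              mean_r = br$mean_r, sd_r = br$sd_r,
              icc = icc_val, icc_band = classify_icc(icc_val))
          }
        } else {
          tt <- if (n_sub >= 3) {
            stability_ttest(global_auc[[mode]][[m]][[met]][, reference_run, d],
                            global_auc[[mode]][[m]][[met]][, reference_run, ref_d])
          } else list(t = NA_real_, p = NA_real_)
          stab[[length(stab) + 1L]] <- data.frame(
            metric = met, method = m, mode = mode, duration_s = durations[d],
            kind = "paired_t", mean_r = NA_real_, sd_r = NA_real_,
            t = tt$t, p = tt$p)
          if (n_run >= 2 && n_sub >= 3) {
            br <- between_run_correlation(global_auc[[mode]][[m]][[met]][, 1, d],
                                          global_auc[[mode]][[m]][[met]][, 2, d],
                                          level = "across_subjects")
            icc_val <- icc(global_auc[[mode]][[m]][[met]][, 1:2, d])
            rel[[length(rel) + 1L]] <- data.frame(
              metric = met, method = m, mode = mode, duration_s = durations[d],
              kind = "across_subject_r", mean_r = br$r, sd_r = NA_real_,
              icc = icc_val, icc_band = classify_icc(icc_val))
          }
        }
      }
    }
  }
  structure(
    list(stability = do.call(rbind, stab),
         reliability = if (length(rel)) do.call(rbind, rel) else NULL,
         durations = durations, methods = methods, modes = modes,
         detail = list(fc_vec = fc_vec, nodal_auc = nodal_auc,
                       global_auc = global_auc)),
    class = "duration_sweep_result")
}

#' @export
print.duration_sweep_result <- function(x, ...) {
  cat(sprintf(
    "<duration_sweep_result> %d durations (%g-%g s) | methods: %s | modes: %s\n",
    length(x$durations), min(x$durations), max(x$durations),
    paste(x$methods, collapse = ", "), paste(x$modes, collapse = ", ")))
  cat(sprintf("  stability rows: %d | reliability rows: %d\n",
              nrow(x$stability),
              if (is.null(x$reliability)) 0L else nrow(x$reliability)))
  invisible(x)
}
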