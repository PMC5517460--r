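# File formats: TSV recordings with a small key-value header, matrix TSV,
# long-format results TSV, JSON config. All writes are atomic
# (temp file + rename).

atomic_write <- function(path, write_fn) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fn(tmp)
  if (!file.rename(tmp, path)) stop("failed to move temporary file onto ", path)
  invisible(path)
}

#' Write a recording as delimited text
#'
#' Layout: `#key<TAB>value` header lines (sampling rate, identifiers,
#' species), then one row per channel: channel id followed by the samples,
#' tab-separated.
#'
#' @param recording A `nirs_recording`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "nirs_recording"))
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("#sampling_rate_hz\t%.10g", recording$sampling_rate_hz),
      sprintf("#subject_id\t%s", recording$subject_id),
      sprintf("#run_id\t%s", recording$run_id),
      sprintf("#species\t%s", recording$species),
      sprintf("#n_channels\t%d", nrow(recording$data)),
      sprintf("#n_samples\t%d", ncol(recording$data))), con)
    utils::write.table(
      cbind(channel = rownames(recording$data),
            format(recording$data, digits = 17, trim = TRUE, scientific = TRUE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  })
}

#' Read a recording written by [write_recording()]
#'
#' Validates the layout and fails with informative errors on a missing
#' header, ragged rows, or non-finite cells.
#'
#' @param path Input file.
#' @return A `nirs_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such recording file: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0 || any(diff(hdr_idx) != 1) || hdr_idx[1] != 1) {
    stop(path, ": expected a leading block of #key<TAB>value header lines")
  }
  hdr <- strsplit(sub("^#", "", lines[hdr_idx]), "\t", fixed = TRUE)
  keys <- vapply(hdr, `[`, "", 1)
  vals <- vapply(hdr, `[`, "", 2)
  need <- c("sampling_rate_hz", "species")
  if (!all(need %in% keys)) {
    stop(path, ": header is missing required key(s): ",
         paste(setdiff(need, keys), collapse = ", "))
  }
  get <- function(k, default = NA) if (k %in% keys) vals[keys == k] else default
  body <- lines[-hdr_idx]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, length(hdr_idx) + bad, lens[bad], lens[1]))
  }
  ids <- vapply(parts, `[`, "", 1)
  data <- do.call(rbind, lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1]))
    if (anyNA(v)) {
      col <- which(is.na(v))[1]
      stop(sprintf("%s: non-numeric or missing cell at line %d (channel %s), sample column %d",
                   path, length(hdr_idx) + i, ids[i], col))
    }
    v
  }))
  rownames(data) <- ids
  new_recording(data, as.numeric(get("sampling_rate_hz")),
                subject_id = get("subject_id", "S01"),
                run_id = get("run_id", "1"),
                species = get("species"))
}

#' Write a square matrix (FC or adjacency) as TSV with channel-id header
#'
#' @param m Matrix (or `connectivity_matrix`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "connectivity_matrix")) m <- m$values
  atomic_write(path, function(tmp) {
    utils::write.table(format(m, digits = 17, trim = TRUE),
                       tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !is.null(colnames(m)))
  })
}

#' Read a square matrix TSV written by [write_matrix_tsv()]
#' @param path Input file.
#' @param header Whether the file has a channel-id header row.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("no such matrix file: ", path)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = header,
                                   check.names = FALSE))
  if (header) rownames(m) <- colnames(m)
  m
}

#' Write a long-format results table as TSV
#' @param df Data frame (e.g. `stability` / `reliability` from
#'   [run_duration_sweep()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Pipeline configuration with every tunable default
#'
#' Central registry of the thresholds and defaults used across the
#' pipeline; values may be overridden individually. Defaults equal the
#' stated acquisition/analysis values where such exist (band 0.01-0.1 Hz,
#' sparsity 0.17-0.50 step 0.01, 30-s duration bins from 60 to 600 s,
#' 46 channels at 25 Hz).
#'
#' @param ... Named overrides of any default field.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    band_low_hz = 0.01, band_high_hz = 0.1, filter_order = 3,
    pca_variance_retained = 0.99,
    jump_sd = 1, spike_rate_per_min = 5, ushape_r2 = 0.8,
    dispersion_kurtosis = 1.5,
    max_lag_s = 20, min_overlap_frac = 0.5,
    sparsity_min = 0.17, sparsity_max = 0.50, sparsity_step = 0.01,
    edge_rounding = "half_up",
    icc_cuts = c(fair = 0.4, good = 0.6, excellent = 0.75),
    species = "HbO",
    duration_min_s = 60, duration_max_s = 600, duration_step_s = 30,
    n_subjects = 18, n_runs = 2, n_channels = 46, sampling_rate_hz = 25,
    artifact_scale = 1, gt_within_r = 0.5, gt_between_r = 0.15,
    gt_modules = 4, coupling_mean = 0.6, seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  stopifnot(cfg$band_low_hz > 0, cfg$band_low_hz < cfg$band_high_hz,
            cfg$band_high_hz < cfg$sampling_rate_hz / 2,
            cfg$sparsity_min > 0, cfg$sparsity_max < 1,
            cfg$sparsity_min <= cfg$sparsity_max, cfg$sparsity_step > 0)
  cfg
}

config_sparsity_grid <- function(cfg) {
  seq(round(cfg$sparsity_min * 100), round(cfg$sparsity_max * 100),
      by = round(cfg$sparsity_step * 100)) / 100
}

#' Write / read a pipeline configuration as JSON
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @return `path` / the configuration.
#' @export
write_config <- function(cfg, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[names(raw) %in% names(pipeline_config())])
}
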