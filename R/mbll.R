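# Beer-Lambert forward model and inversion between optical density and
# hemoglobin concentration changes.

#' Default extinction coefficients
#'
#' Molar extinction coefficients of HbO and HbR (1/(mM cm)) at the two
#' laser wavelengths of a typical continuous-wave system (690 and 830 nm),
#' rounded literature values. Rows are wavelengths, columns chromophores.
#'
#' @return 2 x 2 numeric matrix with dimnames.
#' @export
default_extinction <- function() {
  matrix(c(0.35, 2.10,
           1.06, 0.74),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("690nm", "830nm"), c("HbO", "HbR")))
}

check_extinction <- function(extinction) {
  extinction <- as.matrix(extinction)
  stopifnot(all(dim(extinction) == c(2, 2)))
  if (abs(det(extinction)) < 1e-12) {
    stop("extinction matrix is singular; wavelength pair cannot separate HbO/HbR")
  }
  kappa <- kappa(extinction, exact = TRUE)
  if (kappa > 100) {
    warning(sprintf("extinction matrix is ill-conditioned (condition number %.1f)", kappa))
  }
  extinction
}

#' Forward Beer-Lambert model: concentrations to optical density
#'
#' Computes the two-wavelength optical-density change produced by given
#' HbO/HbR concentration changes under the modified Beer-Lambert law:
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * 1e-3 *
#' separation_cm * dpf(lambda)` (the `1e-3` converts micromolar
#' concentrations to the millimolar units of the extinction coefficients).
#'
#' @param hbo A `nirs_recording` with `species = "HbO"`.
#' @param hbr Optional matching `nirs_recording` with `species = "HbR"`;
#'   when omitted, a typical anticorrelated surrogate `-0.3 * HbO` is used.
#' @param extinction 2 x 2 extinction matrix (wavelengths x chromophores).
#' @param dpf Differential pathlength factor per wavelength (length 2).
#' @param separation_cm Source-detector separation in cm.
#' @return An object of class `od_series`: list with channels x samples
#'   matrices `od` (per wavelength), sampling rate and identifiers.
#' @export
simulate_optical_density <- function(hbo, hbr = NULL,
                                     extinction = default_extinction(),
                                     dpf = c(6, 6), separation_cm = 3.2) {
  stopifnot(inherits(hbo, "nirs_recording"), hbo$species == "HbO",
            length(dpf) == 2, separation_cm > 0)
  extinction <- check_extinction(extinction)
  if (is.null(hbr)) {
    hbr <- hbo
    hbr$data <- -0.3 * hbo$data
    hbr$species <- "HbR"
  }
  stopifnot(inherits(hbr, "nirs_recording"), hbr$species == "HbR",
            all(dim(hbr$data) == dim(hbo$data)))
  od <- lapply(1:2, function(w) {
    (extinction[w, "HbO"] * hbo$data + extinction[w, "HbR"] * hbr$data) *
      1e-3 * separation_cm * dpf[w]
  })
  names(od) <- rownames(extinction)
  structure(
    list(od = od, sampling_rate_hz = hbo$sampling_rate_hz,
         subject_id = hbo$subject_id, run_id = hbo$run_id,
         channel_layout = hbo$channel_layout,
         extinction = extinction, dpf = dpf, separation_cm = separation_cm),
    class = "od_series")
}

#' @export
print.od_series <- function(x, ...) {
  cat(sprintf("<od_series> wavelengths %s | %d channels x %d samples @ %g Hz\n",
              paste(names(x$od), collapse = "/"),
              nrow(x$od[[1]]), ncol(x$od[[1]]), x$sampling_rate_hz))
  invisible(x)
}

#' Modified Beer-Lambert conversion: optical density to concentrations
#'
#' Inverts the 2 x 2 linear system of [simulate_optical_density()] per
#' channel and sample, recovering HbO and HbR concentration changes
#' (micromolar) from two-wavelength optical-density changes.
#'
#' @param od An `od_series`.
#' @param extinction,dpf,separation_cm Forward-model parameters; default to
#'   the values stored in `od`.
#' @return A list with `nirs_recording` elements `HbO` and `HbR`.
#' @export
mbll_convert <- function(od, extinction = od$extinction, dpf = od$dpf,
                         separation_cm = od$separation_cm) {
  stopifnot(inherits(od, "od_series"), length(dpf) == 2, separation_cm > 0)
  extinction <- check_extinction(extinction)
  # effective absorption per unit concentration, including pathlength
  A <- extinction * 1e-3 * separation_cm * dpf   # rows scaled by dpf[w]
  Ainv <- solve(A)
  n_ch <- nrow(od$od[[1]])
  n_s <- ncol(od$od[[1]])
  stacked <- rbind(as.vector(od$od[[1]]), as.vector(od$od[[2]]))
  conc <- Ainv %*% stacked
  out <- lapply(1:2, function(k) {
    m <- matrix(conc[k, ], n_ch, n_s)
    rownames(m) <- rownames(od$od[[1]])
    new_recording(m, od$sampling_rate_hz, subject_id = od$subject_id,
                  run_id = od$run_id, species = c("HbO", "HbR")[k],
                  channel_layout = od$channel_layout)
  })
  names(out) <- c("HbO", "HbR")
  out
}
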