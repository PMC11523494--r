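#' Topographic-analysis configuration
#'
#' Collects every tunable of the preprocessing chain and of the six metrics.
#' Defaults reproduce the standard protocol for chewing-surface scans:
#' decimation to ~10 000 triangles, Taubin smoothing (lambda 0.9, mu -0.95,
#' 10 iterations), DNE with the top 1% of energy-times-area contributions
#' trimmed and boundary triangles included, OPCR with 8 rotations of 5.625
#' degrees and a minimum patch size of 3 faces, and PCV with 256 directions
#' on the northern (occlusal, +z) hemisphere.
#'
#' @param decimate_target target face count for decimation.
#' @param taubin_lambda,taubin_mu,taubin_iters Taubin smoothing constants.
#' @param dne_outlier_quantile fraction of top contributions trimmed
#'   (count-based; 0.01 = "DNE 99%"; 0 disables trimming).
#' @param dne_boundary_mode `"include"` (default) or `"exclude"` boundary
#'   triangles from the DNE sum.
#' @param dne_trim_mode `"count"` (default; drop the top `ceiling(q*F)`
#'   faces) or `"mass"` (drop the smallest face set carrying the top `q`
#'   fraction of total energy-times-area).
#' @param opcr_rotations,opcr_step_deg number and step (degrees) of the
#'   z-rotations averaged by OPCR.
#' @param opcr_bins number of azimuth bins (8 compass sectors).
#' @param opcr_min_patch minimum faces for a patch to be counted.
#' @param opcr_slope_tol_deg faces whose normal is within this angle of
#'   vertical are "flat" and carry no aspect.
#' @param pcv_count number of visibility directions.
#' @param pcv_hemisphere `"north"` (only +z directions).
#' @param oa_mode `"union"` (exact union of projected triangles, default)
#'   or `"alpha_auto"` (alpha shape of projected vertices, alpha from an
#'   automated sweep).
#' @param component_min_faces isolated-piece cutoff for [clean_mesh];
#'   `NULL` means 1% of the face total.
#' @param rfi_half_log use the half-log (square-root) relief convention
#'   (default `TRUE`); `FALSE` gives the raw log ratio.
#' @return an object of class `topo_config`.
#' @export
topo_config <- function(decimate_target = 10000L,
                        taubin_lambda = 0.9,
                        taubin_mu = -0.95,
                        taubin_iters = 10L,
                        dne_outlier_quantile = 0.01,
                        dne_boundary_mode = c("include", "exclude"),
                        dne_trim_mode = c("count", "mass"),
                        opcr_rotations = 8L,
                        opcr_step_deg = 5.625,
                        opcr_bins = 8L,
                        opcr_min_patch = 3L,
                        opcr_slope_tol_deg = 0.1,
                        pcv_count = 256L,
                        pcv_hemisphere = "north",
                        oa_mode = c("union", "alpha_auto"),
                        component_min_faces = NULL,
                        rfi_half_log = TRUE) {
  dne_boundary_mode <- match.arg(dne_boundary_mode)
  dne_trim_mode <- match.arg(dne_trim_mode)
  oa_mode <- match.arg(oa_mode)
  stopifnot(decimate_target >= 4, taubin_iters >= 0,
            dne_outlier_quantile >= 0, dne_outlier_quantile < 1,
            opcr_rotations >= 1, opcr_step_deg > 0, opcr_bins >= 2,
            opcr_min_patch >= 1, opcr_slope_tol_deg >= 0,
            pcv_count >= 1, identical(pcv_hemisphere, "north"))
  if (opcr_step_deg * opcr_rotations > 360 / opcr_bins + opcr_step_deg)
    stop("opcr rotations sweep more than one bin width")
  if (!is.null(component_min_faces) && component_min_faces < 1)
    stop("component_min_faces must be >= 1 or NULL")
  structure(list(decimate_target = as.integer(decimate_target),
                 taubin_lambda = taubin_lambda, taubin_mu = taubin_mu,
                 taubin_iters = as.integer(taubin_iters),
                 dne_outlier_quantile = dne_outlier_quantile,
                 dne_boundary_mode = dne_boundary_mode,
                 dne_trim_mode = dne_trim_mode,
                 opcr_rotations = as.integer(opcr_rotations),
                 opcr_step_deg = opcr_step_deg,
                 opcr_bins = as.integer(opcr_bins),
                 opcr_min_patch = as.integer(opcr_min_patch),
                 opcr_slope_tol_deg = opcr_slope_tol_deg,
                 pcv_count = as.integer(pcv_count),
                 pcv_hemisphere = pcv_hemisphere,
                 oa_mode = oa_mode,
                 component_min_faces = component_min_faces,
                 rfi_half_log = isTRUE(rfi_half_log)),
            class = "topo_config")
}

#' @export
print.topo_config <- function(x, ...) {
  cat("topo_config\n")
  cat(sprintf("  decimate to ~%d faces; Taubin(%g, %g) x %d\n",
              x$decimate_target, x$taubin_lambda, x$taubin_mu, x$taubin_iters))
  cat(sprintf("  DNE trim %.3g (%s, boundary %s); OPCR %d x %g deg, %d bins, min patch %d, flat tol %g deg\n",
              x$dne_outlier_quantile, x$dne_trim_mode, x$dne_boundary_mode,
              x$opcr_rotations, x$opcr_step_deg, x$opcr_bins,
              x$opcr_min_patch, x$opcr_slope_tol_deg))
  cat(sprintf("  PCV %d dirs (%s); OA %s; RFI %s-log\n", x$pcv_count,
              x$pcv_hemisphere, x$oa_mode,
              if (x$rfi_half_log) "half" else "raw"))
  invisible(x)
}

# short deterministic fingerprint of a config for provenance columns
config_hash <- function(config) {
  s <- paste(vapply(config, function(v) paste(format(v, digits = 15),
                                              collapse = ","), ""),
             collapse = ";")
  # multiplicative string hash, 31 bit (stays in exact-double range)
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
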