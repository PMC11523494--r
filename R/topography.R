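#' Compute the full topographic profile of a molar surface
#'
#' Runs all six metrics — DNE (with convex/concave split), RFI, OPCR, PCV,
#' 3D surface area and 2D projected occlusal area — on one mesh and returns
#' them with the per-element fields needed for metric maps. Deterministic:
#' identical mesh and config give a bit-identical result.
#'
#' @param mesh a [trimesh]; expected already preprocessed (clean, decimated,
#'   smoothed, occlusal-up) unless `preprocess = TRUE`.
#' @param config a [topo_config].
#' @param preprocess run [clean_mesh], [decimate] and [taubin_smooth] first.
#' @return an object of class `topography_result`: list with `dne_total`,
#'   `dne_convex`, `dne_concave`, `rfi`, `opcr`, `opc_per_rotation`, `pcv`,
#'   `pcv_unweighted`, `sa3d`, `oa2d`, `alpha_used`, `face_dne`,
#'   `face_opc_bin`, `vertex_pcv`, `n_faces`.
#' @export
topography <- function(mesh, config = topo_config(), preprocess = FALSE) {
  stopifnot_trimesh(mesh)
  if (preprocess) {
    mesh <- clean_mesh(mesh, config)
    mesh <- decimate(mesh, config$decimate_target)
    mesh <- taubin_smooth(mesh, config$taubin_lambda, config$taubin_mu,
                          config$taubin_iters)
  }
  d <- dne(mesh, config)
  pa <- projected_area(mesh, config)
  sa <- surface_area(mesh)
  oc <- opcr(mesh, config)
  pv <- pcv(mesh, config)
  structure(list(
    dne_total = d$dne_total, dne_convex = d$dne_convex,
    dne_concave = d$dne_concave,
    rfi = rfi_from_areas(sa, pa$oa2d, config$rfi_half_log),
    opcr = oc$opcr, opc_per_rotation = oc$opc_per_rotation,
    pcv = pv$pcv, pcv_unweighted = pv$pcv_unweighted,
    sa3d = sa, oa2d = pa$oa2d, alpha_used = pa$alpha,
    face_dne = d$face_dne, face_convex = d$face_convex,
    face_opc_bin = oc$face_opc_bin,
    vertex_pcv = pv$vertex_pcv,
    n_faces = nrow(mesh$faces)), class = "topography_result")
}

#' @export
print.topography_result <- function(x, ...) {
  cat("topography_result (", x$n_faces, " faces)\n", sep = "")
  cat(sprintf("  DNE  %10.3f  (convex %.3f + concave %.3f)\n",
              x$dne_total, x$dne_convex, x$dne_concave))
  cat(sprintf("  RFI  %10.4f\n", x$rfi))
  cat(sprintf("  OPCR %10.3f  (per rotation: %s)\n", x$opcr,
              paste(x$opc_per_rotation, collapse = " ")))
  cat(sprintf("  PCV  %10.4f  (unweighted %.4f)\n", x$pcv, x$pcv_unweighted))
  cat(sprintf("  SA3D %10.4f mm^2   OA2D %.4f mm^2\n", x$sa3d, x$oa2d))
  invisible(x)
}

#' Flatten a topography result to a one-row data frame
#'
#' @param x a `topography_result`.
#' @param ... unused.
#' @return a one-row data frame with the scalar metrics.
#' @export
as.data.frame.topography_result <- function(x, ...) {
  data.frame(dne = x$dne_total, dne_convex = x$dne_convex,
             dne_concave = x$dne_concave, rfi = x$rfi, opcr = x$opcr,
             pcv = x$pcv, sa3d = x$sa3d, oa2d = x$oa2d,
             faces_after_preprocess = x$n_faces,
             alpha_used = x$alpha_used)
}
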