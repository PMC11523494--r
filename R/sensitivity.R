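#' Population coefficient of variation
#'
#' Population (divide-by-n) standard deviation over the mean. All-zero
#' input returns 0; a zero mean with nonzero spread is an error because the
#' CV is undefined there.
#'
#' @param values numeric vector, length >= 2.
#' @return the CV (dimensionless, >= 0).
#' @export
cv_pop <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values for a CV")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (m == 0) {
    if (s == 0) return(0)
    stop("CV undefined: mean is 0 with nonzero spread")
  }
  abs(s / m)
}

#' Orientation-sensitivity protocol
#'
#' Quantifies how much each topographic metric depends on the (partly
#' subjective) occlusal alignment: the mesh is tilted clockwise and
#' anticlockwise about the x- and y-axes by `tilt_deg`, giving five
#' variants (original, +x, -x, +y, -y); every requested metric is computed
#' on each variant and summarised as a population CV. Rigid-motion
#' invariant metrics (DNE, 3D SA) give CVs at numerical zero; projection-
#' dependent metrics (RFI, OPCR, PCV, 2D OA) do not.
#'
#' @param mesh an oriented [trimesh].
#' @param tilt_deg tilt angle in degrees (> 0; default 5, small enough to
#'   stay "approximately occlusal" while moving the projection).
#' @param config a [topo_config].
#' @param metrics which metrics to evaluate (default all six).
#' @return an object of class `sensitivity_report`: data frame with one row
#'   per metric (`metric`, the five variant values, `mean`, `sd_pop`, `cv`)
#'   plus a `variants` attribute describing axis and angle.
#' @export
orientation_sensitivity <- function(mesh, tilt_deg = 5, config = topo_config(),
                                    metrics = c("dne", "rfi", "opcr", "pcv",
                                                "sa3d", "oa2d")) {
  stopifnot_trimesh(mesh)
  if (tilt_deg < 0) stop("tilt_deg must be >= 0")
  metrics <- match.arg(metrics, several.ok = TRUE)
  variants <- list(original = mesh,
                   x_plus = rotate_mesh(mesh, "x", tilt_deg),
                   x_minus = rotate_mesh(mesh, "x", -tilt_deg),
                   y_plus = rotate_mesh(mesh, "y", tilt_deg),
                   y_minus = rotate_mesh(mesh, "y", -tilt_deg))
  vals <- sapply(variants, function(mm) {
    out <- c()
    if (any(c("rfi", "oa2d") %in% metrics)) pa <- projected_area(mm, config)
    if (any(c("rfi", "sa3d") %in% metrics)) sa <- surface_area(mm)
    for (met in metrics) {
      out[met] <- switch(met,
        dne = dne(mm, config)$dne_total,
        rfi = rfi_from_areas(sa, pa$oa2d, config$rfi_half_log),
        opcr = opcr(mm, config)$opcr,
        pcv = pcv(mm, config)$pcv,
        sa3d = sa,
        oa2d = pa$oa2d)
    }
    out
  })
  vals <- matrix(vals, nrow = length(metrics),
                 dimnames = list(metrics, names(variants)))
  rep_df <- data.frame(metric = metrics,
                       as.data.frame(vals),
                       mean = rowMeans(vals),
                       sd_pop = apply(vals, 1L, function(v)
                         sqrt(mean((v - mean(v))^2))),
                       row.names = NULL)
  rep_df$cv <- ifelse(rep_df$mean == 0 & rep_df$sd_pop == 0, 0,
                      abs(rep_df$sd_pop / rep_df$mean))
  attr(rep_df, "variants") <- data.frame(
    variant = names(variants),
    axis = c(NA, "x", "x", "y", "y"),
    angle_deg = c(0, tilt_deg, -tilt_deg, tilt_deg, -tilt_deg))
  class(rep_df) <- c("sensitivity_report", "data.frame")
  rep_df
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("orientation sensitivity (population CV across 5 variants)\n")
  print.data.frame(x, digits = 6)
  invisible(x)
}
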