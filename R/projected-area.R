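#' Two-dimensional projected occlusal area
#'
#' Area of the mesh footprint on the z = 0 plane, the denominator of the
#' relief index. Mode `"union"` (default) computes the exact area of the
#' union of all projected triangles and is parameter-free. Mode
#' `"alpha_auto"` takes the alpha shape of the projected vertices, sweeping
#' alpha over a geometric grid upward from the mean projected edge length
#' until the shape is a single polygon containing every projected point,
#' and reports the alpha used. When both modes disagree by more than 5%
#' the result is flagged (`check2d_flag`), which usually means the alpha
#' shape bridged a genuine concavity or the projection folds over itself.
#'
#' @param mesh a [trimesh] oriented occlusal-up.
#' @param config a [topo_config] (`oa_mode` selects the mode).
#' @return a list: `oa2d` (mm^2), `mode`, `alpha` (NA for union mode),
#'   `check2d_flag` (logical; only evaluated in alpha mode).
#' @export
projected_area <- function(mesh, config = topo_config()) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  rx <- range(v[, 1L]); ry <- range(v[, 2L])
  if (diff(rx) <= 0 && diff(ry) <= 0)
    stop("degenerate projection: mesh projects to a point")
  if (diff(rx) <= 1e-12 * diff(ry) || diff(ry) <= 1e-12 * diff(rx))
    stop("degenerate projection: mesh projects to a line")
  px <- matrix(v[f, 1L], ncol = 3L)
  py <- matrix(v[f, 2L], ncol = 3L)
  a_union <- .union_area_cpp(px, py)
  if (config$oa_mode == "union")
    return(list(oa2d = a_union, mode = "union", alpha = NA_real_,
                check2d_flag = FALSE))
  as <- alpha_shape_area(mesh)
  flag <- is.finite(a_union) && a_union > 0 &&
    abs(as$area - a_union) / a_union > 0.05
  if (flag)
    warning(sprintf("projected areas disagree: union %.4g vs alpha %.4g",
                    a_union, as$area))
  list(oa2d = as$area, mode = "alpha_auto", alpha = as$alpha,
       check2d_flag = flag)
}

# alpha-complex area of the projected vertices with an automated alpha sweep
alpha_shape_area <- function(mesh) {
  v <- mesh$vertices
  xy <- v[, 1:2, drop = FALSE]
  # drop exact duplicates (vertical walls project onto each other)
  key <- paste(signif(xy[, 1L], 12), signif(xy[, 2L], 12))
  xy <- xy[!duplicated(key), , drop = FALSE]
  tri <- .delaunay_cpp(xy[, 1L], xy[, 2L])
  ax <- xy[tri[, 1L], 1L]; ay <- xy[tri[, 1L], 2L]
  bx <- xy[tri[, 2L], 1L]; by <- xy[tri[, 2L], 2L]
  cx <- xy[tri[, 3L], 1L]; cy <- xy[tri[, 3L], 2L]
  la <- sqrt((bx - cx)^2 + (by - cy)^2)
  lb <- sqrt((ax - cx)^2 + (ay - cy)^2)
  lc <- sqrt((ax - bx)^2 + (ay - by)^2)
  areas <- 0.5 * abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  circ <- la * lb * lc / (4 * pmax(areas, .Machine$double.xmin))
  # mean projected edge length over the Delaunay edges
  alpha0 <- mean(c(la, lb, lc))
  n <- nrow(xy)
  for (alpha in alpha0 * 1.3^(0:40)) {
    keep <- circ <= alpha
    if (!any(keep)) next
    kt <- tri[keep, , drop = FALSE]
    if (length(unique(as.vector(kt))) < n) next
    if (!alpha_complex_connected(kt)) next
    return(list(area = sum(areas[keep]), alpha = alpha))
  }
  # fall back to the full triangulation (convex hull)
  list(area = sum(areas), alpha = Inf)
}

alpha_complex_connected <- function(tri) {
  verts <- unique(as.vector(tri))
  id <- match(tri, verts)
  dim(id) <- dim(tri)
  parent <- seq_along(verts)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(id))) {
    parent[find(id[i, 2L])] <- find(id[i, 1L])
    parent[find(id[i, 3L])] <- find(id[i, 1L])
  }
  length(unique(vapply(seq_along(verts), find, 1L))) == 1L
}

#' Relief index
#'
#' Log ratio of the 3D surface area to its 2D projected (occlusal) area:
#' `0.5 * log(sa3d / oa2d)` under the default half-log (square-root)
#' convention, or `log(sa3d / oa2d)` with `rfi_half_log = FALSE`. A proxy
#' for relative crown height: 0 for a flat sheet, growing with relief.
#'
#' @param mesh a [trimesh] oriented occlusal-up.
#' @param config a [topo_config].
#' @return the relief index (dimensionless).
#' @export
rfi <- function(mesh, config = topo_config()) {
  sa <- surface_area(mesh)
  oa <- projected_area(mesh, config)$oa2d
  rfi_from_areas(sa, oa, half_log = config$rfi_half_log)
}

#' Relief index from precomputed areas
#'
#' @param sa3d 3D surface area (mm^2).
#' @param oa2d 2D projected area (mm^2).
#' @param half_log use the half-log convention (default).
#' @return the relief index.
#' @export
rfi_from_areas <- function(sa3d, oa2d, half_log = TRUE) {
  if (any(oa2d <= 0)) stop("projected area must be positive")
  if (any(sa3d < oa2d * (1 - 1e-9)))
    warning("3D area below projected area: check mesh orientation")
  (if (half_log) 0.5 else 1) * log(sa3d / oa2d)
}
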