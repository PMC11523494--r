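#' Ambient-occlusion wear-resistance (PCV, portion de ciel visible)
#'
#' For each vertex, the fraction of `pcv_count` sky directions (a
#' deterministic Fibonacci-spiral layout on the +z hemisphere) that are
#' neither behind the local surface (`d . n <= 0`) nor blocked by any other
#' part of the mesh along a ray from the vertex. Rays start a small offset
#' (1e-4 of the bounding-box diagonal) along the vertex normal to avoid
#' self-intersection. The molar-level PCV is the area-weighted mean of the
#' per-vertex values (weights = one third of the incident triangle areas);
#' the unweighted mean is reported alongside. Higher values mean a flatter,
#' more exposed — more wear-resistant — surface.
#'
#' @param mesh a [trimesh] oriented occlusal-up.
#' @param config a [topo_config].
#' @return a list: `pcv` (area-weighted mean, in [0,1]), `pcv_unweighted`,
#'   `vertex_pcv` (per-vertex fraction of visible directions).
#' @export
pcv <- function(mesh, config = topo_config()) {
  stopifnot_trimesh(mesh)
  dirs <- pcv_directions(config$pcv_count)
  vn <- if (!is.null(mesh$normals)) mesh$normals else vertex_normals(mesh)
  offset <- 1e-4 * bbox_diag(mesh)
  res <- .pcv_cpp(mesh$vertices, mesh$faces, vn, dirs, offset)
  vertex_pcv <- res$seen / config$pcv_count
  w <- vertex_area_weights(mesh)
  list(pcv = sum(w * vertex_pcv) / sum(w),
       pcv_unweighted = mean(vertex_pcv),
       vertex_pcv = vertex_pcv)
}

# deterministic Fibonacci-spiral directions on the northern hemisphere
pcv_directions <- function(count) {
  i <- seq_len(count) - 1L
  z <- (i + 0.5) / count
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))  # golden angle
  cbind(r * cos(phi), r * sin(phi), z)
}

# one third of the summed incident triangle areas per vertex
vertex_area_weights <- function(mesh) {
  a <- face_areas(mesh)
  w <- numeric(nrow(mesh$vertices))
  acc <- rowsum(rep(a / 3, 3L), c(mesh$faces[, 1L], mesh$faces[, 2L],
                                  mesh$faces[, 3L]))
  w[as.integer(rownames(acc))] <- acc
  w
}
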