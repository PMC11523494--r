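#' Orientation patch count rotated (OPCR)
#'
#' Counts the "tools" of the occlusal surface: every face steeper than the
#' flatness tolerance is assigned to one of `opcr_bins` azimuth sectors
#' (45-degree sectors centred on the 8 compass directions, boundaries at
#' 22.5 + k*45 degrees); edge-connected runs of same-sector faces form
#' patches; patches below `opcr_min_patch` faces are discarded. The patch
#' count is averaged over `opcr_rotations` rotations of the mesh about z in
#' steps of `opcr_step_deg` to soften the arbitrariness of the sector
#' boundaries.
#'
#' @param mesh a [trimesh] oriented occlusal-up.
#' @param config a [topo_config].
#' @return a list: `opcr` (mean patch count, possibly fractional),
#'   `opc_per_rotation` (integer vector), `face_opc_bin` (sector label per
#'   face at rotation 0; 0 = flat/unbinned).
#' @export
opcr <- function(mesh, config = topo_config()) {
  stopifnot_trimesh(mesh)
  fn <- face_normals(mesh)
  adj <- face_adjacency(mesh)
  counts <- integer(config$opcr_rotations)
  bins0 <- NULL
  for (k in seq_len(config$opcr_rotations) - 1L) {
    th <- -k * config$opcr_step_deg * pi / 180  # rotate mesh by +k*step == normals azimuth - k*step
    az <- atan2(fn[, 2L], fn[, 1L]) + th
    bins <- opcr_bin_faces(fn, az, config)
    if (k == 0L) bins0 <- bins
    counts[k + 1L] <- opcr_count_patches(bins, adj, config$opcr_min_patch)
  }
  list(opcr = mean(counts), opc_per_rotation = counts, face_opc_bin = bins0)
}

# sector index per face (0 = flat); az in radians
opcr_bin_faces <- function(fn, az, config) {
  slope <- acos(pmin(1, pmax(-1, abs(fn[, 3L])))) * 180 / pi
  nb <- config$opcr_bins
  width <- 2 * pi / nb
  # sectors centred on 0, 45, ... => shift by half a width
  b <- (floor((az + width / 2) / width) %% nb) + 1L
  b[slope <= config$opcr_slope_tol_deg] <- 0L
  as.integer(b)
}

# union-find over same-bin adjacent faces; count patches >= min_patch
opcr_count_patches <- function(bins, adj, min_patch) {
  m <- length(bins)
  keep <- adj[bins[adj[, 1L]] == bins[adj[, 2L]] & bins[adj[, 1L]] != 0L, ,
              drop = FALSE]
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(keep)) for (i in seq_len(nrow(keep)))
    parent[find(keep[i, 2L])] <- find(keep[i, 1L])
  binned <- which(bins != 0L)
  if (!length(binned)) return(0L)
  roots <- vapply(binned, find, 1L)
  sum(tabulate(match(roots, unique(roots))) >= min_patch)
}
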