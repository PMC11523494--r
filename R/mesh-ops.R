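#' Clean a mesh before topographic analysis
#'
#' Removes zero-area faces, unreferenced (floating) vertices and connected
#' components smaller than the isolated-piece threshold, compacts indices
#' and unifies face winding so outward normals are well defined. Idempotent.
#'
#' @param mesh a [trimesh].
#' @param config a [topo_config]; `component_min_faces` may be a count or,
#'   when `NULL`, defaults to 1% of the face total.
#' @return the cleaned [trimesh].
#' @export
clean_mesh <- function(mesh, config = topo_config()) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  a <- face_areas(mesh)
  eps <- (bbox_diag(mesh) * 1e-12)^2
  f <- f[a > eps, , drop = FALSE]
  if (nrow(f) == 0L) stop("cleaning removed every face: mesh is degenerate")

  # drop small connected components
  minf <- config$component_min_faces
  if (is.null(minf)) minf <- ceiling(0.01 * nrow(f))
  if (minf > 1L) {
    comp <- face_components(f, nrow(v))
    keep <- comp %in% which(tabulate(comp) >= minf)
    if (!any(keep)) stop("cleaning removed every face: all components below threshold")
    f <- f[keep, , drop = FALSE]
  }

  # drop unreferenced vertices, compact indices
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  v <- v[used, , drop = FALSE]
  f <- matrix(remap[f], ncol = 3L)

  out <- trimesh(v, f)
  unify_winding(out)
}

# connected components of faces over shared vertices (union-find)
face_components <- function(f, nv) {
  parent <- seq_len(nv)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(f))) {
    r1 <- find(f[i, 1L]); r2 <- find(f[i, 2L]); r3 <- find(f[i, 3L])
    parent[r2] <- r1; parent[find(r3)] <- find(r1)
  }
  roots <- vapply(f[, 1L], find, 1L)
  match(roots, unique(roots))
}

# orient faces so that winding is consistent across shared edges, then flip
# globally (per component) so mean normal z is >= 0 (occlusal-up convention)
unify_winding <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  adj <- face_adjacency(mesh)
  # CSR-style neighbour lists
  src <- c(adj[, 1L], adj[, 2L]); dst <- c(adj[, 2L], adj[, 1L])
  o <- order(src); src <- src[o]; dst <- dst[o]
  ptr <- c(0L, cumsum(tabulate(src, nbins = m)))
  visited <- logical(m)
  flip <- logical(m)
  has_dir_edge <- function(tri, a, b) {
    (tri[1L] == a && tri[2L] == b) || (tri[2L] == a && tri[3L] == b) ||
      (tri[3L] == a && tri[1L] == b)
  }
  stack <- integer(m)
  for (s in seq_len(m)) {
    if (visited[s]) next
    top <- 1L; stack[1L] <- s; visited[s] <- TRUE
    comp <- integer(m); ncomp <- 0L
    while (top > 0L) {
      i <- stack[top]; top <- top - 1L
      ncomp <- ncomp + 1L; comp[ncomp] <- i
      ti <- if (flip[i]) f[i, c(1L, 3L, 2L)] else f[i, ]
      lo <- ptr[i] + 1L; hi <- ptr[i + 1L]
      if (hi < lo) next
      for (j in dst[lo:hi]) {
        if (visited[j]) next
        tj <- f[j, ]
        # consistent winding: the shared directed edge must appear in the
        # same direction in ti and tj only if j needs flipping
        same_dir <- has_dir_edge(tj, ti[1L], ti[2L]) ||
          has_dir_edge(tj, ti[2L], ti[3L]) || has_dir_edge(tj, ti[3L], ti[1L])
        flip[j] <- same_dir
        visited[j] <- TRUE
        top <- top + 1L; stack[top] <- j
      }
    }
    comp <- comp[seq_len(ncomp)]
    fc <- f[comp, , drop = FALSE]
    fc[flip[comp], ] <- fc[flip[comp], c(1L, 3L, 2L), drop = FALSE]
    sub <- trimesh(mesh$vertices, fc)
    fn <- face_normals(sub); ar <- face_areas(sub)
    if (sum(fn[, 3L] * ar) < 0) fc <- fc[, c(1L, 3L, 2L), drop = FALSE]
    f[comp, ] <- fc
  }
  trimesh(mesh$vertices, f)
}

#' Rigid rotation about a coordinate axis
#'
#' Right-handed rotation about the origin of the input coordinates.
#'
#' @param mesh a [trimesh].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle rotation angle in degrees (positive = anticlockwise looking
#'   down the axis toward the origin).
#' @return the rotated [trimesh] (connectivity unchanged).
#' @export
rotate_mesh <- function(mesh, axis = c("x", "y", "z"), angle) {
  stopifnot_trimesh(mesh)
  axis <- match.arg(axis)
  th <- angle * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  R <- switch(axis,
    x = matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3L),
    y = matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3L),
    z = matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3L))
  out <- mesh
  out$vertices <- mesh$vertices %*% t(R)
  if (!is.null(mesh$normals)) out$normals <- mesh$normals %*% t(R)
  out
}

#' Three-dimensional surface area
#'
#' Sum of triangle areas, in mm^2.
#'
#' @param mesh a [trimesh].
#' @return surface area (mm^2).
#' @export
surface_area <- function(mesh) {
  stopifnot_trimesh(mesh)
  sum(face_areas(mesh))
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin); meaningful only for closed, consistently wound surfaces.
#'
#' @param mesh a closed [trimesh].
#' @return enclosed volume (mm^3), absolute value.
#' @export
mesh_volume <- function(mesh) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  cr <- cbind(p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L],
              p2[, 3L] * p3[, 1L] - p2[, 1L] * p3[, 3L],
              p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])
  abs(sum(rowSums(p1 * cr)) / 6)
}

#' Taubin smoothing
#'
#' Two-step Laplacian smoothing with uniform (umbrella) weights: each
#' iteration moves every vertex by `lambda` times its umbrella vector, then
#' by `mu` times the recomputed umbrella vector. With `lambda = 0.9`,
#' `mu = -0.95` the negative second step counteracts the shrinkage of plain
#' Laplacian smoothing. The displacement is restricted to the vertex-normal
#' direction, so smoothing attacks geometric noise without tangential
#' vertex sliding; in particular boundary vertices of open crops participate
#' with their available neighbours (no pinning) yet do not creep inward,
#' and an exactly planar sheet is a fixed point. Connectivity is unchanged.
#'
#' @param mesh a [trimesh].
#' @param lambda positive smoothing step (default 0.9).
#' @param mu negative un-shrinking step (default -0.95).
#' @param iterations number of lambda/mu pairs (default 10).
#' @return the smoothed [trimesh].
#' @export
taubin_smooth <- function(mesh, lambda = 0.9, mu = -0.95, iterations = 10L) {
  stopifnot_trimesh(mesh)
  if (lambda == 0 && mu == 0) return(mesh)
  if (lambda < 0) stop("lambda must be >= 0")
  if (mu > 0) stop("mu must be <= 0")
  et <- edge_table(mesh)
  i <- c(et$v1, et$v2)
  j <- c(et$v2, et$v1)
  idx <- sort(unique(i))  # vertices with edges; others stay put
  deg <- tabulate(i, nbins = nrow(mesh$vertices))
  v <- mesh$vertices
  mm <- mesh
  step <- function(v, fac) {
    if (fac == 0) return(v)
    mm$vertices <- v
    nrm <- vertex_normals(mm)
    nb <- rowsum(v[j, , drop = FALSE], i, reorder = TRUE)
    umb <- nb / deg[idx] - v[idx, , drop = FALSE]
    disp <- rowSums(umb * nrm[idx, , drop = FALSE])  # normal component
    v[idx, ] <- v[idx, , drop = FALSE] + fac * disp * nrm[idx, , drop = FALSE]
    v
  }
  for (it in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  out <- mesh
  out$vertices <- v
  out
}
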