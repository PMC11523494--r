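#' Triangle mesh of a molar occlusal surface
#'
#' A `trimesh` is the substrate every topographic metric acts on: an n x 3
#' matrix of vertex coordinates (mm) and an m x 3 integer matrix of
#' 1-based vertex indices, one row per triangle. Coordinates are assumed to
#' be in millimetres with the occlusal (chewing) surface facing +z.
#'
#' @param vertices numeric matrix, n x 3 (x, y, z in mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param normals optional numeric matrix, n x 3, per-vertex unit normals.
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(vertices) < 1L) stop("mesh has no vertices")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) < 1L) stop("mesh has no faces")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinate")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face index out of range [1, ", nrow(vertices), "]")
  if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
          faces[, 1L] == faces[, 3L]))
    stop("a face repeats a vertex")
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(vertices)))
      stop("normals must match vertices in dimension")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("trimesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox  x [%.4g, %.4g]  y [%.4g, %.4g]  z [%.4g, %.4g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

is_trimesh <- function(x) inherits(x, "trimesh")

stopifnot_trimesh <- function(x) {
  if (!is_trimesh(x)) stop("expected a 'trimesh' object")
  invisible(x)
}

bbox_diag <- function(mesh) {
  bb <- apply(mesh$vertices, 2L, range)
  sqrt(sum((bb[2L, ] - bb[1L, ])^2))
}

# cross products of the two edge vectors of each face, rows = faces
face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  w <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
        u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
        u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
}

face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr * cr))
}

# unit face normals; zero-area faces get a zero row
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr * cr))
  ok <- len > 0
  cr[ok, ] <- cr[ok, , drop = FALSE] / len[ok]
  cr[!ok, ] <- 0
  cr
}

# angle-weighted vertex normals (the standard tie-break-free weighting for
# curvature work on irregular triangulations)
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- face_normals(mesh)
  n <- matrix(0, nrow(v), 3L)
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  ang <- function(a, b) {
    # angle between row vectors a, b
    dn <- sqrt(rowSums(a * a) * rowSums(b * b))
    ct <- rowSums(a * b) / pmax(dn, .Machine$double.xmin)
    acos(pmin(1, pmax(-1, ct)))
  }
  a1 <- ang(p2 - p1, p3 - p1)
  a2 <- ang(p1 - p2, p3 - p2)
  a3 <- ang(p1 - p3, p2 - p3)
  idx <- c(f[, 1L], f[, 2L], f[, 3L])
  w <- c(a1, a2, a3)
  fn3 <- rbind(fn, fn, fn)
  for (j in 1:3) {
    acc <- rowsum(w * fn3[, j], idx)
    n[as.integer(rownames(acc)), j] <- acc
  }
  len <- sqrt(rowSums(n * n))
  ok <- len > 0
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n
}

# undirected edge table: one row per undirected edge, columns v1 < v2,
# plus incident face counts (boundary edges have count 1)
edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  ekey <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(ekey)
  first <- !duplicated(ekey)
  data.frame(v1 = pmin(e[first, 1L], e[first, 2L]),
             v2 = pmax(e[first, 1L], e[first, 2L]),
             nfaces = as.integer(cnt[ekey[first]]))
}

# logical vector over faces: TRUE if the face touches a boundary edge
boundary_faces <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  ekey <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(ekey)
  onb <- as.integer(cnt[ekey]) == 1L
  m <- nrow(f)
  onb[1:m] | onb[(m + 1):(2 * m)] | onb[(2 * m + 1):(3 * m)]
}

# face adjacency over shared edges: two-column matrix of face index pairs
face_adjacency <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  ekey <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  fid <- rep(seq_len(m), 3L)
  o <- order(ekey)
  ekey <- ekey[o]; fid <- fid[o]
  same <- ekey[-1L] == ekey[-length(ekey)]
  cbind(fid[c(same, FALSE)], fid[c(FALSE, same)])
}
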