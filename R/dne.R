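#' Dirichlet normal energy (DNE)
#'
#' Measures how fast the unit-normal field varies over the surface: the
#' per-face energy density is the squared differential of the linearly
#' interpolated angle-weighted vertex normals, measured in the metric of the
#' face's first fundamental form (for a smooth surface the density converges
#' to k1^2 + k2^2). Each face contributes energy density times area; the top
#' `dne_outlier_quantile` fraction of contributions is trimmed ("DNE 99%"
#' with the default 0.01) and boundary faces are retained by default.
#' Faces are partitioned into convex and concave by the sign of the local
#' mean-curvature estimate from the same interpolated normal field, so
#' `dne_total = dne_convex + dne_concave`. Scale- and rotation-invariant.
#'
#' @param mesh a clean, oriented [trimesh].
#' @param config a [topo_config].
#' @return a list: `dne_total`, `dne_convex`, `dne_concave`, `face_dne`
#'   (per-face retained contribution, 0 for trimmed faces), `face_convex`
#'   (logical), `n_degenerate` (faces excluded for degenerate normals).
#' @export
dne <- function(mesh, config = topo_config()) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  vn <- if (!is.null(mesh$normals)) mesh$normals else vertex_normals(mesh)

  p1 <- v[f[, 1L], , drop = FALSE]; n1 <- vn[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]; n2 <- vn[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]; n3 <- vn[f[, 3L], , drop = FALSE]
  u <- p2 - p1; w <- p3 - p1
  nu <- n2 - n1; nw <- n3 - n1

  E <- rowSums(u * u); G <- rowSums(w * w); Fm <- rowSums(u * w)
  det_g <- E * G - Fm * Fm
  # h entries of the normal-difference Gram matrix
  e11 <- rowSums(nu * nu); e22 <- rowSums(nw * nw); e12 <- rowSums(nu * nw)
  # energy density = tr(g^-1 h)
  dens <- (G * e11 - 2 * Fm * e12 + E * e22) / det_g
  area <- face_areas(mesh)
  degen <- !is.finite(dens) | det_g <= 0
  n_degenerate <- sum(degen)
  if (n_degenerate > 0) {
    message("dne: excluded ", n_degenerate, " faces with degenerate metric")
    dens[degen] <- 0
  }
  contrib <- dens * area

  # convex/concave by the sign of the mean curvature of the interpolated
  # normal field: H ~ 0.5 tr(g^-1 b), b = symmetrised <dp, dn>
  b11 <- rowSums(u * nu); b22 <- rowSums(w * nw)
  b12 <- 0.5 * (rowSums(u * nw) + rowSums(w * nu))
  H <- 0.5 * (G * b11 - 2 * Fm * b12 + E * b22) / det_g
  H[degen] <- 0
  convex <- H >= 0

  keep <- rep(TRUE, length(contrib))
  if (config$dne_boundary_mode == "exclude") keep[boundary_faces(mesh)] <- FALSE
  q <- config$dne_outlier_quantile
  if (q > 0) {
    idx <- which(keep)
    if (config$dne_trim_mode == "count") {
      ndrop <- ceiling(q * length(idx))
      drop <- idx[order(contrib[idx], decreasing = TRUE)][seq_len(ndrop)]
    } else {
      # smallest top set whose cumulative contribution reaches the q mass
      o <- idx[order(contrib[idx], decreasing = TRUE)]
      cum <- cumsum(contrib[o])
      ndrop <- which(cum >= q * sum(contrib[idx]))[1L]
      drop <- o[seq_len(ndrop)]
    }
    keep[drop] <- FALSE
  }

  face_dne <- ifelse(keep, contrib, 0)
  list(dne_total = sum(face_dne),
       dne_convex = sum(face_dne[convex]),
       dne_concave = sum(face_dne[!convex]),
       face_dne = face_dne,
       face_convex = convex,
       n_degenerate = n_degenerate)
}
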