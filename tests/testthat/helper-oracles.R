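# Independent oracles and small fixture builders shared across tests.

# axis-aligned unit cube (12 faces, outward winding)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  clean_mesh(trimesh(v, f), topo_config(component_min_faces = 1))
}

# flat rectangular grid sheet in z = 0
grid_sheet <- function(n = 20, extent = 2) {
  molartopo:::height_field_mesh(n, extent, function(x, y) 0 * x)
}

# brute-force PCV: same directions/offset as production, all-faces
# Moller-Trumbore in R
pcv_bruteforce <- function(mesh, config = topo_config()) {
  dirs <- molartopo:::pcv_directions(config$pcv_count)
  vn <- molartopo:::vertex_normals(mesh)
  off <- 1e-4 * molartopo:::bbox_diag(mesh)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  seen <- numeric(nrow(v))
  for (vi in seq_len(nrow(v))) {
    n <- vn[vi, ]
    o <- v[vi, ] + off * n
    s <- 0L
    for (k in seq_len(nrow(dirs))) {
      d <- dirs[k, ]
      if (sum(d * n) <= 0) next
      pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                  d[3] * e2[, 1] - d[1] * e2[, 3],
                  d[1] * e2[, 2] - d[2] * e2[, 1])
      det <- rowSums(e1 * pv)
      tv <- -sweep(a, 2, o)
      u <- rowSums(tv * pv) / det
      qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
                  tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
                  tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
      vv <- (qv %*% d) / det
      th <- rowSums(e2 * qv) / det
      hit <- abs(det) >= 1e-300 & u >= 0 & u <= 1 & vv >= 0 & u + vv <= 1 & th > 0
      if (!any(hit, na.rm = TRUE)) s <- s + 1L
    }
    seen[vi] <- s
  }
  vertex_pcv <- seen / config$pcv_count
  w <- molartopo:::vertex_area_weights(mesh)
  list(pcv = sum(w * vertex_pcv) / sum(w), vertex_pcv = vertex_pcv)
}

# rasterisation oracle for the projected footprint: supersampled
# pixel-centre coverage of the union of projected triangles
projected_area_raster <- function(mesh, npix = 2000) {
  v <- mesh$vertices; f <- mesh$faces
  rx <- range(v[, 1]); ry <- range(v[, 2])
  pad <- 1e-9 * max(diff(rx), diff(ry))
  xs <- seq(rx[1] - pad, rx[2] + pad, length.out = npix)
  ys <- seq(ry[1] - pad, ry[2] + pad, length.out = npix)
  hx <- xs[2] - xs[1]; hy <- ys[2] - ys[1]
  cov <- matrix(FALSE, npix, npix)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], 1:2, drop = FALSE]
    ix <- which(xs >= min(tri[, 1]) - hx & xs <= max(tri[, 1]) + hx)
    iy <- which(ys >= min(tri[, 2]) - hy & ys <= max(tri[, 2]) + hy)
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], times = length(iy))
    py <- rep(ys[iy], each = length(ix))
    d <- (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
         (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1])
    if (abs(d) < 1e-300) next
    l1 <- ((tri[2, 1] - px) * (tri[3, 2] - py) -
           (tri[2, 2] - py) * (tri[3, 1] - px)) / d
    l2 <- ((tri[3, 1] - px) * (tri[1, 2] - py) -
           (tri[3, 2] - py) * (tri[1, 1] - px)) / d
    l3 <- 1 - l1 - l2
    inside <- l1 >= 0 & l2 >= 0 & l3 >= 0
    cov[cbind(rep(ix, times = length(iy)), rep(iy, each = length(ix)))] <-
      cov[cbind(rep(ix, times = length(iy)), rep(iy, each = length(ix)))] | inside
  }
  sum(cov) * hx * hy
}

# OPCR patch-count oracle: same binning, components via igraph
opcr_oracle <- function(mesh, config = topo_config()) {
  fn <- molartopo:::face_normals(mesh)
  adj <- molartopo:::face_adjacency(mesh)
  counts <- integer(config$opcr_rotations)
  for (k in seq_len(config$opcr_rotations) - 1L) {
    az <- atan2(fn[, 2], fn[, 1]) - k * config$opcr_step_deg * pi / 180
    bins <- molartopo:::opcr_bin_faces(fn, az, config)
    keep <- adj[bins[adj[, 1]] == bins[adj[, 2]] & bins[adj[, 1]] != 0L, ,
                drop = FALSE]
    if (nrow(keep) == 0L) {
      counts[k + 1L] <- if (config$opcr_min_patch <= 1L) sum(bins != 0L) else 0L
      next
    }
    g <- igraph::graph_from_edgelist(keep, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(bins) - igraph::vcount(g)))
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership[bins != 0L]]
    counts[k + 1L] <- length(unique(
      comp$membership[bins != 0L][sizes >= config$opcr_min_patch]))
  }
  list(opcr = mean(counts), opc_per_rotation = counts)
}

# exact signed-rank p by explicit enumeration over all 2^n sign patterns
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= W + 1e-12), mean(ws >= W - 1e-12)))
}

# exact rank-sum p by explicit enumeration over all labelings: doubled
# smaller tail of U_a under the permutation null, capped at 1
mann_whitney_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); N <- length(pooled)
  ua <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combs <- utils::combn(N, n1)
  uas <- apply(combs, 2, function(ix) {
    aa <- pooled[ix]; bb <- pooled[-ix]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  min(1, 2 * min(mean(uas <= ua + 1e-12), mean(uas >= ua - 1e-12)))
}

# paired differences with a prescribed set of positive ranks (|d| = 1..n)
diffs_with_positive_ranks <- function(pos_ranks, n = 7) {
  d <- -(1:n)
  d[pos_ranks] <- abs(d[pos_ranks])
  d
}
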