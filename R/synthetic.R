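#' Analytic test surfaces
#'
#' Deterministic fixtures with known topographic values: a flat disc
#' (DNE 0, RFI 0, PCV 1, OPCR 0), a unit hemisphere (SA -> 2*pi,
#' OA -> pi, DNE -> 4*pi under refinement), a single centred Gaussian cusp
#' on a flat base (OPCR 8), two well-separated cusps (OPCR 16), and a
#' closed unit sphere (for volume/shrinkage checks).
#'
#' @param name one of `"flat_disc"`, `"hemisphere"`, `"single_cusp"`,
#'   `"two_cusps"`, `"sphere"`.
#' @param resolution tessellation density (>= 16); rings/segments for the
#'   round fixtures, grid vertices per side for the cusp fixtures.
#' @return a [trimesh].
#' @export
make_fixture <- function(name = c("flat_disc", "hemisphere", "single_cusp",
                                  "two_cusps", "sphere"),
                         resolution = 48L) {
  name <- match.arg(name)
  if (resolution < 16L) stop("resolution must be >= 16")
  switch(name,
    flat_disc = disc_mesh(resolution),
    hemisphere = hemisphere_mesh(resolution),
    sphere = sphere_mesh(resolution),
    single_cusp = height_field_mesh(
      grid_n = resolution, extent = 4,
      z_fun = function(x, y) exp(-(x^2 + y^2) / (2 * 0.5^2))),
    two_cusps = height_field_mesh(
      grid_n = resolution, extent = 11,
      z_fun = function(x, y)
        exp(-((x - 3)^2 + y^2) / (2 * 0.5^2)) +
        exp(-((x + 3)^2 + y^2) / (2 * 0.5^2))))
}

# unit-radius flat disc in z = 0: centre fan plus quad rings with a
# constant segment count (slivers near the rim-free centre are harmless
# on a flat surface)
disc_mesh <- function(nring) {
  nseg <- 4L * nring
  th <- 2 * pi * (seq_len(nseg) - 1L) / nseg
  verts <- matrix(c(0, 0, 0), 1L)
  faces <- NULL
  prev <- NULL
  for (r in seq_len(nring)) {
    ring <- cbind(r / nring * cos(th), r / nring * sin(th), 0)
    idx <- nrow(verts) + seq_len(nseg)
    verts <- rbind(verts, ring)
    if (r == 1L) {
      faces <- cbind(1L, idx, idx[c(2:nseg, 1L)])
    } else {
      s2 <- c(2:nseg, 1L)
      faces <- rbind(faces,
                     cbind(prev, idx, idx[s2]),
                     cbind(prev, idx[s2], prev[s2]))
    }
    prev <- idx
  }
  trimesh(verts, faces)
}

# open unit hemisphere (z >= 0), latitude-longitude tessellation
hemisphere_mesh <- function(res) {
  nlat <- res; nlon <- 2L * res
  verts <- matrix(c(0, 0, 1), 1L)  # pole
  faces <- NULL
  prev <- 1L
  for (i in seq_len(nlat)) {
    th <- pi / 2 * i / nlat  # polar angle from +z
    lon <- 2 * pi * (seq_len(nlon) - 1L) / nlon
    ring <- cbind(sin(th) * cos(lon), sin(th) * sin(lon), cos(th))
    idx <- nrow(verts) + seq_len(nlon)
    verts <- rbind(verts, ring)
    if (length(prev) == 1L) {
      for (s in seq_len(nlon))
        faces <- rbind(faces, c(prev, idx[s], idx[s %% nlon + 1L]))
    } else {
      for (s in seq_len(nlon)) {
        s2 <- s %% nlon + 1L
        faces <- rbind(faces, c(prev[s], idx[s], idx[s2]),
                       c(prev[s], idx[s2], prev[s2]))
      }
    }
    prev <- idx
  }
  trimesh(verts, faces)
}

# closed unit sphere: two hemispheres glued on the equator
sphere_mesh <- function(res) {
  top <- hemisphere_mesh(res)
  bot <- top
  bot$vertices[, 3L] <- -bot$vertices[, 3L]
  bot$faces <- bot$faces[, c(1L, 3L, 2L)]  # restore outward winding
  nv <- nrow(top$vertices)
  faces <- rbind(top$faces, bot$faces + nv)
  verts <- rbind(top$vertices, bot$vertices)
  # weld duplicated equator ring
  key <- apply(round(verts, 12L), 1L, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid[faces], ncol = 3L)
  trimesh(verts, faces)
}

# triangulated height field over a centred square of side `extent`
height_field_mesh <- function(grid_n, extent, z_fun) {
  g <- seq(-extent / 2, extent / 2, length.out = grid_n)
  xy <- expand.grid(x = g, y = g)
  z <- z_fun(xy$x, xy$y)
  verts <- cbind(xy$x, xy$y, z)
  faces <- grid_faces(grid_n)
  trimesh(verts, faces)
}

grid_faces <- function(n) {
  i <- rep(seq_len(n - 1L), n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  v00 <- (j - 1L) * n + i
  v10 <- v00 + 1L
  v01 <- v00 + n
  v11 <- v01 + 1L
  # winding chosen so normals point +z
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

#' Specification of a synthetic molar-like surface
#'
#' Parametric stand-in for a micro-CT molar crop: a height field of Gaussian
#' cusps (round bumps, the forb-feeder form) and/or Gaussian crests (ridges
#' along an axis, the grass-feeder form) over a square base, with mild
#' height noise so no region is exactly flat. The default geometry mimics a
#' grasshopper pars molaris: a ~1.5 mm footprint, cusp relief of ~0.35 mm,
#' and noise of 0.5% of the extent.
#'
#' @param kind `"cusped"` or `"crested"` preset, or `"custom"` with
#'   `features` supplied explicitly.
#' @param grid_n vertices per side (>= 16; default 72, which triangulates
#'   to about 10 000 faces, matching the decimation target of real scans).
#' @param extent side length of the base (mm).
#' @param base_noise_sd Gaussian height-noise sd (mm); default 0.5% of
#'   `extent`.
#' @param features list of feature lists: `kind` ("cusp" or "crest"),
#'   `center` (cusp, xy) or `axis` (crest: list(from, to) xy endpoints),
#'   `height` (mm), `width` (Gaussian sigma, mm).
#' @param seed integer; fixes the surface exactly.
#' @return an object of class `molar_spec`.
#' @export
molar_spec <- function(kind = c("cusped", "crested", "custom"),
                       grid_n = 72L, extent = 1.5,
                       base_noise_sd = 0.005 * extent,
                       features = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (grid_n < 16L) stop("grid_n must be >= 16")
  if (is.null(features)) {
    u <- extent / 2
    features <- switch(kind,
      cusped = list(
        list(kind = "cusp", center = c(-0.45, -0.45) * u, height = 0.98, width = 0.088 * extent),
        list(kind = "cusp", center = c(0.45, -0.45) * u, height = 0.90, width = 0.088 * extent),
        list(kind = "cusp", center = c(-0.45, 0.45) * u, height = 0.92, width = 0.088 * extent),
        list(kind = "cusp", center = c(0.45, 0.45) * u, height = 0.98, width = 0.088 * extent),
        list(kind = "cusp", center = c(0, 0.05) * u, height = 0.78, width = 0.077 * extent),
        list(kind = "cusp", center = c(0, -0.85) * u, height = 0.70, width = 0.072 * extent)),
      crested = list(
        # full-width lophs: the blade runs off both edges of the base, as
        # on graminivore-style molars, so each crest contributes flank
        # patches rather than cusp-like end caps
        list(kind = "crest", axis = list(c(-1.2, -0.5) * u, c(1.2, -0.5) * u), height = 0.60, width = 0.066 * extent),
        list(kind = "crest", axis = list(c(-1.2, 0.1) * u, c(1.2, 0.1) * u), height = 0.55, width = 0.066 * extent),
        list(kind = "crest", axis = list(c(-1.2, 0.7) * u, c(1.2, 0.7) * u), height = 0.60, width = 0.066 * extent)),
      custom = stop("kind = 'custom' requires an explicit features list"))
  }
  for (ft in features) {
    if (!ft$kind %in% c("cusp", "crest")) stop("feature kind must be cusp or crest")
    if (ft$height <= 0 || ft$width <= 0) stop("feature heights and widths must be positive")
  }
  structure(list(kind = kind, grid_n = as.integer(grid_n), extent = extent,
                 base_noise_sd = base_noise_sd, features = features,
                 seed = as.integer(seed)), class = "molar_spec")
}

#' Generate a synthetic molar surface from a spec
#'
#' Height field z(x, y) = sum of Gaussian cusps and crests plus Gaussian
#' noise, triangulated on a regular grid. Deterministic given `spec$seed`
#' (the generator draws from its own RNG stream and restores the caller's).
#'
#' @param spec a [molar_spec].
#' @return a [trimesh], occlusal-up.
#' @export
make_molar <- function(spec) {
  if (!inherits(spec, "molar_spec")) stop("expected a 'molar_spec'")
  g <- seq(-spec$extent / 2, spec$extent / 2, length.out = spec$grid_n)
  xy <- expand.grid(x = g, y = g)
  z <- numeric(nrow(xy))
  for (ft in spec$features) {
    if (ft$kind == "cusp") {
      d2 <- (xy$x - ft$center[1])^2 + (xy$y - ft$center[2])^2
    } else {
      d2 <- dist2_to_segment(xy$x, xy$y, ft$axis[[1]], ft$axis[[2]])
    }
    z <- z + ft$height * exp(-d2 / (2 * ft$width^2))
  }
  if (spec$base_noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(spec$seed)
    z <- z + rnorm(length(z), 0, spec$base_noise_sd)
  }
  trimesh(cbind(xy$x, xy$y, z), grid_faces(spec$grid_n))
}

# squared distance from points to a segment a-b (xy)
dist2_to_segment <- function(x, y, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- pmin(1, pmax(0, ((x - a[1]) * abx + (y - a[2]) * aby) / len2))
  (x - (a[1] + t * abx))^2 + (y - (a[2] + t * aby))^2
}

#' Apply parametric wear to an occlusal surface
#'
#' Models attrition as a soft planar abrasion: material above the
#' `(1 - wear_fraction)` quantile of vertex heights is planed off through a
#' smooth clamp `z' = z - delta * softplus((z - zc) / delta)`, whose
#' rounding scale `delta` grows with the depth of material removed (heavier
#' wear gives blunter rims, as on real facets). The clamp squashes height
#' variation on the facet toward zero — worn facets are polished — while
#' leaving the flanks untouched, reproducing the morphology of a worn
#' molar: lower, rounded, flatter cusps, hence lower DNE, RFI, OPCR and 3D
#' area and higher PCV. `wear_fraction = 0` is the identity; the operator
#' is pointwise monotone in `wear_fraction`, so wear stages nest.
#'
#' @param mesh a height-field-like [trimesh], occlusal-up.
#' @param wear_fraction in [0, 1): fraction of the height distribution
#'   planed off.
#' @param rim_sharpness ratio of removed depth to the rim rounding scale
#'   (default 4: `delta` is a quarter of the removed depth).
#' @return the worn [trimesh].
#' @export
apply_wear <- function(mesh, wear_fraction, rim_sharpness = 4) {
  stopifnot_trimesh(mesh)
  if (wear_fraction < 0 || wear_fraction >= 1)
    stop("wear_fraction must be in [0, 1)")
  if (wear_fraction == 0) return(mesh)
  z <- mesh$vertices[, 3L]
  zc <- stats::quantile(z, 1 - wear_fraction, names = FALSE)
  delta <- (max(z) - zc) / rim_sharpness
  if (delta <= 0) return(mesh)
  t <- (z - zc) / delta
  softplus <- ifelse(t > 30, t, log1p(exp(pmin(t, 30))))
  out <- mesh
  out$vertices[, 3L] <- z - delta * softplus
  out
}
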