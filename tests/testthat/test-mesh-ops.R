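test_that("clean_mesh removes zero-area faces, floaters and small pieces", {
  m <- make_molar(molar_spec("cusped", grid_n = 20, seed = 1))
  nf <- nrow(m$faces)
  # a face repeating a vertex index is rejected at construction
  expect_error(trimesh(m$vertices, rbind(m$faces, m$faces[1, c(1, 2, 2)])),
               "repeats")
  # zero-area via a duplicated coordinate (distinct index, same position)
  v3 <- rbind(m$vertices, m$vertices[1, ], c(99, 99, 99))
  dup <- nrow(m$vertices) + 1L
  f3 <- rbind(m$faces, c(m$faces[1, 1], dup, m$faces[1, 2]))
  cl <- clean_mesh(trimesh(v3, f3), topo_config(component_min_faces = 1))
  expect_equal(nrow(cl$faces), nf)
  expect_false(any(apply(cl$vertices, 1, function(r) all(r == c(99, 99, 99)))))

  # small-component removal: main molar + 2-face shard, threshold by default 1%
  shard_v <- rbind(c(5, 5, 5), c(5.1, 5, 5), c(5, 5.1, 5), c(5.1, 5.1, 5.1))
  nv <- nrow(m$vertices)
  shard_f <- rbind(c(nv + 1, nv + 2, nv + 3), c(nv + 2, nv + 4, nv + 3))
  both <- trimesh(rbind(m$vertices, shard_v), rbind(m$faces, shard_f))
  cl2 <- clean_mesh(both)
  expect_equal(nrow(cl2$faces), nf)

  # idempotence
  cl3 <- clean_mesh(cl2)
  expect_identical(cl3$vertices, cl2$vertices)
  expect_identical(cl3$faces, cl2$faces)

  # a mesh whose only face is exactly zero-area cleans to nothing
  expect_error(clean_mesh(trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0)),
                                  matrix(1:3, 1))),
               "degenerate")
})

test_that("clean_mesh unifies winding so signed normals are consistent", {
  m <- make_molar(molar_spec("cusped", grid_n = 16, seed = 2))
  flip <- seq(1, nrow(m$faces), by = 3)
  f <- m$faces
  f[flip, ] <- f[flip, c(1, 3, 2)]
  cl <- clean_mesh(trimesh(m$vertices, f), topo_config(component_min_faces = 1))
  fn <- molartopo:::face_normals(cl)
  expect_true(all(fn[, 3] > 0))  # height field: all normals occlusal-up
})

test_that("rotation is a rigid inverse-consistent isometry", {
  m <- make_molar(molar_spec("cusped", grid_n = 20, seed = 5))
  expect_equal(rotate_mesh(m, "x", 0)$vertices, m$vertices)
  r <- rotate_mesh(rotate_mesh(m, "y", 33.3), "y", -33.3)
  expect_lt(max(abs(r$vertices - m$vertices)), 1e-9)
  for (ax in c("x", "y", "z")) {
    expect_equal(surface_area(rotate_mesh(m, ax, 17.2)), surface_area(m),
                 tolerance = 1e-12)
  }
})

test_that("surface_area matches closed forms and the scaling law", {
  expect_equal(surface_area(cube_mesh()), 6)
  hs <- make_fixture("hemisphere", 48)
  expect_equal(surface_area(hs), 2 * pi, tolerance = 0.005)
  # refinement converges
  err <- sapply(c(24, 48), function(r)
    abs(surface_area(make_fixture("hemisphere", r)) - 2 * pi))
  expect_lt(err[2], err[1])
  m <- make_molar(molar_spec("cusped", grid_n = 20, seed = 1))
  m2 <- m; m2$vertices <- 2 * m2$vertices
  expect_equal(surface_area(m2), 4 * surface_area(m), tolerance = 1e-12)
})

test_that("taubin smoothing fixes planes, resists shrinkage, reduces noise energy", {
  g <- grid_sheet(20)
  gs <- taubin_smooth(g)
  expect_lt(max(abs(gs$vertices - g$vertices)), 1e-9)
  expect_identical(taubin_smooth(g, 0, 0, 10)$vertices, g$vertices)

  s <- make_fixture("sphere", 24)
  v0 <- mesh_volume(s)
  expect_lt(abs(mesh_volume(taubin_smooth(s)) / v0 - 1), 0.02)
  # pure Laplacian (mu = 0) shrinks the same sphere by far more
  expect_gt(abs(mesh_volume(taubin_smooth(s, 0.9, 0, 10)) / v0 - 1), 0.05)

  set.seed(42)
  sn <- s
  sn$vertices <- sn$vertices * (1 + rnorm(nrow(sn$vertices), 0, 0.02))
  cfg0 <- topo_config(dne_outlier_quantile = 0)
  expect_lt(dne(taubin_smooth(sn), cfg0)$dne_total,
            dne(sn, cfg0)$dne_total)
})

test_that("quadric decimation hits the target and preserves area", {
  sp <- molar_spec("cusped", grid_n = 144, base_noise_sd = 0.001, seed = 3)
  m <- clean_mesh(make_molar(sp))
  expect_gt(nrow(m$faces), 40000)
  d <- decimate(m, 10000)
  expect_gte(nrow(d$faces), 9800)
  expect_lte(nrow(d$faces), 10200)
  expect_lt(abs(surface_area(d) / surface_area(m) - 1), 0.01)
  # already below target: unchanged
  small <- make_molar(molar_spec("cusped", grid_n = 24, seed = 1))
  expect_identical(decimate(small, 10000)$vertices, small$vertices)
  expect_error(decimate(small, 3), "target")
})
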