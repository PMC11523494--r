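cfg0 <- topo_config(dne_outlier_quantile = 0)

test_that("DNE vanishes on flat surfaces and hits 4*pi on the hemisphere", {
  expect_lt(dne(grid_sheet(20), cfg0)$dne_total, 1e-9)
  expect_lt(dne(make_fixture("flat_disc", 20), cfg0)$dne_total, 1e-9)
  err <- sapply(c(32, 64), function(r)
    abs(dne(make_fixture("hemisphere", r), cfg0)$dne_total - 4 * pi))
  expect_lt(err[2] / (4 * pi), 0.02)
  expect_lt(err[2], err[1])  # refinement converges
})

test_that("DNE is scale- and rotation-invariant", {
  m <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 32, seed = 6)))
  d0 <- dne(m)$dne_total
  m2 <- m; m2$vertices <- 2 * m2$vertices
  expect_equal(dne(m2)$dne_total, d0, tolerance = 1e-6)
  for (ax in c("x", "y", "z")) {
    expect_equal(dne(rotate_mesh(m, ax, 23.7))$dne_total, d0,
                 tolerance = 1e-6)
  }
})

test_that("convex and concave parts sum to the total and split sensibly", {
  m <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 32, seed = 6)))
  d <- dne(m)
  expect_equal(d$dne_convex + d$dne_concave, d$dne_total,
               tolerance = 1e-9 * d$dne_total)
  expect_gt(d$dne_convex, 0)
  expect_gt(d$dne_concave, 0)
  # a convex cap is (almost) all convex energy
  h <- dne(make_fixture("hemisphere", 32), cfg0)
  expect_gt(h$dne_convex / h$dne_total, 0.99)
})

test_that("outlier trimming is monotone and count-based", {
  m <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 32, seed = 6)))
  full <- dne(m, cfg0)
  trimmed <- dne(m, topo_config(dne_outlier_quantile = 0.01))
  expect_lt(trimmed$dne_total, full$dne_total)
  nf <- nrow(m$faces)
  expect_equal(sum(trimmed$face_dne == 0) - sum(full$face_dne == 0),
               ceiling(0.01 * nf), tolerance = 0.5)
  # boundary exclusion removes boundary contributions
  excl <- dne(m, topo_config(dne_outlier_quantile = 0,
                             dne_boundary_mode = "exclude"))
  bf <- molartopo:::boundary_faces(m)
  expect_equal(excl$dne_total, sum(full$face_dne[!bf]), tolerance = 1e-9)
  # mass-mode trimming also reduces the total
  mass <- dne(m, topo_config(dne_outlier_quantile = 0.01,
                             dne_trim_mode = "mass"))
  expect_lt(mass$dne_total, full$dne_total)
})
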