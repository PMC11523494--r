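test_that("projected area matches closed forms", {
  expect_equal(projected_area(cube_mesh())$oa2d, 1, tolerance = 1e-12)
  hs <- make_fixture("hemisphere", 64)
  expect_equal(projected_area(hs)$oa2d, pi, tolerance = 0.005 * pi)
  g <- grid_sheet(12, extent = 3)
  expect_equal(projected_area(g)$oa2d, 9, tolerance = 1e-9)
})

test_that("union mode agrees with the rasterisation oracle within 0.1%", {
  m <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 32, seed = 9)))
  a_union <- projected_area(m)$oa2d
  a_ras <- projected_area_raster(m, 3000)
  expect_lt(abs(a_union / a_ras - 1), 0.001)
  sc <- make_fixture("single_cusp", 32)
  expect_lt(abs(projected_area(sc)$oa2d / projected_area_raster(sc, 2000) - 1),
            0.005)
})

test_that("alpha_auto mode reports its alpha and flags disagreement only when real", {
  m <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 32, seed = 9)))
  pa <- projected_area(m, topo_config(oa_mode = "alpha_auto"))
  expect_true(is.finite(pa$alpha))
  expect_false(pa$check2d_flag)
  expect_equal(pa$oa2d, projected_area(m)$oa2d, tolerance = 0.02)
})

test_that("degenerate projections raise errors", {
  v <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(0, 1e-15, 1))
  f <- rbind(c(1, 2, 4), c(2, 3, 4))
  expect_error(projected_area(trimesh(v, f)), "degenerate")
})

test_that("relief index follows the half-log convention", {
  expect_lt(abs(rfi(grid_sheet(12))), 1e-9)
  hs <- make_fixture("hemisphere", 64)
  expect_equal(rfi(hs), 0.5 * log(2), tolerance = 0.005)
  expect_equal(rfi(hs, topo_config(rfi_half_log = FALSE)), log(2),
               tolerance = 0.01)
  # worked group means: both printed group relief values recover to 3 d.p.
  expect_equal(round(rfi_from_areas(3.058, 1.181), 3), 0.476)
  expect_equal(round(rfi_from_areas(2.963, 1.118), 3), 0.487)
  expect_error(rfi_from_areas(1, 0), "positive")
  expect_warning(rfi_from_areas(0.5, 1), "orientation")
})
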