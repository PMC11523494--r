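test_that("flat sheets carry no orientation patches", {
  expect_equal(opcr(grid_sheet(16))$opcr, 0)
  expect_equal(opcr(make_fixture("flat_disc", 16))$opcr, 0)
})

test_that("a radially symmetric cusp yields the 8 azimuth sectors", {
  for (res in c(48, 96)) {
    oc <- opcr(make_fixture("single_cusp", res))
    expect_equal(oc$opc_per_rotation, rep(8L, 8))
    expect_equal(oc$opcr, 8)
  }
})

test_that("disjoint cusps contribute additively", {
  oc <- opcr(make_fixture("two_cusps", 80))
  expect_equal(oc$opc_per_rotation, rep(16L, 8))
})

test_that("production flood fill equals the independent components oracle", {
  meshes <- list(
    taubin_smooth(make_molar(molar_spec("cusped", grid_n = 28, seed = 4))),
    taubin_smooth(make_molar(molar_spec("crested", grid_n = 28, seed = 5))),
    make_fixture("single_cusp", 24))
  for (m in meshes) {
    expect_lte(nrow(m$faces), 2000)
    expect_identical(opcr(m)$opc_per_rotation,
                     opcr_oracle(m)$opc_per_rotation)
  }
})

test_that("opcr is invariant under z-rotations by whole bin widths", {
  m <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 32, seed = 8)))
  o0 <- opcr(m)$opc_per_rotation
  for (ang in c(45, 90, 180)) {
    expect_identical(opcr(rotate_mesh(m, "z", ang))$opc_per_rotation, o0)
  }
})

test_that("opcr per-rotation counts are nonnegative integers, mean as stated", {
  m <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 28, seed = 2)))
  oc <- opcr(m)
  expect_true(all(oc$opc_per_rotation >= 0))
  expect_true(all(oc$opc_per_rotation == round(oc$opc_per_rotation)))
  expect_equal(oc$opcr, mean(oc$opc_per_rotation), tolerance = 1e-12)
})
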