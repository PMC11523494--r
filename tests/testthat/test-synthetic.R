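test_that("generators are seed-deterministic", {
  sp <- molar_spec("cusped", grid_n = 24, seed = 42)
  m1 <- make_molar(sp); m2 <- make_molar(sp)
  expect_identical(m1$vertices, m2$vertices)
  m3 <- make_molar(molar_spec("cusped", grid_n = 24, seed = 43))
  expect_false(identical(m1$vertices, m3$vertices))
  # the generator does not disturb the caller's RNG stream
  set.seed(7); x1 <- runif(1)
  set.seed(7); invisible(make_molar(sp)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("fixture metrics match their analytic values", {
  fd <- make_fixture("flat_disc", 20)
  t <- topography(fd, topo_config(dne_outlier_quantile = 0))
  expect_lt(t$dne_total, 1e-9)
  expect_lt(abs(t$rfi), 1e-9)
  expect_equal(t$opcr, 0)
  expect_equal(t$pcv, 1, tolerance = 1e-12)
  expect_error(make_fixture("pyramid"), "arg")
  expect_error(make_fixture("flat_disc", 4), "resolution")
})

test_that("complexity grows with cusp count and relief with cusp height", {
  mk <- function(feats) taubin_smooth(make_molar(
    molar_spec("custom", features = feats, base_noise_sd = 0, seed = 2)))
  one <- list(list(kind = "cusp", center = c(0, 0), height = 0.6,
                   width = 0.12))
  four <- lapply(list(c(-0.4, -0.4), c(0.4, -0.4), c(-0.4, 0.4),
                      c(0.4, 0.4)),
                 function(ctr) list(kind = "cusp", center = ctr * 0.75,
                                    height = 0.6, width = 0.12))
  m1 <- mk(one); m4 <- mk(four)
  expect_gt(opcr(m4)$opcr, opcr(m1)$opcr)
  taller <- lapply(one, function(f) { f$height <- 1.2; f })
  expect_gt(rfi(mk(taller)), rfi(m1))
})

test_that("crested molars are less complex than cusped ones", {
  # matched relief and feature count; a fragment-suppressing minimum patch
  # size isolates the structural signal, and the crest axis avoids exact
  # alignment with any rotated bin boundary
  cfg <- topo_config(opcr_min_patch = 10)
  mk <- function(feats) taubin_smooth(make_molar(
    molar_spec("custom", features = feats, base_noise_sd = 0, seed = 5)))
  u <- 0.75
  rot10 <- function(p) c(cos(pi / 18) * p[1] - sin(pi / 18) * p[2],
                         sin(pi / 18) * p[1] + cos(pi / 18) * p[2])
  cusps <- lapply(list(c(-0.5, 0), c(0, 0), c(0.5, 0)), function(ctr)
    list(kind = "cusp", center = ctr * 2 * u * 0.6, height = 0.6,
         width = 0.1))
  crests <- lapply(list(-0.45, 0, 0.45), function(y)
    list(kind = "crest",
         axis = list(rot10(c(-1.2, y) * u), rot10(c(1.2, y) * u)),
         height = 0.6, width = 0.1))
  expect_lt(opcr(mk(crests), cfg)$opcr, opcr(mk(cusps), cfg)$opcr)
  # the default presets show the same contrast under the default config
  pc <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 48, seed = 11)))
  pr <- taubin_smooth(make_molar(molar_spec("crested", grid_n = 48, seed = 11)))
  expect_lt(opcr(pr)$opcr, opcr(pc)$opcr)
})

test_that("wear is the identity at 0 and composes monotonically", {
  m <- make_molar(molar_spec("cusped", grid_n = 32, seed = 7))
  expect_identical(apply_wear(m, 0)$vertices, m$vertices)
  expect_error(apply_wear(m, 1), "wear_fraction")
  # pointwise monotone: deeper wear never raises the surface
  w2 <- apply_wear(m, 0.2)
  w4 <- apply_wear(m, 0.4)
  expect_true(all(w4$vertices[, 3] <= w2$vertices[, 3] + 1e-12))
  expect_true(all(w2$vertices[, 3] <= m$vertices[, 3] + 1e-12))
  # repeated wear nests between its single stages: quantile truncation is
  # close to idempotent (the clamped mass sits at the cut), so wearing
  # twice digs slightly deeper than once but far less than the compounded
  # quantile
  ww <- apply_wear(apply_wear(m, 0.2), 0.2)
  wq <- apply_wear(m, 1 - 0.8^2)
  eps <- 1e-9
  expect_true(all(ww$vertices[, 3] <= w2$vertices[, 3] + eps))
  expect_true(all(ww$vertices[, 3] >= wq$vertices[, 3] - eps))
})

test_that("wear drives every metric in its observed direction", {
  # life order: the tooth wears first, the scan-processing chain follows
  stages <- lapply(c(0, 0.2, 0.4), function(wf)
    topography(taubin_smooth(apply_wear(
      make_molar(molar_spec("cusped", seed = 7)), wf))))
  dir_ok <- function(get, sign) {
    v <- vapply(stages, get, numeric(1))
    all(sign * diff(v) <= 0)
  }
  expect_true(dir_ok(function(t) t$dne_total, 1))
  expect_true(dir_ok(function(t) t$rfi, 1))
  expect_true(dir_ok(function(t) t$opcr, 1))
  expect_true(dir_ok(function(t) t$sa3d, 1))
  expect_true(dir_ok(function(t) t$pcv, -1))   # visibility rises with wear
})
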