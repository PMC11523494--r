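test_that("population CV matches hand-computed values", {
  expect_equal(cv_pop(c(1, 1, 1)), 0)
  expect_equal(cv_pop(c(1, 3)), 0.5)
  expect_equal(cv_pop(c(2, 4, 4, 4, 5, 5, 7, 9)), 0.4)
  expect_equal(cv_pop(c(0, 0, 0)), 0)
  expect_error(cv_pop(c(-1, 1)), "undefined")
  expect_error(cv_pop(1), "at least 2")
})

test_that("rigid-motion-invariant metrics have numerically zero CVs", {
  m <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 32, seed = 13)))
  rep_ <- orientation_sensitivity(m, tilt_deg = 5,
                                  metrics = c("dne", "sa3d"))
  expect_lt(rep_$cv[rep_$metric == "sa3d"], 1e-9)
  expect_lt(rep_$cv[rep_$metric == "dne"], 1e-6)
})

test_that("projection-dependent metrics move under tilt; zero tilt is null", {
  m <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 32, seed = 13)))
  rep_ <- orientation_sensitivity(m, tilt_deg = 5,
                                  metrics = c("rfi", "oa2d"))
  expect_gt(rep_$cv[rep_$metric == "rfi"], 0)
  expect_gt(rep_$cv[rep_$metric == "oa2d"], 0)
  rep0 <- orientation_sensitivity(m, tilt_deg = 0,
                                  metrics = c("rfi", "sa3d", "oa2d"))
  expect_true(all(rep0$cv == 0))
})

test_that("the report carries the five variants and all six metrics by default", {
  m <- taubin_smooth(make_molar(molar_spec("cusped", grid_n = 24, seed = 1)))
  rep_ <- orientation_sensitivity(m, tilt_deg = 5)
  expect_setequal(rep_$metric, c("dne", "rfi", "opcr", "pcv", "sa3d", "oa2d"))
  va <- attr(rep_, "variants")
  expect_equal(nrow(va), 5)
  expect_equal(va$angle_deg, c(0, 5, -5, 5, -5))
  expect_true(all(rep_$cv >= 0))
  expect_equal(rep_$mean, rowMeans(as.matrix(rep_[, 2:6])))
})
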