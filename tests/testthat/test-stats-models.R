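test_that("aicc arithmetic, limits and degeneracy", {
  expect_equal(aicc(-5, 2, 10), 14 + 12 / 7)
  expect_equal(aicc(-5, 0, 10), 10)              # k = 0: plain AIC
  expect_equal(aicc(-5, 3, 1e9), -2 * -5 + 6, tolerance = 1e-6)
  expect_warning(expect_true(is.na(aicc(-5, 9, 10))), "undefined")
})

test_that("the family enumerates all 8 subsets with normalised weights", {
  set.seed(3)
  df <- data.frame(individual_id = rep(1:12, each = 2),
                   side = rep(c("L", "R"), 12),
                   sex = rep(rep(c("F", "M"), 6), each = 2),
                   species = rep(rep(c("A", "B"), each = 6), each = 2))
  df$y <- rnorm(24)
  fam <- fit_model_family(df, "y", estimator = "ols")
  expect_equal(nrow(fam), 8)
  expect_setequal(fam$effects,
                  c("(none)", "side", "sex", "species", "side+sex",
                    "side+species", "sex+species", "side+sex+species"))
  expect_equal(sum(fam$weight), 1, tolerance = 1e-9)
  expect_equal(min(fam$delta_aicc), 0)
  expect_true(all(diff(fam$aicc) >= 0))
})

test_that("with no signal the intercept-only model wins", {
  set.seed(11)
  wins <- 0L
  for (i in 1:20) {
    df <- data.frame(individual_id = rep(1:15, each = 2),
                     side = rep(c("L", "R"), 15),
                     sex = rep(sample(c("F", "M"), 15, TRUE), each = 2),
                     species = rep(sample(c("A", "B"), 15, TRUE), each = 2),
                     y = rnorm(30))
    fam <- fit_model_family(df, "y", estimator = "ols")
    if (fam$effects[1] == "(none)") wins <- wins + 1L
  }
  expect_gt(wins, 10)   # majority of null draws
})

test_that("cell-mean reconstructions give the group-difference identities", {
  # species-only model on two constant species groups
  rec <- data.frame(individual_id = c(rep(1:7, each = 2), rep(8:25, each = 2)),
                    species = c(rep("P. saxosus", 14),
                                rep("V. nigricornis", 36)),
                    sex = "F", side = rep(c("L", "R"), 25),
                    dne = c(rep(590.096, 14), rep(472.835, 36)))
  co <- suppressWarnings(family_coefficients(
    fit_model_family(rec, "dne", estimator = "ols"), "species"))
  expect_equal(unname(co[1]), 590.096, tolerance = 1e-9)
  expect_equal(round(unname(co[2]), 3), -117.261)
  # sex+species on three constant cells: the saturated-fit identities
  rec2 <- data.frame(individual_id = 1:50,
                     species = c(rep("P. saxosus", 14),
                                 rep("V. nigricornis", 36)),
                     sex = c(rep("F", 28), rep("M", 22)),
                     side = "L",
                     opcr = c(rep(159.5, 14), rep(149.894, 14),
                              rep(162.756, 22)))
  co2 <- suppressWarnings(family_coefficients(
    fit_model_family(rec2, "opcr", estimator = "ols"), c("sex", "species")))
  expect_equal(unname(co2["(Intercept)"]), 159.5, tolerance = 1e-9)
  expect_equal(round(unname(co2[grep("species", names(co2))]), 3), -9.606)
  expect_equal(unname(co2[grep("sex", names(co2))]), 162.756 - 149.894,
               tolerance = 1e-9)
})

test_that("positive coefficients mean right/male/second-species greater", {
  df <- data.frame(individual_id = rep(1:20, each = 2),
                   side = rep(c("L", "R"), 20),
                   sex = rep(rep(c("F", "M"), 10), each = 2),
                   species = rep(rep(c("P. saxosus", "V. nigricornis"),
                                     each = 10), each = 2))
  df$y <- 1 + 0.5 * (df$side == "R") + 0.25 * (df$sex == "M") +
    2 * (df$species == "V. nigricornis")
  co <- suppressWarnings(family_coefficients(
    fit_model_family(df, "y", estimator = "ols"),
    c("side", "sex", "species")))
  expect_equal(unname(co[c("sideR", "sexM", "speciesV. nigricornis")]),
               c(0.5, 0.25, 2), tolerance = 1e-9)
})

test_that("the mixed model recovers planted effects within 2 SE almost always", {
  set.seed(99)
  nsim <- 200
  hits <- matrix(0L, nsim, 3)
  for (s in seq_len(nsim)) {
    n_ind <- 100   # enough clusters for ML standard errors to be calibrated
    ind <- rep(seq_len(n_ind), each = 2)
    df <- data.frame(individual_id = ind,
                     side = rep(c("L", "R"), n_ind),
                     sex = rep(sample(c("F", "M"), n_ind, TRUE), each = 2),
                     species = rep(rep(c("A", "B"), each = n_ind / 2),
                                   each = 2))
    b <- c(side = 1.5, sex = -2, species = 3)
    df$y <- 10 + b["side"] * (df$side == "R") + b["sex"] * (df$sex == "M") +
      b["species"] * (df$species == "B") +
      rep(rnorm(n_ind, 0, 1), each = 2) + rnorm(2 * n_ind, 0, 0.7)
    fit <- lme4::lmer(y ~ side + sex + species + (1 | individual_id),
                      data = df, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    est <- lme4::fixef(fit)[c("sideR", "sexM", "speciesB")]
    se <- sqrt(diag(as.matrix(vcov(fit))))[c("sideR", "sexM", "speciesB")]
    hits[s, ] <- as.integer(abs(est - b) <= 2 * se)
    if (s == nsim) {
      # the family's full model is the same ML fit
      fam <- fit_model_family(df, "y")
      co <- family_coefficients(fam, c("side", "sex", "species"))
      expect_equal(co[names(est)], est, tolerance = 1e-6)
    }
  }
  expect_gte(min(colMeans(hits)), 0.95 - 2 * sqrt(0.05 * 0.95 / nsim))
})

test_that("random-intercept and ols estimators both run and agree on means", {
  set.seed(21)
  df <- data.frame(individual_id = rep(1:10, each = 2),
                   side = rep(c("L", "R"), 10),
                   sex = rep(rep(c("F", "M"), 5), each = 2),
                   species = rep(rep(c("A", "B"), each = 5), each = 2))
  df$y <- 5 + 2 * (df$species == "B") + rnorm(20, 0, 0.1)
  fam_ri <- fit_model_family(df, "y", estimator = "random_intercept")
  fam_ols <- fit_model_family(df, "y", estimator = "ols")
  expect_equal(nrow(fam_ri), 8)
  c_ri <- family_coefficients(fam_ri, "species")
  c_ols <- family_coefficients(fam_ols, "species")
  expect_equal(unname(c_ri[2]), unname(c_ols[2]), tolerance = 0.05)
  # the random-intercept fit counts two variance components
  expect_equal(fam_ri$k[fam_ri$effects == "(none)"], 3L)
  expect_equal(fam_ols$k[fam_ols$effects == "(none)"], 2L)
})
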