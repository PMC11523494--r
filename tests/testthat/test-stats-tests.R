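test_that("signed-rank worked examples reproduce the printed statistic/p pairs", {
  cases <- list(list(pos = c(7, 6, 1), W = 14, p = 1),
                list(pos = 5, W = 5, p = 0.15625),
                list(pos = 1, W = 1, p = 0.03125),
                list(pos = integer(0), W = 0, p = 0.015625),
                list(pos = c(7, 6, 5), W = 18, p = 0.578125))
  for (cs in cases) {
    t <- signed_rank_exact(diffs_with_positive_ranks(cs$pos))
    expect_equal(t$statistic, cs$W)
    expect_equal(t$p_two_sided, cs$p, tolerance = 1e-12)
    expect_identical(t$method, "signed_rank_exact")
  }
})

test_that("signed-rank p equals brute-force enumeration for all n <= 10", {
  set.seed(31)
  for (n in 2:10) {
    for (rep in 1:4) {
      d <- round(rnorm(n), 2)
      d[d == 0] <- 0.01
      if (rep %% 2 == 0) d <- round(d * 4) / 4  # force ties in |d|
      d <- d[d != 0]
      if (length(d) < 2) next
      expect_equal(signed_rank_exact(d)$p_two_sided, signed_rank_enum_p(d),
                   tolerance = 1e-12)
    }
  }
  expect_error(signed_rank_exact(c(0, 0)), "zero")
})

test_that("rank-sum exact p equals enumeration for n1+n2 <= 12 (ties included)", {
  set.seed(17)
  for (rep in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- round(rnorm(n1) * 2) / 2
    b <- round(rnorm(n2) * 2) / 2
    has_ties <- anyDuplicated(c(a, b)) > 0
    t <- mann_whitney_exact(a, b, ties = "enumerate")
    expect_equal(t$p_two_sided, mann_whitney_enum_p(a, b), tolerance = 1e-12)
    if (!has_ties) expect_identical(t$method, "rank_sum_exact")
  }
})

test_that("rank-sum worked examples and conventions", {
  # complete separation at 3 vs 3
  t <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$statistic, 0)
  expect_equal(t$p_two_sided, 0.1, tolerance = 1e-12)
  # U = 11 at (7, 11): exact when tie-free
  a <- c(1:6, 100); b <- 10:20
  t2 <- mann_whitney_exact(a, b)
  expect_equal(t2$statistic, 11)
  expect_identical(t2$method, "rank_sum_exact")
  expect_equal(t2$p_two_sided, 2 * pwilcox(11, 7, 11), tolerance = 1e-12)
  # a pooled tie forces the flagged normal approximation, as in the
  # standard R test; its p rounds to 0.014
  a3 <- c(1, 1, 2, 3, 4, 5, 100)
  t3 <- mann_whitney_exact(a3, b)
  expect_equal(t3$statistic, 11)
  expect_identical(t3$method, "normal_approx")
  expect_equal(round(t3$p_two_sided, 3), 0.014)
  expect_equal(t3$p_two_sided,
               suppressWarnings(wilcox.test(a3, b)$p.value),
               tolerance = 1e-9)
  # identical samples: U = n^2/2, p = 1
  t4 <- mann_whitney_exact(1:4, 1:4, ties = "enumerate")
  expect_equal(t4$statistic, 8)
  expect_equal(t4$p_two_sided, 1)
})

test_that("exact tests hold nominal size under an exchangeable null", {
  set.seed(2024)
  nrep <- 2000
  rej_sr <- rej_mw <- 0L
  for (i in seq_len(nrep)) {
    d <- rnorm(8)
    if (signed_rank_exact(d)$p_two_sided <= 0.05) rej_sr <- rej_sr + 1L
    x <- rnorm(5); y <- rnorm(6)
    if (mann_whitney_exact(x, y)$p_two_sided <= 0.05) rej_mw <- rej_mw + 1L
  }
  bound <- 0.05 + 2 * sqrt(0.05 * 0.95 / nrep)
  expect_lte(rej_sr / nrep, bound)
  expect_lte(rej_mw / nrep, bound)
})

test_that("effect sizes report pooled, paired and rank-based measures", {
  e0 <- effect_sizes(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(e0$cohens_d_pooled, 0)
  expect_equal(e0$cohens_d_paired, 0)
  expect_equal(e0$rank_r, 0)
  e <- effect_sizes(c(1, 2, 3), c(3, 4, 5))
  expect_equal(e$cohens_d_pooled, -2)   # (mean_a - mean_b) / pooled sd
  expect_identical(e$band, "large")
  set.seed(5)
  e2 <- effect_sizes(rnorm(1e4, 1), rnorm(1e4, 0))
  expect_equal(e2$cohens_d_pooled, 1, tolerance = 0.05)
  expect_warning(effect_sizes(c(1, 1), c(2, 2)), "infinite")
})

test_that("pearson matrices obey exact identities and subset filters", {
  x <- 1:20
  df <- data.frame(a = x, b = 2 * x + 1, c = -x,
                   species = rep(c("s1", "s2"), 10))
  m <- pearson_matrix(df, c("a", "b", "c"))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  sub <- pearson_matrix(df, c("a", "b"), subset = list(species = "s1"))
  expect_equal(dim(sub), c(2L, 2L))
  set.seed(8)
  big <- data.frame(u = rnorm(1e4), v = rnorm(1e4))
  expect_lt(abs(pearson_matrix(big, c("u", "v"))["u", "v"]), 0.05)
  dfc <- data.frame(a = x, k = rep(1, 20))
  expect_warning(mc <- pearson_matrix(dfc, c("a", "k")), "constant")
  expect_true(is.na(mc["a", "k"]))
})
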