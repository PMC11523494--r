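#' Exact Wilcoxon signed-rank test (the paired two-sided rank test)
#'
#' Tests for a side difference between paired measurements. Zero
#' differences are dropped before ranking (the convention of standard R)
#' unless `zero_method = "pratt"`. Absolute differences are mid-ranked; the
#' statistic W is the rank sum of the positive differences. For n <= 25 the
#' null distribution is computed exactly by convolution over all 2^n sign
#' assignments (ties handled exactly via doubled midranks); the two-sided p
#' is `min(1, 2 * min(P(W <= w), P(W >= w)))`. Larger n uses the normal
#' approximation with tie correction and continuity correction, flagged in
#' `method`.
#'
#' @param paired_differences numeric vector of paired differences.
#' @param exact_max largest n for exact enumeration (default 25).
#' @param zero_method `"drop"` (default) or `"pratt"` (keep zeros in the
#'   ranking, then drop their signed contribution).
#' @return an object of class `rank_test`: list with `method`, `statistic`,
#'   `p_two_sided`, `n`, `effect_rank_r`.
#' @export
signed_rank_exact <- function(paired_differences, exact_max = 25L,
                              zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- paired_differences[!is.na(paired_differences)]
  if (zero_method == "drop") d <- d[d != 0]
  if (length(d) == 0L || all(d == 0))
    stop("no information: all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  if (zero_method == "pratt") {
    keep <- d != 0
    W <- sum(r[keep][d[keep] > 0])
    r <- r[keep]; n_eff <- sum(keep)
  } else {
    W <- sum(r[d > 0])
    n_eff <- n
  }
  # null moments (over the signed, possibly tied, ranks actually used)
  mu <- sum(r) / 2
  sig <- sqrt(sum(r^2) / 4)
  z <- (W - mu) / sig
  zc <- (W - mu - sign(W - mu) * 0.5) / sig  # continuity-corrected
  if (n <= exact_max) {
    # exact over 2^n sign assignments by convolution on doubled midranks
    r2 <- as.integer(round(2 * r))
    probs <- signrank_null(r2)
    w2 <- as.integer(round(2 * W))
    p_lo <- sum(probs[seq_len(w2 + 1L)])
    p_hi <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "signed_rank_exact"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(zc)))
    method <- "normal_approx"
  }
  structure(list(method = method, statistic = W, p_two_sided = p, n = n_eff,
                 effect_rank_r = abs(z) / sqrt(n_eff)),
            class = "rank_test")
}

# exact null pmf of 2*W over sign assignments; index i holds P(2W = i-1)
signrank_null <- function(r2) {
  total <- sum(r2)
  probs <- numeric(total + 1L)
  probs[1L] <- 1
  for (rv in r2) {
    shifted <- c(rep(0, rv), probs[seq_len(total + 1L - rv)])
    probs <- 0.5 * (probs + shifted)
  }
  probs
}

#' Exact Mann-Whitney U test (unpaired two-sided rank-sum test)
#'
#' U is the smaller of U_a = #\{(a, b): a > b\} (+1/2 per tie) and U_b.
#' Without ties and for n1 + n2 <= `exact_max` the exact two-sided p is
#' `min(1, 2 * P(U <= u))` under the label-permutation null (count
#' recurrence). With ties the exact distribution is data-dependent:
#' `ties = "approx"` (default, the behaviour of the standard R test) uses
#' the normal approximation with tie and continuity correction, flagged in
#' `method`; `ties = "enumerate"` enumerates all choose(n1+n2, n1)
#' labelings exactly (practical for small samples).
#'
#' @param sample_a,sample_b numeric vectors.
#' @param exact_max largest n1 + n2 for exact computation (default 25).
#' @param ties `"approx"` or `"enumerate"`.
#' @return an object of class `rank_test`: list with `method`, `statistic`
#'   (the smaller U), `u_a`, `p_two_sided`, `n1`, `n2`, `effect_rank_r`.
#' @export
mann_whitney_exact <- function(sample_a, sample_b, exact_max = 25L,
                               ties = c("approx", "enumerate")) {
  ties <- match.arg(ties)
  a <- sample_a[!is.na(sample_a)]; b <- sample_b[!is.na(sample_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both samples must be nonempty")
  ua <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u <- min(ua, n1 * n2 - ua)
  pooled <- c(a, b)
  has_ties <- anyDuplicated(pooled) > 0L
  N <- n1 + n2
  # normal-approximation ingredients (tie-corrected)
  tie_tab <- table(pooled)
  mu <- n1 * n2 / 2
  sig <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1))))
  z <- (ua - mu) / sig
  if (!has_ties && N <= exact_max) {
    p <- min(1, 2 * sum(dwilcox_count(n1, n2)[seq_len(floor(u) + 1L)]))
    method <- "rank_sum_exact"
  } else if (has_ties && ties == "enumerate" && choose(N, n1) <= 5e5) {
    p <- mw_enumerate_p(a, b, ua)
    method <- "rank_sum_exact"
  } else {
    zc <- (u + 0.5 - mu) / sig   # lower tail of the smaller U, cc inward
    p <- min(1, 2 * stats::pnorm(zc))
    method <- "normal_approx"
  }
  structure(list(method = method, statistic = u, u_a = ua, p_two_sided = p,
                 n1 = n1, n2 = n2, effect_rank_r = abs(z) / sqrt(N)),
            class = "rank_test")
}

# exact pmf of U for (n1, n2) without ties: index i holds P(U = i-1)
dwilcox_count <- function(n1, n2) {
  # classic recurrence on partition counts, built as repeated convolution:
  # generating function prod_{j=1..n1} (1 - x^(n2+j)) / (1 - x^j)
  maxu <- n1 * n2
  cnt <- numeric(maxu + 1L); cnt[1L] <- 1
  for (j in seq_len(n1)) {
    # multiply by 1/(1 - x^j): prefix sums with stride j
    for (k in (j + 1L):(maxu + 1L)) cnt[k] <- cnt[k] + cnt[k - j]
    # multiply by (1 - x^(n2+j))
    s <- n2 + j
    if (s <= maxu) for (k in (maxu + 1L):(s + 1L)) cnt[k] <- cnt[k] - cnt[k - s]
  }
  cnt / choose(n1 + n2, n1)
}

# exact two-sided p with ties by full enumeration of labelings:
# doubled smaller tail of U_a, capped at 1
mw_enumerate_p <- function(a, b, ua_obs) {
  pooled <- c(a, b)
  n1 <- length(a); N <- length(pooled)
  combs <- utils::combn(N, n1)
  uas <- apply(combs, 2L, function(ix) {
    aa <- pooled[ix]; bb <- pooled[-ix]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  min(1, 2 * min(mean(uas <= ua_obs + 1e-9), mean(uas >= ua_obs - 1e-9)))
}

#' @export
print.rank_test <- function(x, ...) {
  lab <- if (!is.null(x$n1)) sprintf("U = %g (n1 = %d, n2 = %d)",
                                     x$statistic, x$n1, x$n2)
         else sprintf("W = %g (n = %d)", x$statistic, x$n)
  cat(sprintf("%s: %s, two-sided p = %.6g [rank r = %.3f]\n",
              x$method, lab, x$p_two_sided, x$effect_rank_r))
  invisible(x)
}

#' Effect sizes for a two-group comparison
#'
#' Reports three effect measures side by side: pooled Cohen's d (difference
#' of means over the (n-1)-weighted pooled sd), paired Cohen's d (mean
#' difference over the sd of the differences; needs equal lengths), and the
#' rank-based r = |z| / sqrt(N) from the corresponding rank test's normal
#' approximation. Bands: |d| >= 0.8 large, >= 0.5 medium, >= 0.2 small.
#'
#' @param sample_a,sample_b numeric vectors (length >= 2 each).
#' @param paired interpret the samples as paired (element-wise).
#' @return list with `cohens_d_pooled`, `cohens_d_paired` (NA when not
#'   paired), `rank_r`, and `band` (interpretation of the pooled d).
#' @export
effect_sizes <- function(sample_a, sample_b, paired = FALSE) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("need >= 2 values per sample")
  n1 <- length(sample_a); n2 <- length(sample_b)
  v1 <- stats::var(sample_a); v2 <- stats::var(sample_b)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  dm <- mean(sample_a) - mean(sample_b)
  d_pooled <- if (sp > 0) dm / sp else if (dm == 0) 0 else {
    warning("zero pooled variance with unequal means: infinite d")
    sign(dm) * Inf
  }
  d_paired <- NA_real_
  if (paired) {
    if (n1 != n2) stop("paired effect size needs equal lengths")
    dd <- sample_a - sample_b
    sdd <- stats::sd(dd)
    d_paired <- if (sdd > 0) mean(dd) / sdd else if (mean(dd) == 0) 0 else {
      warning("zero sd of differences with nonzero mean: infinite d")
      sign(mean(dd)) * Inf
    }
  }
  rank_r <- if (paired) {
    dd <- sample_a - sample_b
    if (all(dd == 0)) 0 else signed_rank_exact(dd)$effect_rank_r
  } else {
    mann_whitney_exact(sample_a, sample_b)$effect_rank_r
  }
  band <- if (!is.finite(d_pooled)) "large"
          else if (abs(d_pooled) >= 0.8) "large"
          else if (abs(d_pooled) >= 0.5) "medium"
          else if (abs(d_pooled) >= 0.2) "small" else "negligible"
  list(cohens_d_pooled = d_pooled, cohens_d_paired = d_paired,
       rank_r = rank_r, band = band)
}

#' Pearson correlation matrix over specimen metrics
#'
#' Pairwise-complete Pearson correlations between topographic metrics,
#' optionally on a subset of records (species, sex, side). Constant columns
#' give NA entries and a warning rather than a silent 0.
#'
#' @param records a data frame with one row per molar, containing the
#'   metric columns plus optional `species`, `sex`, `side`.
#' @param metrics character vector of metric column names.
#' @param subset optional named list of filters, e.g.
#'   `list(species = "P. saxosus", sex = "F")`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(records, metrics, subset = NULL) {
  df <- as.data.frame(records)
  if (!is.null(subset))
    for (nm in names(subset)) df <- df[df[[nm]] %in% subset[[nm]], , drop = FALSE]
  missing_cols <- setdiff(metrics, names(df))
  if (length(missing_cols)) stop("missing metric columns: ",
                                 paste(missing_cols, collapse = ", "))
  x <- as.matrix(df[metrics])
  if (sum(stats::complete.cases(x)) < 3L)
    stop("need >= 3 complete rows for correlations")
  const <- apply(x, 2L, function(col) stats::var(col, na.rm = TRUE) == 0)
  if (any(const))
    warning("constant metric column(s): ",
            paste(metrics[const], collapse = ", "), " (entries set to NA)")
  suppressWarnings(m <- stats::cor(x, use = "pairwise.complete.obs"))
  m[const, ] <- NA_real_; m[, const] <- NA_real_
  diag(m) <- 1
  m
}
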