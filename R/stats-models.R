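#' Small-sample Akaike information criterion
#'
#' `AICc = -2*loglik + 2k + 2k(k+1)/(n - k - 1)`; undefined (NA with a
#' warning) when `n <= k + 1`.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters (including variance components).
#' @param n number of observations.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    warning("AICc undefined: n <= k + 1")
    return(NA_real_)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the full fixed-effect model family for one topographic metric
#'
#' Fits all 8 subsets of the fixed effects \{side, sex, species\} (including
#' the intercept-only model of pure chance) for one response, by maximum
#' likelihood, and ranks them by AICc with Akaike weights. Factors are coded
#' with reference levels left / female / first species, so positive
#' coefficients mean the right side, males, or the second species have
#' greater values. Estimator `"random_intercept"` (default) adds a
#' per-individual random intercept (fitted with ML, not REML, so AICc is
#' comparable across fixed-effect sets); `"ols"` is an ordinary linear
#' model. Models whose AICc is undefined (n <= k + 1) are dropped with a
#' warning.
#'
#' @param records data frame with the response column plus `side`, `sex`,
#'   `species`, `individual_id`.
#' @param metric name of the response column.
#' @param estimator `"random_intercept"` or `"ols"`.
#' @param reference named list overriding the reference levels, e.g.
#'   `list(side = "L", sex = "F", species = "P. saxosus")`.
#' @return an object of class `model_family`: data frame with one row per
#'   fit (`effects`, `k`, `loglik`, `aicc`, `delta_aicc`, `weight`) plus a
#'   `fits` attribute holding the coefficient vectors; rows sorted by AICc.
#' @export
fit_model_family <- function(records, metric,
                             estimator = c("random_intercept", "ols"),
                             reference = list(side = "L", sex = "F",
                                              species = NULL)) {
  estimator <- match.arg(estimator)
  df <- as.data.frame(records)
  if (!metric %in% names(df)) stop("no column '", metric, "' in records")
  df <- df[is.finite(df[[metric]]), , drop = FALSE]
  n <- nrow(df)
  if (n < 3L) stop("too few complete records")
  for (fac in c("side", "sex", "species")) {
    if (!fac %in% names(df)) next
    lev <- unique(as.character(df[[fac]]))
    ref <- reference[[fac]]
    if (is.null(ref) || !ref %in% lev) ref <- sort(lev)[1L]
    df[[fac]] <- factor(df[[fac]], levels = c(ref, setdiff(sort(lev), ref)))
  }
  if (estimator == "random_intercept") {
    if (!"individual_id" %in% names(df))
      stop("random_intercept estimator needs an individual_id column")
    if (length(unique(df$individual_id)) < 2L)
      stop("need >= 2 individuals")
    df$individual_id <- factor(df$individual_id)
  }

  effect_sets <- unlist(lapply(0:3, function(m)
    utils::combn(c("side", "sex", "species"), m, simplify = FALSE)),
    recursive = FALSE)
  # drop effects with a single observed level (cannot be estimated)
  usable <- vapply(c("side", "sex", "species"), function(fac)
    fac %in% names(df) && nlevels(df[[fac]]) > 1L, TRUE)
  fits <- lapply(effect_sets, function(fx) {
    if (any(!usable[fx])) return(NULL)
    rhs <- if (length(fx)) paste(fx, collapse = " + ") else "1"
    if (estimator == "ols") {
      fo <- stats::as.formula(paste0("`", metric, "` ~ ", rhs))
      fit <- stats::lm(fo, data = df)
      ll <- as.numeric(stats::logLik(fit))
      k <- length(stats::coef(fit)) + 1L  # + residual variance
      co <- stats::coef(fit)
    } else {
      fo <- stats::as.formula(paste0("`", metric, "` ~ ", rhs,
                                     " + (1 | individual_id)"))
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(fo, data = df, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))))
      ll <- as.numeric(stats::logLik(fit))
      k <- length(lme4::fixef(fit)) + 2L  # + random-intercept var + residual var
      co <- lme4::fixef(fit)
    }
    list(effects = fx, loglik = ll, k = k, coefficients = co)
  })
  fits <- Filter(Negate(is.null), fits)
  tab <- data.frame(
    effects = vapply(fits, function(f)
      if (length(f$effects)) paste(f$effects, collapse = "+") else "(none)", ""),
    k = vapply(fits, `[[`, 1L, "k"),
    loglik = vapply(fits, `[[`, 1, "loglik"))
  tab$aicc <- suppressWarnings(
    mapply(aicc, tab$loglik, tab$k, MoreArgs = list(n = n)))
  if (any(is.na(tab$aicc))) {
    warning(sum(is.na(tab$aicc)), " model(s) dropped: AICc undefined at n = ", n)
    fits <- fits[!is.na(tab$aicc)]
    tab <- tab[!is.na(tab$aicc), , drop = FALSE]
  }
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  w <- exp(-0.5 * tab$delta_aicc)
  tab$weight <- w / sum(w)
  o <- order(tab$aicc)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[o]
  attr(tab, "estimator") <- estimator
  attr(tab, "metric") <- metric
  attr(tab, "n") <- n
  class(tab) <- c("model_family", "data.frame")
  tab
}

#' @export
print.model_family <- function(x, ...) {
  cat(sprintf("model family for '%s' (%s, ML, n = %d)\n",
              attr(x, "metric"), attr(x, "estimator"), attr(x, "n")))
  print.data.frame(x, digits = 5)
  best <- attr(x, "fits")[[1L]]
  cat("best-model coefficients:\n")
  print(round(best$coefficients, 4))
  invisible(x)
}

#' Coefficients of one member of a model family
#'
#' @param family a `model_family`.
#' @param effects character vector naming the fixed effects of the wanted
#'   subset (e.g. `c("sex", "species")`; `character(0)` for the
#'   intercept-only model).
#' @return named coefficient vector.
#' @export
family_coefficients <- function(family, effects) {
  want <- if (length(effects)) paste(sort(effects), collapse = "+") else "(none)"
  for (f in attr(family, "fits")) {
    have <- if (length(f$effects)) paste(sort(f$effects), collapse = "+") else "(none)"
    if (identical(have, want)) return(f$coefficients)
  }
  stop("no fit with effects: ", want)
}
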