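# Group-level inference: Pearson chi-square, covariate-adjusted ANOVA with
# Bonferroni post hocs, partial correlations, Fisher-z comparison of
# correlations, and a BIC-based Bayes factor approximation.

#' Pearson chi-square test of independence
#'
#' The uncorrected Pearson statistic sum((O - E)^2 / E) with
#' df = (r - 1)(c - 1). No continuity correction is applied anywhere in the
#' package: the study's printed statistics are only reproduced without it.
#'
#' @param table Integer matrix of counts (at least 2 x 2, non-negative).
#' @return List: `chi2`, `df`, `p`; for a degenerate table (a zero row or
#'   column margin) the statistic is `NA` with a `reason`.
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integer counts", call. = FALSE)
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(
      chi2 = NA_real_, df = NA_integer_, p = NA_real_,
      reason = "zero margin: expected counts undefined"
    ))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(
    chi2 = unname(ct$statistic),
    df = unname(ct$parameter),
    p = unname(ct$p.value)
  )
}

#' One-way ANOVA with covariates (ANCOVA) and Bonferroni post hocs
#'
#' Fits `values ~ group + covariates` by least squares with sum-to-zero
#' contrasts and reports the Type-III F test for the group factor, partial
#' eta-squared, covariate-adjusted group means (estimated marginal means at
#' covariate means), and Bonferroni-adjusted pairwise comparisons.
#'
#' @param values Numeric outcome vector.
#' @param group Group labels (coerced to factor).
#' @param covariates Data.frame of covariates; character or factor columns
#'   (e.g. school) are treated as unordered categorical.
#' @return List of class `ccc_ancova`: `F`, `df_num`, `df_den`, `p`,
#'   `eta_sq` (partial), `adjusted_means` (data.frame), `posthoc`
#'   (data.frame of pairwise differences with Bonferroni-adjusted p), `model`
#'   (the `lm` fit).
#' @export
ancova <- function(values, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  dat <- data.frame(.y = values, group = group)
  rhs <- "group"
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      if (is.character(covariates[[nm]])) {
        covariates[[nm]] <- factor(covariates[[nm]])
      }
    }
    dat <- cbind(dat, covariates)
    rhs <- paste(c("group", names(covariates)), collapse = " + ")
  }
  fit <- stats::lm(
    stats::as.formula(paste(".y ~", rhs)),
    data = dat,
    contrasts = local({
      fac <- names(dat)[vapply(dat, is.factor, logical(1))]
      stats::setNames(as.list(rep("contr.sum", length(fac))), fac)
    })
  )
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    stop(
      "rank-deficient design; check covariates: ",
      paste(colnames(X)[-1], collapse = ", "),
      call. = FALSE
    )
  }
  a3 <- car::Anova(fit, type = 3)
  grow <- which(rownames(a3) == "group")
  rrow <- which(rownames(a3) == "Residuals")
  ss_g <- a3[grow, "Sum Sq"]
  ss_r <- a3[rrow, "Sum Sq"]

  emm <- emmeans::emmeans(fit, "group")
  adj <- as.data.frame(emm)
  ph <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "bonferroni"))

  structure(list(
    F = a3[grow, "F value"],
    df_num = a3[grow, "Df"],
    df_den = a3[rrow, "Df"],
    p = a3[grow, "Pr(>F)"],
    eta_sq = ss_g / (ss_g + ss_r),
    adjusted_means = adj,
    posthoc = ph,
    model = fit
  ), class = "ccc_ancova")
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlates the residuals of `x` and `y` after linear removal of the
#' covariates (categorical covariates expanded to dummies). The test is
#' two-sided from `t = r * sqrt(df / (1 - r^2))` with
#' `df = n - 2 - k`, `k` the number of covariate parameters.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data.frame of covariates, or `NULL` for a plain Pearson
#'   correlation.
#' @return List (`CorrelationResult`): `r`, `df`, `t`, `p`, `n`,
#'   `covariates` (names used). Zero residual variance gives `r = NA` with a
#'   `reason`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    Z <- matrix(1, n, 1)
    k <- 0L
    cov_names <- character(0)
  } else {
    covariates <- covariates[keep, , drop = FALSE]
    for (nm in names(covariates)) {
      if (is.character(covariates[[nm]])) {
        covariates[[nm]] <- factor(covariates[[nm]])
      }
    }
    Z <- stats::model.matrix(~., data = covariates)
    k <- ncol(Z) - 1L
    cov_names <- names(covariates)
  }
  if (n <= k + 2) stop("need n > covariate parameters + 2", call. = FALSE)
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  degenerate <- function(res, orig) {
    stats::sd(res) <= 1e-10 * max(stats::sd(orig), 1e-300)
  }
  if (degenerate(rx, x) || degenerate(ry, y)) {
    return(list(
      r = NA_real_, df = NA_integer_, t = NA_real_, p = NA_real_, n = n,
      covariates = cov_names, reason = "zero residual variance"
    ))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(
    r = r, df = df, t = tval,
    p = 2 * stats::pt(-abs(tval), df),
    n = n, covariates = cov_names
  )
}

#' Fisher-z comparison of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1 - 3) + 1/(n2 - 3))` with a
#' two-sided normal p value.
#'
#' @param r1,r2 Correlation coefficients (|r| < 1).
#' @param n1,n2 Sample sizes (> 3).
#' @return List: `z`, `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations must satisfy |r| < 1", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' BIC approximation to the Bayes factor for nested models
#'
#' `BF10 = exp((BIC_null - BIC_alt) / 2)`. This is the standard unit-
#' information-prior approximation; it is not identical to a JZS Bayes
#' factor and is reported as a descriptive supplement only.
#'
#' @param loglik_null,loglik_alt Maximised log-likelihoods of the nested
#'   fits on identical data.
#' @param k_null,k_alt Parameter counts.
#' @param n Sample size.
#' @return `BF10` (numeric).
#' @export
bf_bic <- function(loglik_null, k_null, loglik_alt, k_alt, n) {
  if (n <= max(k_null, k_alt)) stop("need n > number of parameters", call. = FALSE)
  bic_null <- -2 * loglik_null + k_null * log(n)
  bic_alt <- -2 * loglik_alt + k_alt * log(n)
  exp((bic_null - bic_alt) / 2)
}

#' Evidence label for a Bayes factor
#'
#' `BF10 > 3`: evidence for H1; `BF10 < 1/3`: evidence for H0; otherwise
#' inconclusive.
#'
#' @param bf10 Bayes factor.
#' @return Character label.
#' @export
bf_label <- function(bf10) {
  if (bf10 > 3) {
    "evidence for H1"
  } else if (bf10 < 1 / 3) {
    "evidence for H0"
  } else {
    "inconclusive"
  }
}
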