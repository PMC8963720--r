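# Chi-square, covariate-adjusted ANOVA, partial correlations, Fisher z, and
# the BIC Bayes factor approximation.

test_that("chi-square reproduces the study's demographic statistics", {
  sex_by_group <- rbind(c(29, 10), c(24, 10), c(17, 19))
  res <- chisq_independence(sex_by_group)
  expect_equal(round(res$chi2, 2), 6.87)
  expect_equal(res$df, 2)
  expect_equal(round(res$p, 3), 0.032)

  td_vs_adhd <- rbind(c(29, 10), c(17, 19))
  expect_equal(round(chisq_independence(td_vs_adhd)$chi2, 2), 5.81)
})

test_that("chi-square equals the hand-computed Pearson statistic", {
  set.seed(61)
  for (i in 1:25) {
    tab <- matrix(rpois(6, 12) + 1, nrow = sample(2:3, 1))
    res <- chisq_independence(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chi2, sum((tab - E)^2 / E))
    expect_equal(res$df, (nrow(tab) - 1) * (ncol(tab) - 1))
  }
})

test_that("2x2 chi-square equals the squared two-proportion z statistic", {
  tab <- rbind(c(15, 24), c(9, 25))
  n1 <- sum(tab[1, ])
  n2 <- sum(tab[2, ])
  p1 <- tab[1, 1] / n1
  p2 <- tab[2, 1] / n2
  p <- (tab[1, 1] + tab[2, 1]) / (n1 + n2)
  z <- (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  expect_equal(chisq_independence(tab)$chi2, z^2)
})

test_that("proportional rows and zero margins are handled", {
  expect_equal(chisq_independence(rbind(c(10, 20), c(5, 10)))$chi2, 0)
  res <- chisq_independence(rbind(c(0, 0), c(5, 10)))
  expect_true(is.na(res$chi2))
  expect_error(chisq_independence(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("ANCOVA group F equals a two-model residual-sum-of-squares oracle", {
  set.seed(62)
  n <- 12
  d <- data.frame(
    y = rnorm(n, rep(c(10, 12, 15), each = 4), 2),
    g = rep(c("a", "b", "c"), each = 4),
    age = runif(n, 8, 13),
    sex = sample(c("M", "F"), n, replace = TRUE)
  )
  res <- ancova(d$y, d$g, d[, c("age", "sex")])
  full <- lm(y ~ g + age + sex, data = d)
  red <- lm(y ~ age + sex, data = d)
  rss_f <- sum(residuals(full)^2)
  rss_r <- sum(residuals(red)^2)
  df_f <- n - length(coef(full))
  f_oracle <- ((rss_r - rss_f) / 2) / (rss_f / df_f)
  expect_equal(res$F, f_oracle)
  expect_equal(res$df_den, df_f)
  expect_equal(res$eta_sq, (rss_r - rss_f) / rss_r)
})

test_that("ANCOVA without covariates equals the textbook one-way F", {
  set.seed(63)
  y <- rnorm(30, rep(c(5, 6, 8), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  res <- ancova(y, g)
  means <- tapply(y, g, mean)
  ss_b <- sum(10 * (means - mean(y))^2)
  ss_w <- sum((y - means[g])^2)
  f_oracle <- (ss_b / 2) / (ss_w / 27)
  expect_equal(res$F, f_oracle)
  expect_equal(res$df_num, 2)
  expect_equal(res$df_den, 27)
})

test_that("ANCOVA is null-calibrated and reports adjusted contrasts", {
  set.seed(64)
  n <- 600
  d <- data.frame(
    y = rnorm(n, 10, 2),
    g = sample(c("a", "b", "c"), n, replace = TRUE),
    noise = rnorm(n)
  )
  res <- ancova(d$y, d$g, d[, "noise", drop = FALSE])
  expect_lt(res$F, 4)
  expect_gt(res$p, 0.01)
  expect_lt(res$eta_sq, 0.02)
  expect_equal(nrow(res$posthoc), 3)
  expect_equal(nrow(res$adjusted_means), 3)
})

test_that("rank-deficient designs are rejected with the columns named", {
  y <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  covs <- data.frame(x1 = 1:20, x2 = 2 * (1:20))
  expect_error(ancova(y, g, covs), "rank-deficient")
})

test_that("partial correlation matches the precision-matrix identity", {
  set.seed(65)
  x <- rnorm(8)
  y <- 0.5 * x + rnorm(8)
  z1 <- rnorm(8)
  z2 <- 0.3 * x + rnorm(8)
  covs <- data.frame(z1 = z1, z2 = z2)
  res <- partial_correlation(x, y, covs)
  omega <- solve(cov(cbind(x, y, z1, z2)))
  oracle <- -omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2])
  expect_equal(res$r, oracle)
  expect_equal(res$df, 8 - 2 - 2)
})

test_that("partial correlation degenerates and symmetrizes correctly", {
  set.seed(66)
  x <- rnorm(40)
  y <- rnorm(40)
  ortho <- data.frame(z = rnorm(40))
  # covariates orthogonal by construction: residualize z against x and y
  ortho$z <- residuals(lm(ortho$z ~ x + y))
  res <- partial_correlation(x, y, ortho)
  expect_equal(res$r, cor(x, y), tolerance = 1e-10)

  # y identical to a covariate leaves no partial association
  res2 <- partial_correlation(x, x * 2 + 3, data.frame(w = x))
  expect_true(is.na(res2$r))

  # symmetry and affine invariance of covariates
  covs <- data.frame(a = rnorm(40))
  expect_equal(
    partial_correlation(x, y, covs)$r,
    partial_correlation(y, x, covs)$r
  )
  expect_equal(
    partial_correlation(x, y, covs)$r,
    partial_correlation(x, y, data.frame(a = 5 * covs$a - 2))$r
  )
})

test_that("Fisher z comparison follows the closed form", {
  expect_equal(fisher_z_compare(0.4, 40, 0.4, 50)$z, 0)
  res <- fisher_z_compare(0.5, 50, 0, 50)
  expect_equal(round(res$z, 2), 2.66)
  expect_equal(res$z, atanh(0.5) / sqrt(2 / 47))
  expect_equal(
    fisher_z_compare(0.5, 50, 0, 50)$z,
    -fisher_z_compare(0, 50, 0.5, 50)$z
  )
  expect_error(fisher_z_compare(1, 50, 0, 50), "\\|r\\|")
  expect_error(fisher_z_compare(0.5, 3, 0, 50), "n > 3")
})

test_that("BIC Bayes factor follows the closed form and labels evidence", {
  expect_equal(bf_bic(-100, 3, -100, 3, 50), 1)
  # a BIC difference of 2 in favour of the alternative gives BF10 = e
  n <- 50
  ll_alt <- -100
  ll_null <- ll_alt - (2 + log(n)) / 2
  expect_equal(bf_bic(ll_null, 3, ll_alt, 4, n), exp(1))
  expect_identical(bf_label(5), "evidence for H1")
  expect_identical(bf_label(0.2), "evidence for H0")
  expect_identical(bf_label(1), "inconclusive")
})
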