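# CUE-GMM estimation: objective, unrobust/robust fits, heterogeneity test,
# Wald intervals.

test_that("CUE objective matches hand computation and vanishes at exact fit", {
  # K = 1, p = 2, diagonal Omega: Q(theta) = (0.5-theta)^2/0.2 + (0.1-2theta)^2/0.5
  red <- make_reduction(B = c(1, 2), by = c(0.5, 0.1),
                        omega_yy = diag(c(0.2, 0.5)),
                        omega_blocks = list(list(matrix(0, 2, 2))))
  expect_equal(cue_objective(0.3, 0, red), 0.2^2 / 0.2 + 0.5^2 / 0.5,
               tolerance = 1e-12)
  # exact solution: g = 0 -> Q = 0
  red0 <- make_reduction(B = c(1, 2), by = c(0.4, 0.8),
                         omega_yy = diag(c(0.2, 0.5)),
                         omega_blocks = list(list(matrix(0, 2, 2))))
  expect_equal(cue_objective(0.4, 0, red0), 0)
  expect_error(cue_objective(0.3, -1, red), "non-negative")
})

test_that("objective is non-increasing in kappa2 when moments are non-zero", {
  set.seed(21)
  for (i in 1:5) {
    p <- 6
    B <- matrix(rnorm(p * 2), p, 2)
    red <- make_reduction(B, by = rnorm(p), omega_yy = crossprod(matrix(rnorm(p * p), p)) / p + diag(p) * 0.1)
    th <- rnorm(2)
    ks <- c(0, 0.1, 0.5, 1, 5)
    qs <- vapply(ks, function(k) cue_objective(th, k, red), numeric(1))
    expect_true(all(diff(qs) <= 1e-10))
  }
})

test_that("unrobust fit matches a dense grid-search oracle on a small instance", {
  set.seed(31)
  B <- matrix(c(1.0, 0.4, 0.2, 0.8,
                0.3, 1.1, 0.7, 0.1), 4, 2)
  by <- drop(B %*% c(0.3, -0.2)) + c(0.02, -0.03, 0.01, 0.015)
  blocks <- list(list(diag(0.01, 4), matrix(0, 4, 4)),
                 list(matrix(0, 4, 4), diag(0.01, 4)))
  red <- make_reduction(B, by, omega_yy = diag(0.02, 4),
                        omega_blocks = blocks)
  fit <- fit_unrobust(red)
  expect_true(fit$converged)

  # two-stage dense grid over theta
  g1 <- seq(-1, 1, by = 0.01)
  qg <- outer(g1, g1, Vectorize(function(a, b) cue_objective(c(a, b), 0, red)))
  i0 <- which(qg == min(qg), arr.ind = TRUE)[1, ]
  c0 <- c(g1[i0[1]], g1[i0[2]])
  g2a <- seq(c0[1] - 0.01, c0[1] + 0.01, by = 2e-4)
  g2b <- seq(c0[2] - 0.01, c0[2] + 0.01, by = 2e-4)
  qg2 <- outer(g2a, g2b, Vectorize(function(a, b) cue_objective(c(a, b), 0, red)))
  i1 <- which(qg2 == min(qg2), arr.ind = TRUE)[1, ]
  grid_theta <- c(g2a[i1[1]], g2b[i1[2]])

  expect_lte(fit$q_stat, min(qg2) + 1e-4)
  expect_equal(unname(fit$theta), grid_theta, tolerance = 5e-3)
})

test_that("with fixed weighting the estimator reduces to the IVW/GLS solution", {
  # K = 1 and zero risk-factor uncertainty: Omega does not depend on theta,
  # so CUE equals generalized least squares in closed form
  set.seed(41)
  p <- 8
  B <- matrix(rnorm(p, 0, 1), p, 1)
  W <- diag(runif(p, 0.01, 0.1))
  by <- drop(B) * 0.25 + rnorm(p, 0, 0.05)
  red <- make_reduction(B, by, omega_yy = W,
                        omega_blocks = list(list(matrix(0, p, p))))
  fit <- fit_unrobust(red)
  gls <- drop(solve(t(B) %*% solve(W) %*% B, t(B) %*% solve(W) %*% by))
  expect_equal(unname(fit$theta), gls, tolerance = 1e-6)
})

test_that("exact proportional data recover theta with zero heterogeneity", {
  B <- matrix(c(0.5, 1, 1.5, -0.7), 4, 1)
  red <- make_reduction(B, by = drop(B) * 0.8, omega_yy = diag(0.01, 4),
                        omega_blocks = list(list(matrix(0, 4, 4))))
  fit <- fit_unrobust(red)
  expect_equal(unname(fit$theta), 0.8, tolerance = 1e-8)
  expect_equal(fit$q_stat, 0, tolerance = 1e-10)
  ht <- heterogeneity_test(fit)
  expect_equal(ht$pvalue, 1)
})

test_that("robust fit floors kappa2 at zero and otherwise matches a root oracle", {
  # under-dispersed data: kappa2 = 0 and the fit equals the unrobust one
  B <- matrix(c(0.5, 1, 1.5, -0.7, 0.9, 1.1), 6, 1)
  red <- make_reduction(B, by = drop(B) * 0.8 + 1e-4,
                        omega_yy = diag(0.05, 6),
                        omega_blocks = list(list(matrix(0, 6, 6))))
  fr <- fit_robust(red)
  fu <- fit_unrobust(red)
  expect_equal(fr$kappa2, 0)
  expect_equal(fr$theta, fu$theta, tolerance = 1e-8)

  # inflated residuals: kappa2 solves Q(theta_hat, k2) = p - K; check against
  # an independent scalar root-finder at the fitted theta
  set.seed(51)
  by2 <- drop(B) * 0.8 + rnorm(6, 0, 0.6)
  red2 <- make_reduction(B, by2, omega_yy = diag(0.05, 6),
                         omega_blocks = list(list(matrix(0, 6, 6))))
  fr2 <- fit_robust(red2)
  expect_gt(fr2$kappa2, 0)
  df <- red2$p - 1
  f <- function(k2) cue_objective(fr2$theta, k2, red2) - df
  oracle <- uniroot(f, c(1e-12, 1e6), tol = 1e-12)$root
  expect_equal(fr2$kappa2, oracle, tolerance = 1e-4)
  expect_equal(cue_objective(fr2$theta, fr2$kappa2, red2), df,
               tolerance = 1e-6)

  # robust standard errors dominate when kappa2 > 0
  fu2 <- fit_unrobust(red2)
  expect_true(all(fr2$se_theta >= fu2$se_theta - 1e-10))
})

test_that("heterogeneity test matches the chi-squared reference and rejects robust fits", {
  set.seed(61)
  B <- matrix(rnorm(12), 12, 1)
  red <- make_reduction(B, by = drop(B) * 0.5 + rnorm(12, 0, 0.3),
                        omega_yy = diag(0.04, 12),
                        omega_blocks = list(list(matrix(0, 12, 12))))
  fu <- fit_unrobust(red)
  ht <- heterogeneity_test(fu)
  expect_equal(ht$df, 11)
  expect_equal(ht$pvalue, pchisq(fu$q_stat, 11, lower.tail = FALSE))
  fr <- fit_robust(red)
  expect_error(heterogeneity_test(fr), "robust")
})

test_that("Wald intervals reproduce the reference log-odds interval shape", {
  fit <- structure(list(theta = c(BMI = 1.146),
                        se_theta = c(BMI = 0.854 / qnorm(0.975))),
                   class = "pcgmm_fit")
  ci <- wald_ci(fit, 0.95)
  expect_equal(ci$lower, 0.292, tolerance = 1e-3)
  expect_equal(ci$upper, 2.000, tolerance = 1e-3)

  # nested levels
  ci90 <- wald_ci(fit, 0.90)
  expect_gt(ci90$lower, ci$lower)
  expect_lt(ci90$upper, ci$upper)

  # zero SE collapses the interval onto the estimate
  fit0 <- structure(list(theta = c(x = 0.5), se_theta = c(x = 0)),
                    class = "pcgmm_fit")
  ci0 <- wald_ci(fit0, 0.95)
  expect_equal(ci0$lower, 0.5)
  expect_equal(ci0$upper, 0.5)
  expect_error(wald_ci(fit0, 1.2), "level")
})

test_that("identification guard: p <= K is rejected", {
  red <- make_reduction(matrix(rnorm(4), 2, 2), c(0.1, 0.2), diag(0.1, 2))
  expect_error(fit_unrobust(red), "identify")
  expect_error(fit_robust(make_reduction(matrix(rnorm(6), 3, 2),
                                         rnorm(3), diag(0.1, 3))),
               "overidentification")
})
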