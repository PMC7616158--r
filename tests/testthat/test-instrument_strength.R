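# Conditional F-statistics for dimension-reduced associations.

test_that("statistic is zero when the rank reduction holds exactly", {
  # column 2 is exactly a linear combination of columns 1 and 3
  B <- cbind(c(1, 0.5, 0.2, 0.9, 0.1),
             NA,
             c(0.3, 1.2, 0.8, 0.4, 0.6))
  B[, 2] <- 0.7 * B[, 1] - 0.4 * B[, 3]
  red <- make_reduction(B, by = rnorm(5), omega_yy = diag(0.01, 5))
  res <- conditional_f(red, 2)
  expect_lt(res$statistic, 1e-8)
  expect_equal(res$df, 5 - 3 + 1)
  expect_equal(res$pvalue, 1, tolerance = 1e-6)
})

test_that("statistic matches a dense grid-search oracle when the weight is stable", {
  # make the non-tested factor's uncertainty negligible so the criterion's
  # weight matrix is effectively constant in delta and the GLS solution is
  # the global minimizer
  B <- matrix(c(1.0, 0.4, 0.2, 0.8,
                0.3, 1.1, 0.7, 0.1), 4, 2)
  blocks <- list(list(diag(c(0.02, 0.03, 0.015, 0.025)), matrix(0, 4, 4)),
                 list(matrix(0, 4, 4), diag(1e-10, 4)))
  red <- make_reduction(B, by = rnorm(4), omega_yy = diag(0.01, 4),
                        omega_blocks = blocks)
  res <- conditional_f(red, 1)
  q_fit <- res$statistic * res$df

  V <- blocks[[1]][[1]]  # weight effectively constant
  grid <- seq(-3, 3, by = 1e-4)
  qs <- vapply(grid, function(d) {
    h <- B[, 1] - d * B[, 2]
    drop(t(h) %*% solve(V + d^2 * blocks[[2]][[2]]) %*% h)
  }, numeric(1))
  expect_equal(q_fit, min(qs), tolerance = 1e-4)
  expect_equal(res$df, 3)
})

test_that("a mirror-symmetric two-factor system gives equal conditional Fs", {
  b1 <- c(1, 2, 3, 4)
  B <- cbind(b1, rev(b1))
  red <- make_reduction(B, by = rnorm(4), omega_yy = diag(0.01, 4),
                        omega_blocks = list(list(diag(0.01, 4), matrix(0, 4, 4)),
                                            list(matrix(0, 4, 4), diag(0.01, 4))))
  cf <- suppressMessages(all_conditional_f(red))
  expect_equal(unname(cf$f_stats[1]), unname(cf$f_stats[2]), tolerance = 1e-8)
})

test_that("statistic is invariant to rescaling one factor's betas and SEs", {
  set.seed(71)
  p <- 6
  B <- matrix(rnorm(p * 3), p, 3)
  mk_blocks <- function(scales) {
    lapply(1:3, function(k) lapply(1:3, function(l) {
      if (k == l) diag(0.01 * scales[k]^2, p) else matrix(0, p, p)
    }))
  }
  red1 <- make_reduction(B, by = rnorm(p), omega_yy = diag(0.01, p),
                         omega_blocks = mk_blocks(c(1, 1, 1)))
  c_scale <- 3.7
  B2 <- B
  B2[, 2] <- B[, 2] * c_scale
  red2 <- make_reduction(B2, by = red1$beta_y_pc, omega_yy = diag(0.01, p),
                         omega_blocks = mk_blocks(c(1, c_scale, 1)))
  f1 <- suppressMessages(all_conditional_f(red1))$f_stats
  f2 <- suppressMessages(all_conditional_f(red2))$f_stats
  expect_equal(unname(f1), unname(f2), tolerance = 1e-6)
})

test_that("single risk factor falls back to the mean chi-squared association", {
  set.seed(72)
  p <- 5
  B <- matrix(rnorm(p), p, 1)
  V <- diag(0.02, p)
  red <- make_reduction(B, by = rnorm(p), omega_yy = diag(0.01, p),
                        omega_blocks = list(list(V)))
  res <- conditional_f(red, 1)
  q <- drop(t(B) %*% solve(V) %*% B)
  expect_equal(res$statistic, q / p, tolerance = 1e-10)
  expect_equal(res$df, p)
})

test_that("simulated phenotypic-heterogeneity patterns behave as designed", {
  ld <- synthetic_ld()
  # xi = 0: factors 2 and 3 share instruments -> their conditional Fs are
  # near the null level while factor 1 keeps unique signal
  spec0 <- simulation_spec(xi = 0, kappa2 = 0, n_x = 20000, n_y = 20000,
                           seed = 202)
  d0 <- generate_two_sample(spec0, ld)
  r0 <- pc_transform(d0, ld, 0.9999,
                     trait_cor = trait_correlation(attr(d0, "trait_cor")))
  cf0 <- suppressMessages(all_conditional_f(r0))
  expect_gt(cf0$f_stats[1], 5)
  expect_lt(cf0$f_stats[2], 3)
  expect_lt(cf0$f_stats[3], 3)

  # xi = 1: all factors have their own instruments and all Fs grow with n
  fstat_at <- function(n, seed) {
    sp <- simulation_spec(xi = 1, kappa2 = 0, n_x = n, n_y = n, seed = seed)
    d <- generate_two_sample(sp, ld)
    r <- pc_transform(d, ld, 0.9999,
                      trait_cor = trait_correlation(attr(d, "trait_cor")))
    suppressMessages(all_conditional_f(r))$f_stats
  }
  f_small <- fstat_at(1500, 203)
  f_large <- fstat_at(20000, 204)
  expect_true(all(f_large > f_small))
  expect_true(all(f_large > 10))
})

test_that("fewer retained components raises conditional F on trait-driven data", {
  ld <- synthetic_ld()
  spec <- simulation_spec(xi = 1, kappa2 = 0, n_x = 20000, n_y = 20000,
                          seed = 205)
  d <- generate_two_sample(spec, ld)
  tc <- trait_correlation(attr(d, "trait_cor"))
  r_hi <- pc_transform(d, ld, 0.9999, trait_cor = tc)
  r_lo <- pc_transform(d, ld, 0.99, trait_cor = tc)
  expect_lt(r_lo$p, r_hi$p)
  f_hi <- suppressMessages(all_conditional_f(r_hi))$f_stats
  f_lo <- suppressMessages(all_conditional_f(r_lo))$f_stats
  expect_gt(mean(f_lo), mean(f_hi))
})
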