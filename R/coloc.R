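# Approximate-Bayes-factor colocalization for two traits in one region,
# under the single-causal-variant-per-trait assumption, with sensitivity
# analysis over the shared-causal-variant prior.

#' Per-variant approximate Bayes factors
#'
#' Wakefield-style log approximate Bayes factor comparing a normal effect
#' prior of standard deviation `prior_sd` against the point null, for each
#' variant: with shrinkage ratio `r = prior_sd^2 / (prior_sd^2 + se^2)` and
#' `z = beta / se`, `logABF = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se marginal association estimates and standard errors
#'   (`se > 0`).
#' @param prior_sd prior standard deviation of the true effect; 0.15 is the
#'   usual default for quantitative traits and 0.2 for log odds ratios.
#' @return Length-J vector of log ABFs (natural log).
#' @export
approximate_bayes_factors <- function(beta, se, prior_sd = 0.15) {
  if (!all(is.finite(beta)) || !all(is.finite(se))) {
    stop("non-finite association estimates", call. = FALSE)
  }
  assert_that(all(se > 0), "standard errors must be strictly positive")
  assert_that(prior_sd >= 0, "prior_sd must be non-negative")
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalization of two traits in one region
#'
#' Enumerates the standard five hypotheses under one causal variant per
#' trait: H0 no association with either trait, H1/H2 association with one
#' trait only, H3 distinct causal variants, H4 a shared causal variant.
#' Per-variant approximate Bayes factors are combined over the J (H1), J
#' (H2), J(J-1) (H3) and J (H4) causal-variant configurations with prior
#' weights `p1`, `p2`, `p1 p2` and `p12`, aggregated by log-sum-exp, and
#' normalized. The analysis runs on marginal (not PC-transformed)
#' associations.
#'
#' @param data1,data2 lists with components `beta` and `se` for the two
#'   traits, in a shared variant order.
#' @param priors length-3 vector `(p1, p2, p12)`: per-variant prior
#'   probabilities of being causal for trait 1 only, trait 2 only, and both.
#'   Defaults `(1e-4, 1e-4, 1e-5)`.
#' @param prior_sd1,prior_sd2 effect-size prior standard deviations for the
#'   two traits (0.15 for quantitative traits; use 0.2 for case-control
#'   log odds ratios).
#' @return Object of class `coloc_result`: list with `posteriors` (named
#'   H0..H4, summing to 1), `priors`, `conditional_h3` = H3 / (H3 + H4),
#'   and `n_variants`.
#' @export
colocalize <- function(data1, data2, priors = c(1e-4, 1e-4, 1e-5),
                       prior_sd1 = 0.15, prior_sd2 = 0.15) {
  assert_that(length(data1$beta) == length(data2$beta) &&
                length(data1$se) == length(data2$se) &&
                length(data1$beta) == length(data1$se),
              "trait 1 and trait 2 must cover the same variants")
  assert_that(all(priors > 0) && sum(priors) < 1,
              "priors must be positive with p1 + p2 + p12 < 1")
  p1 <- priors[1]; p2 <- priors[2]; p12 <- priors[3]
  l1 <- approximate_bayes_factors(data1$beta, data1$se, prior_sd1)
  l2 <- approximate_bayes_factors(data2$beta, data2$se, prior_sd2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over i != j of ABF1_i * ABF2_j = (sum_i)(sum_j) - sum_j(both at j)
  s3 <- .logdiff(s1 + s2, s12)
  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + s3,
          H4 = log(p12) + s12)
  post <- exp(lh - logsumexp(lh))
  structure(list(posteriors = post / sum(post),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 conditional_h3 = post[["H3"]] / (post[["H3"]] + post[["H4"]]),
                 n_variants = length(l1)),
            class = "coloc_result")
}

# log(exp(a) - exp(b)) for a >= b, clamped at -Inf when equal (J = 1: no
# distinct-variant configurations exist)
#' @noRd
.logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d variants (p1 = %g, p2 = %g, p12 = %g)\n",
              x$n_variants, x$priors[1], x$priors[2], x$priors[3]))
  print(round(x$posteriors, 4))
  cat(sprintf("P(distinct | both causal) = H3/(H3+H4) = %.4f\n",
              x$conditional_h3))
  invisible(x)
}

#' Sensitivity of colocalization to the shared-variant prior
#'
#' Re-runs [colocalize()] across a grid of `p12` values. The posterior of
#' the shared-variant hypothesis H4 is non-decreasing in `p12`, so the grid
#' shows how robust a colocalization conclusion is to this prior.
#'
#' @inheritParams colocalize
#' @param p12_grid vector of positive `p12` values.
#' @param p1,p2 per-trait priors held fixed across the grid.
#' @return data.frame with one row per `p12`: the five posteriors and the
#'   conditional H3 share.
#' @export
p12_sensitivity <- function(data1, data2, p12_grid = 10^seq(-7, -4, by = 0.5),
                            p1 = 1e-4, p2 = 1e-4,
                            prior_sd1 = 0.15, prior_sd2 = 0.15) {
  rows <- lapply(p12_grid, function(p12) {
    res <- colocalize(data1, data2, priors = c(p1, p2, p12),
                      prior_sd1 = prior_sd1, prior_sd2 = prior_sd2)
    data.frame(p12 = p12, t(res$posteriors),
               conditional_h3 = res$conditional_h3)
  })
  do.call(rbind, rows)
}
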