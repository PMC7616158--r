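# Bayesian model averaging over risk-factor subsets applied to the
# PC-transformed multivariable coefficients: posterior model probabilities
# and marginal inclusion probabilities.

#' Log marginal likelihood of a risk-factor subset
#'
#' Gaussian evidence for the sub-model `beta_y_pc = beta_x_pc[, subset]
#' theta_s + noise`, with noise covariance `omega_yy` and independent
#' Gaussian effect priors `theta_s ~ N(0, sigma_prior^2 I)`. The marginal
#' distribution of `beta_y_pc` is normal with covariance
#' `sigma_prior^2 B_s B_s' + omega_yy`, giving a closed form.
#'
#' @param red a `pc_reduction`.
#' @param subset non-empty integer vector of risk-factor indices.
#' @param sigma_prior prior standard deviation of causal effects on the
#'   standardized PC scale.
#' @return Scalar log marginal likelihood.
#' @export
model_evidence <- function(red, subset, sigma_prior = 0.5) {
  assert_that(length(subset) >= 1, "subset must be non-empty")
  assert_that(red$p > length(subset),
              "need more components than risk factors in the subset")
  B <- red$beta_x_pc[, subset, drop = FALSE]
  C <- sigma_prior^2 * tcrossprod(B) + red$omega_yy
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular marginal covariance in model evidence", call. = FALSE))
  v <- backsolve(ch, red$beta_y_pc, transpose = TRUE)
  -0.5 * (red$p * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(v^2))
}

#' Exhaustive Bayesian model averaging over risk-factor subsets
#'
#' Enumerates every non-empty subset of risk factors up to `max_size`,
#' scores each by its Gaussian evidence ([model_evidence()]) times an
#' independent-inclusion prior `prior_p^s (1 - prior_p)^(K - s)` for a
#' subset of size `s`, and normalizes. Each risk factor's marginal
#' inclusion probability is the summed posterior of all models containing
#' it. Exhaustive enumeration is exact and fast for K up to ~20 risk
#' factors (the stochastic-search approximation used for larger panels is
#' unnecessary here).
#'
#' @param red a `pc_reduction`.
#' @param prior_p prior inclusion probability per risk factor (default 0.1,
#'   a prior expectation of about one causal risk factor in ten).
#' @param sigma_prior effect-size prior standard deviation.
#' @param max_size largest subset size enumerated (default K).
#' @return Object of class `bma_result`: `models` (data.frame of subset
#'   label, size and posterior probability, sorted descending),
#'   `inclusion` (length-K named vector), `prior_p`.
#' @export
enumerate_bma <- function(red, prior_p = 0.1, sigma_prior = 0.5,
                          max_size = NULL) {
  K <- ncol(red$beta_x_pc)
  if (K > 20) {
    stop("exhaustive enumeration supports at most 20 risk factors; cap the panel",
         call. = FALSE)
  }
  assert_that(prior_p > 0 && prior_p < 1, "prior_p must be in (0, 1)")
  max_size <- min(max_size %||% K, K)
  subsets <- list()
  for (s in seq_len(max_size)) {
    cmb <- utils::combn(K, s, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  log_ev <- vapply(subsets, function(sub) model_evidence(red, sub, sigma_prior),
                   numeric(1))
  sizes <- lengths(subsets)
  log_prior <- sizes * log(prior_p) + (K - sizes) * log1p(-prior_p)
  lp <- log_ev + log_prior
  post <- exp(lp - logsumexp(lp))
  post <- post / sum(post)
  inclusion <- vapply(seq_len(K), function(k)
    sum(post[vapply(subsets, function(sub) k %in% sub, logical(1))]),
    numeric(1))
  names(inclusion) <- red$trait_names
  labels <- vapply(subsets, function(sub)
    paste(red$trait_names[sub], collapse = "+"), character(1))
  ord <- order(post, decreasing = TRUE)
  models <- data.frame(model = labels[ord], size = sizes[ord],
                       posterior = post[ord], row.names = NULL)
  structure(list(models = models, inclusion = inclusion, prior_p = prior_p,
                 sigma_prior = sigma_prior),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, n = 5, ...) {
  cat(sprintf("Bayesian model averaging (prior inclusion p = %g):\n", x$prior_p))
  cat("Top models:\n")
  print(utils::head(transform(x$models, posterior = round(posterior, 4)), n))
  cat("Marginal inclusion probabilities:\n")
  print(round(sort(x$inclusion, decreasing = TRUE), 4))
  invisible(x)
}
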