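# Conditional F-statistics for dimension-reduced genetic associations:
# tests of phenotypic heterogeneity per risk factor.

#' Conditional F-statistic for one risk factor
#'
#' Tests the null hypothesis that the PC-scale genetic associations of risk
#' factor `k` are a linear combination of the associations of the other
#' risk factors (a rank reduction of one, i.e. no phenotypic heterogeneity
#' for that risk factor). The test evaluates the variance-standardized
#' quadratic form of the residual moment
#' `beta_x_pc[, k] - beta_x_pc[, -k] delta` at the combination `delta`
#' solving the generalized-least-squares estimating equations, with the
#' moment covariance re-evaluated continuously in `delta` using the
#' trait-correlation-aware covariance blocks. (Solving the estimating
#' equations, rather than fully minimizing the weighted form including its
#' weight-derivative term, preserves the per-risk-factor interpretation:
#' the full minimum is the same for every `k`, a symmetric rank statistic.)
#' The resulting quadratic form
#' is asymptotically chi-squared with `p - K + 1` degrees of freedom under
#' the null; the F-statistic is the quadratic form divided by its degrees
#' of freedom, so values near 1 indicate no evidence of heterogeneity and
#' large values indicate strong phenotypic heterogeneity. These are plain
#' chi-squared critical values, not weak-instrument-adjusted ones.
#'
#' With a single risk factor the unconditional version is returned: the
#' mean chi-squared association of the PC-scale coefficients (`p` degrees
#' of freedom).
#'
#' @param red a `pc_reduction`.
#' @param k risk-factor index.
#' @return List with `statistic` (the F value), `df`, `pvalue`, and `delta`
#'   (the minimizing combination; `NULL` when K = 1).
#' @export
conditional_f <- function(red, k) {
  K <- ncol(red$beta_x_pc)
  p <- red$p
  assert_that(k >= 1 && k <= K, "risk-factor index out of range")
  if (K == 1L) {
    V <- omega_x_block(red, 1, 1)
    q <- quad_inv(V, red$beta_x_pc[, 1])
    return(list(statistic = q / p, df = p,
                pvalue = stats::pchisq(q, p, lower.tail = FALSE),
                delta = NULL))
  }
  assert_that(p > K, "need more components than risk factors")
  others <- setdiff(seq_len(K), k)
  bk <- red$beta_x_pc[, k]
  Bo <- red$beta_x_pc[, others, drop = FALSE]
  blocks <- .omega_blocks(red)
  cvec_of <- function(delta) {
    cv <- numeric(K)
    cv[k] <- 1
    cv[others] <- -delta
    cv
  }
  V_of <- function(cv) {
    V <- matrix(0, p, p)
    for (a in seq_len(K)) {
      if (cv[a] == 0) next
      for (b in seq_len(K)) {
        if (cv[b] == 0) next
        V <- V + (cv[a] * cv[b]) * blocks[[a]][[b]]
      }
    }
    (V + t(V)) / 2
  }
  obj <- function(delta) {
    cv <- cvec_of(delta)
    quad_inv(V_of(cv), bk - drop(Bo %*% delta))
  }
  # delta is estimated by iterated generalized least squares with the weight
  # matrix continuously re-evaluated at the current delta. Solving the GLS
  # estimating equations (rather than fully minimizing the quadratic form
  # including its weight-derivative term) keeps the per-risk-factor meaning
  # of the statistic: the fully-minimized form is invariant to which risk
  # factor is singled out and degenerates into a symmetric rank statistic.
  delta <- tryCatch(qr.solve(Bo, bk), error = function(e) rep(0, K - 1))
  q_cur <- obj(delta)
  converged <- FALSE
  for (it in 1:200) {
    W <- inv_spd(V_of(cvec_of(delta)))
    delta_new <- tryCatch(
      drop(solve(crossprod(Bo, W %*% Bo), crossprod(Bo, W %*% bk))),
      error = function(e) delta)
    step <- 1
    q_new <- obj(delta_new)
    while (!is.finite(q_new) && step > 1e-4) {  # damp divergent steps
      step <- step / 2
      delta_new <- delta + step * (delta_new - delta)
      q_new <- obj(delta_new)
    }
    if (max(abs(delta_new - delta)) < 1e-10 * max(1, max(abs(delta)))) {
      delta <- delta_new
      q_cur <- q_new
      converged <- TRUE
      break
    }
    delta <- delta_new
    q_cur <- q_new
  }
  df <- p - K + 1
  list(statistic = q_cur / df, df = df,
       pvalue = stats::pchisq(q_cur, df, lower.tail = FALSE),
       delta = delta, converged = converged)
}

#' Conditional F-statistics for all risk factors
#'
#' Applies [conditional_f()] to each risk factor in turn and attaches
#' weak-instrument warnings: conditional F below 10 is the conventional
#' weak-instrument caution, and values below 1 indicate essentially no
#' unique genetic signal for that risk factor.
#'
#' @param red a `pc_reduction`.
#' @return Object of class `conditional_f_result`: list with `f_stats`,
#'   `df`, `pvalues`, `n_pcs`, `warning_tier` (character:
#'   `"ok"`/`"weak"`/`"very weak"`).
#' @export
all_conditional_f <- function(red) {
  K <- ncol(red$beta_x_pc)
  res <- lapply(seq_len(K), function(k) conditional_f(red, k))
  f <- vapply(res, `[[`, numeric(1), "statistic")
  names(f) <- red$trait_names
  tier <- ifelse(f < 1, "very weak", ifelse(f < 10, "weak", "ok"))
  for (k in seq_len(K)) {
    if (f[k] < 1) {
      pcg_log("conditional F for %s is %.3f (< 1): effectively no unique instrument signal",
              red$trait_names[k], f[k], level = "WARN")
    } else if (f[k] < 10) {
      pcg_log("conditional F for %s is %.3f (< 10): weak-instrument caution",
              red$trait_names[k], f[k], level = "WARN")
    }
  }
  structure(list(f_stats = f,
                 df = res[[1]]$df,
                 pvalues = vapply(res, `[[`, numeric(1), "pvalue"),
                 n_pcs = red$p,
                 warning_tier = tier),
            class = "conditional_f_result")
}

#' @export
print.conditional_f_result <- function(x, ...) {
  cat(sprintf("Conditional F-statistics (%d PCs, chi-squared df = %d):\n",
              x$n_pcs, x$df))
  print(data.frame(F = round(x$f_stats, 3),
                   p = signif(x$pvalues, 3),
                   tier = x$warning_tier))
  invisible(x)
}
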