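# Continuously-updating GMM estimation of multivariable causal effects on
# the principal-component scale, with an overdispersion parameter that
# corrects inference for pleiotropic heterogeneity.

# Moment covariance Omega(theta, kappa2). The theta-dependent part carries
# the sampling uncertainty of the risk-factor coefficients through the
# moment g(theta) = beta_y_pc - beta_x_pc theta (exposure and outcome
# samples are non-overlapping, so there is no cross term). The
# overdispersion term models direct variant effects on the outcome with
# variance kappa2 each: on the PC scale their image is
# kappa2 * S^{-1} (L' rho rho L) S^{-1} (structure "ld", the default), or
# kappa2 * S^{-1} if the excess dispersion is placed on the marginal
# associations themselves (structure "gram").
# Extract the K x K grid of p x p covariance blocks once per fit.
#' @noRd
.omega_blocks <- function(red) {
  K <- ncol(red$beta_x_pc)
  lapply(seq_len(K), function(k)
    lapply(seq_len(K), function(l) omega_x_block(red, k, l)))
}

#' @noRd
.overdisp_mat <- function(red, overdispersion) {
  if (overdispersion == "ld") red$S_inv %*% red$T2 %*% red$S_inv
  else red$S_inv
}

#' @noRd
omega_matrix <- function(red, theta, kappa2 = 0,
                         overdispersion = c("ld", "gram"), blocks = NULL,
                         M = NULL) {
  overdispersion <- match.arg(overdispersion)
  if (is.null(blocks)) blocks <- .omega_blocks(red)
  K <- ncol(red$beta_x_pc)
  Om <- red$omega_yy
  for (k in seq_len(K)) {
    if (theta[k] == 0) next
    for (l in seq_len(K)) {
      if (theta[l] == 0) next
      Om <- Om + (theta[k] * theta[l]) * blocks[[k]][[l]]
    }
  }
  if (kappa2 > 0) {
    if (is.null(M)) M <- .overdisp_mat(red, overdispersion)
    Om <- Om + kappa2 * M
  }
  (Om + t(Om)) / 2
}

# Objective/gradient pair for the CUE criterion at fixed kappa2, closing
# over precomputed blocks. grad dQ/dtheta_k = -2 B_k' u - u' dOmega_k u with
# u = Omega^{-1} g and dOmega_k = sum_l theta_l (Blk_kl + Blk_kl').
#' @noRd
.cue_funs <- function(red, blocks, M) {
  K <- ncol(red$beta_x_pc)
  B <- red$beta_x_pc
  by <- red$beta_y_pc
  omega_at <- function(theta, kappa2) {
    Om <- red$omega_yy
    for (k in seq_len(K)) {
      if (theta[k] == 0) next
      for (l in seq_len(K)) {
        if (theta[l] == 0) next
        Om <- Om + (theta[k] * theta[l]) * blocks[[k]][[l]]
      }
    }
    if (kappa2 > 0) Om <- Om + kappa2 * M
    Om
  }
  fn <- function(theta, kappa2) {
    g <- by - drop(B %*% theta)
    quad_inv(omega_at(theta, kappa2), g)
  }
  gr <- function(theta, kappa2) {
    g <- by - drop(B %*% theta)
    u <- solve_spd(omega_at(theta, kappa2), g)
    vapply(seq_len(K), function(k) {
      dOm <- matrix(0, red$p, red$p)
      for (l in seq_len(K)) {
        if (theta[l] == 0) next
        dOm <- dOm + theta[l] * (blocks[[k]][[l]] + t(blocks[[k]][[l]]))
      }
      -2 * sum(B[, k] * u) - drop(crossprod(u, dOm %*% u))
    }, numeric(1))
  }
  list(fn = fn, gr = gr)
}

#' Continuously-updating GMM objective
#'
#' Evaluates `Q(theta, kappa2) = g(theta)' Omega(theta, kappa2)^{-1}
#' g(theta)` with moment vector `g(theta) = beta_y_pc - beta_x_pc theta`.
#' The weighting matrix is re-evaluated at every candidate `theta`
#' (continuous updating), which reduces weak-instrument bias relative to
#' two-step GMM.
#'
#' @param theta length-K candidate causal effect vector.
#' @param kappa2 non-negative overdispersion parameter.
#' @param red a `pc_reduction` from [transform_associations()].
#' @param overdispersion how direct variant effects enter the moment
#'   covariance: `"ld"` (default; the PC-scale image of variant-scale direct
#'   effects, `kappa2 * S^{-1} L' rho^2 L S^{-1}`) or `"gram"`
#'   (`kappa2 * S^{-1}`, excess dispersion on the marginal scale).
#' @return The scalar objective value (non-negative).
#' @export
cue_objective <- function(theta, kappa2, red, overdispersion = "ld") {
  assert_that(kappa2 >= 0, "kappa2 must be non-negative")
  g <- red$beta_y_pc - drop(red$beta_x_pc %*% theta)
  Om <- omega_matrix(red, theta, kappa2, overdispersion)
  quad_inv(Om, g)
}

#' @noRd
.theta_start <- function(red) {
  # inverse-variance-weighted start: GLS of beta_y_pc on beta_x_pc with
  # weighting Omega(0, 0)^{-1}
  W <- inv_spd(red$omega_yy)
  B <- red$beta_x_pc
  drop(solve(crossprod(B, W %*% B), crossprod(B, W %*% red$beta_y_pc)))
}

#' @noRd
.minimize_theta <- function(funs, kappa2, start, n_starts = 5L) {
  obj <- function(th) funs$fn(th, kappa2)
  grd <- function(th) funs$gr(th, kappa2)
  best <- stats::optim(start, obj, grd, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
  if (best$convergence != 0) {
    set <- lapply(seq_len(n_starts), function(i) {
      stats::optim(start * (1 + 0.2 * (i - 3) / 2) + 0.05 * (i - 3), obj,
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
    })
    vals <- vapply(set, `[[`, numeric(1), "value")
    cand <- set[[which.min(vals)]]
    if (cand$value < best$value) best <- cand
  }
  best
}

#' @noRd
.fit_se <- function(red, theta, kappa2, overdispersion,
                    se_method = c("hessian", "fisher")) {
  se_method <- match.arg(se_method)
  K <- length(theta)
  V <- NULL
  if (se_method == "hessian") {
    H <- stats::optimHess(theta, function(th)
      cue_objective(th, kappa2, red, overdispersion) / 2)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && any(diag(V) <= 0)) V <- NULL
  }
  if (is.null(V)) {
    Om <- omega_matrix(red, theta, kappa2, overdispersion)
    B <- red$beta_x_pc
    V <- inv_spd(crossprod(B, solve_spd(Om, B)))
  }
  V <- (V + t(V)) / 2
  list(se = sqrt(diag(V)), vcov = V)
}

#' @noRd
.make_fit <- function(red, theta, kappa2, robust, q_stat, converged,
                      overdispersion, se_method, level = 0.95) {
  se <- .fit_se(red, theta, kappa2, overdispersion, se_method)
  z <- stats::qnorm((1 + level) / 2)
  K <- length(theta)
  df <- red$p - K
  names(theta) <- names(se$se) <- red$trait_names
  structure(list(theta = theta, se_theta = se$se, vcov = se$vcov,
                 ci_lower = theta - z * se$se, ci_upper = theta + z * se$se,
                 ci_level = level,
                 pvalue = 2 * stats::pnorm(-abs(theta / se$se)),
                 kappa2 = kappa2, robust = robust,
                 q_stat = q_stat, q_df = df,
                 q_pvalue = if (robust) NA_real_ else
                   stats::pchisq(q_stat, df, lower.tail = FALSE),
                 n_pcs = red$p, n_variants = red$J,
                 overdispersion = overdispersion,
                 converged = converged),
            class = "pcgmm_fit")
}

#' Fit PC-GMM without an overdispersion parameter
#'
#' Minimizes the CUE objective at `kappa2 = 0`, i.e. assuming all
#' heterogeneity in the variant-outcome associations is explained by the
#' modeled risk factors. Standard errors come from the curvature (numerical
#' Hessian of `Q/2`) of the objective at the optimum; the minimized
#' objective is the overidentification (heterogeneity) statistic with
#' `p - K` degrees of freedom.
#'
#' @param red a `pc_reduction` with `p > K`.
#' @param overdispersion covariance structure used when an overdispersion
#'   term is added (irrelevant here beyond bookkeeping); see
#'   [cue_objective()].
#' @param se_method `"hessian"` (default) for curvature-based standard
#'   errors, `"fisher"` for the plug-in `(B' Omega^{-1} B)^{-1}` form.
#' @param level confidence level for the Wald intervals.
#' @return A `pcgmm_fit` object.
#' @export
fit_unrobust <- function(red, overdispersion = "ld",
                         se_method = "hessian", level = 0.95) {
  K <- ncol(red$beta_x_pc)
  if (red$p <= K) {
    stop(sprintf("p = %d components cannot identify %d risk-factor effects",
                 red$p, K), call. = FALSE)
  }
  blocks <- .omega_blocks(red)
  funs <- .cue_funs(red, blocks, .overdisp_mat(red, overdispersion))
  opt <- .minimize_theta(funs, 0, .theta_start(red))
  .make_fit(red, opt$par, 0, robust = FALSE, q_stat = opt$value,
            converged = opt$convergence == 0,
            overdispersion = overdispersion, se_method = se_method,
            level = level)
}

# kappa2 step: root of Q(theta, kappa2) = p - K, the null expectation of the
# objective. Q is non-increasing in kappa2 (Omega grows in the Loewner
# order), so the root is unique when it exists; kappa2 is floored at zero
# when even Q(theta, 0) <= p - K.
#' @noRd
.kappa2_step <- function(funs, theta, df) {
  q0 <- funs$fn(theta, 0)
  if (q0 <= df) return(0)
  upper <- 1
  for (i in 1:60) {
    if (funs$fn(theta, upper) < df) break
    upper <- upper * 4
  }
  stats::uniroot(function(k2) funs$fn(theta, k2) - df,
                 c(0, upper), tol = min(1e-10, upper * 1e-8))$root
}

#' Fit robust PC-GMM with an overdispersion parameter
#'
#' Alternates (i) minimizing the CUE objective over `theta` at the current
#' `kappa2` and (ii) setting `kappa2` to the value matching the minimized
#' objective to its chi-squared null expectation `p - K` (method of
#' moments), floored at zero. Overdispersion affects the variance rather
#' than the consistency of the estimates, so this correction widens
#' confidence intervals without recentering them.
#'
#' @inheritParams fit_unrobust
#' @param tol relative convergence tolerance for the alternation.
#' @param max_iter maximum alternation count.
#' @return A `pcgmm_fit` with `robust = TRUE` and the estimated `kappa2`.
#' @export
fit_robust <- function(red, overdispersion = "ld", se_method = "hessian",
                       level = 0.95, tol = 1e-6, max_iter = 100L) {
  K <- ncol(red$beta_x_pc)
  if (red$p <= K + 1) {
    stop(sprintf("p = %d components leave no overidentification to estimate kappa2 (need p > K + 1 = %d)",
                 red$p, K + 1), call. = FALSE)
  }
  df <- red$p - K
  blocks <- .omega_blocks(red)
  funs <- .cue_funs(red, blocks, .overdisp_mat(red, overdispersion))
  theta <- .theta_start(red)
  opt <- .minimize_theta(funs, 0, theta)
  theta <- opt$par
  kappa2 <- .kappa2_step(funs, theta, df)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    opt <- .minimize_theta(funs, kappa2, theta)
    theta_new <- opt$par
    kappa2_new <- .kappa2_step(funs, theta_new, df)
    delta <- max(abs(theta_new - theta) / pmax(abs(theta), 1),
                 abs(kappa2_new - kappa2) / max(kappa2, 1))
    theta <- theta_new
    kappa2 <- kappa2_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    pcg_log("robust fit: alternation did not reach tolerance %g in %d iterations",
            tol, max_iter, level = "WARN")
  }
  .make_fit(red, theta, kappa2, robust = TRUE,
            q_stat = funs$fn(theta, kappa2),
            converged = converged, overdispersion = overdispersion,
            se_method = se_method, level = level)
}

#' Overidentification (heterogeneity) test
#'
#' Tests the minimized unrobust CUE objective against its chi-squared null
#' distribution with `p - K` degrees of freedom. Rejection indicates
#' heterogeneity unexplained by the model, a sign of possible pleiotropy.
#' The test is undefined after the overdispersion correction, which absorbs
#' exactly this excess dispersion.
#'
#' @param fit an unrobust `pcgmm_fit`.
#' @return List with `statistic`, `df` and `pvalue`.
#' @export
heterogeneity_test <- function(fit) {
  if (isTRUE(fit$robust)) {
    stop("heterogeneity test is undefined for a robust fit (overdispersion already absorbed)",
         call. = FALSE)
  }
  list(statistic = fit$q_stat, df = fit$q_df,
       pvalue = stats::pchisq(fit$q_stat, fit$q_df, lower.tail = FALSE))
}

#' Wald confidence intervals for a PC-GMM fit
#'
#' @param fit a `pcgmm_fit`.
#' @param level confidence level in (0, 1).
#' @return data.frame with columns `trait`, `estimate`, `lower`, `upper`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  assert_that(level > 0 && level < 1, "level must be in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  data.frame(trait = names(fit$theta),
             estimate = unname(fit$theta),
             lower = unname(fit$theta - z * fit$se_theta),
             upper = unname(fit$theta + z * fit$se_theta),
             row.names = NULL)
}

#' @export
print.pcgmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s PC-GMM fit (%d PCs, %d variants)\n",
              if (x$robust) "Robust" else "Unrobust", x$n_pcs, x$n_variants))
  tab <- data.frame(estimate = x$theta,
                    se = x$se_theta,
                    lower = x$ci_lower, upper = x$ci_upper,
                    p = x$pvalue)
  names(tab)[3:4] <- paste0(c("lower_", "upper_"), format(x$ci_level))
  print(round(tab, digits))
  if (x$robust) {
    cat(sprintf("Overdispersion kappa2 = %.4g\n", x$kappa2))
  } else {
    cat(sprintf("Heterogeneity test: Q = %.3f on %d df, p = %.3g\n",
                x$q_stat, x$q_df, x$q_pvalue))
  }
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}
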