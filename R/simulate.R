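# Two-sample summary-data simulator: a linear instrumental-variable model
# with three risk factors, 200 correlated instruments of which 15 are
# causal, tunable phenotypic heterogeneity (xi) and overdispersion
# heterogeneity (kappa2), plus the synthetic regional LD generator and the
# calibration grid runner.

#' Simulation specification
#'
#' Defines the data-generating process for two-sample summary statistics:
#' risk factors
#' `X1 = 0.2 * (Z_c1 + ... + Z_c5) + V1`,
#' `X2 = 0.2 * xi * (Z_c6 + ... + Z_c10) + 0.2 * (1 - xi) * (Z_c11 + ... + Z_c15) + V2`,
#' `X3 = 0.2 * (Z_c11 + ... + Z_c15) + V3`,
#' outcome `Y = theta' X + Z' alpha + U`, where the c's index the 15
#' designated causal instruments, the exposure errors have unit variance
#' and pairwise correlation 0.3, `cor(V_k, U) = 0.2`, `var(U) = 1`, and the
#' direct effects `alpha ~ N(0, kappa2 / n_y)` are drawn once per
#' replicate. `xi = 0` makes the instrument effects of risk factors 2 and 3
#' proportional (no phenotypic heterogeneity for that pair); `xi = 1` gives
#' each risk factor its own instruments.
#'
#' @param xi phenotypic heterogeneity in \[0, 1\].
#' @param kappa2 overdispersion parameter (variance of direct effects is
#'   `kappa2 / n_y` per instrument), non-negative.
#' @param n_x,n_y two-sample sizes (exposure and outcome samples), >= 100.
#' @param theta length-3 true causal effects; default `c(-1/3, 0, 1/3)`.
#' @param J number of instruments (default 200).
#' @param n_causal number of causal instruments (default 15; must be a
#'   multiple of 3 split as 5/5/5 for the default equations).
#' @param beta_scale per-instrument effect size on the risk factors
#'   (default 0.2).
#' @param err_cor pairwise correlation of the exposure errors (default 0.3).
#' @param conf_cor correlation between each exposure error and the outcome
#'   error (confounding; default 0.2).
#' @param seed optional integer seed applied at generation time.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(xi = 1, kappa2 = 0, n_x = 20000, n_y = 20000,
                            theta = c(-1/3, 0, 1/3), J = 200L,
                            n_causal = 15L, beta_scale = 0.2,
                            err_cor = 0.3, conf_cor = 0.2, seed = NULL) {
  assert_that(xi >= 0 && xi <= 1, "xi must be in [0, 1]")
  assert_that(kappa2 >= 0, "kappa2 must be non-negative")
  assert_that(n_x >= 100 && n_y >= 100, "sample sizes must be at least 100")
  assert_that(length(theta) == 3, "theta must have length 3")
  assert_that(n_causal %% 3 == 0, "n_causal must be a multiple of 3")
  assert_that(J >= n_causal, "J must be at least n_causal")
  structure(list(xi = xi, kappa2 = kappa2, n_x = n_x, n_y = n_y,
                 theta = theta, J = as.integer(J),
                 n_causal = as.integer(n_causal), beta_scale = beta_scale,
                 err_cor = err_cor, conf_cor = conf_cor, seed = seed),
            class = "simulation_spec")
}

#' Synthetic regional LD matrix
#'
#' Stand-in for a measured single-gene-region correlation matrix. Dense cis
#' regions contain many variants in perfect LD (proxies carried on the same
#' haplotypes), which makes regional correlation matrices rank-deficient.
#' The generator reproduces this: variants group into perfect-LD clusters
#' (correlation exactly 1 within a cluster); clusters within an LD block are
#' correlated with AR(1) decay `within_block_rho`, and clusters in different
#' blocks with a mild constant `between_block_rho`. The matrix therefore has
#' rank `n_blocks * clusters_per_block` (30 by default), so a handful of
#' principal components carries essentially all regional variation, as in
#' measured gene-region matrices.
#'
#' The designated causal instruments (attribute `causal_idx`) are placed in
#' distinct, non-adjacent clusters so that they are mutually weakly
#' correlated (every pairwise r-squared at most 0.2), the regime in which
#' multivariable effects are identifiable.
#'
#' @param J number of variants (default 200).
#' @param n_blocks number of LD blocks (default 10).
#' @param within_block_rho AR(1) correlation between adjacent clusters
#'   within a block, in \[0, 1); 0 gives the identity matrix (every variant
#'   its own cluster, no correlation).
#' @param between_block_rho constant correlation between clusters of
#'   different blocks (default 0.1).
#' @param clusters_per_block perfect-LD clusters per block (default 3).
#' @param n_causal number of designated causal instruments (default 15).
#' @param seed integer seed controlling how leftover variants are spread
#'   over clusters.
#' @return An [ld_matrix] with attributes `causal_idx` (positions of the
#'   designated causal instruments), `cluster` (cluster index per variant)
#'   and `cluster_chol` (upper Cholesky factor of the cluster correlation
#'   matrix, cached for fast sampling).
#' @export
synthetic_ld <- function(J = 200L, n_blocks = 10L, within_block_rho = 0.65,
                         between_block_rho = 0.1, clusters_per_block = 3L,
                         n_causal = 15L, seed = 1L) {
  assert_that(J >= n_blocks && n_blocks >= 1, "need J >= n_blocks >= 1")
  assert_that(within_block_rho >= 0 && within_block_rho < 1,
              "within_block_rho must be in [0, 1)")
  if (within_block_rho == 0) {
    assert_that(between_block_rho == 0,
                "between_block_rho must be 0 when within_block_rho is 0")
    ld <- ld_matrix(diag(J))
    attr(ld, "causal_idx") <- seq_len(min(n_causal, J))
    attr(ld, "cluster") <- seq_len(J)
    attr(ld, "cluster_chol") <- diag(J)
    return(ld)
  }
  assert_that(between_block_rho >= 0 && between_block_rho < within_block_rho,
              "between_block_rho must be smaller than within_block_rho")
  d <- n_blocks * clusters_per_block
  assert_that(J >= d, "need at least one variant per cluster")
  # cluster correlation matrix A (d x d)
  blk <- rep(seq_len(n_blocks), each = clusters_per_block)
  pos_in_blk <- rep(seq_len(clusters_per_block), n_blocks)
  A <- matrix(between_block_rho, d, d)
  same <- outer(blk, blk, "==")
  A[same] <- within_block_rho^abs(outer(pos_in_blk, pos_in_blk, "-"))[same]
  diag(A) <- 1
  # assign variants to clusters: contiguous runs, remainder spread by seed
  sizes <- rep(J %/% d, d)
  extra <- J %% d
  if (extra > 0) {
    old <- .Random.seed_get()
    set.seed(seed)
    bump <- sample.int(d, extra)
    .Random.seed_set(old)
    sizes[bump] <- sizes[bump] + 1L
  }
  cluster <- rep(seq_len(d), times = sizes)
  rho <- A[cluster, cluster]
  diag(rho) <- 1
  ld <- ld_matrix(rho)
  # causal instruments: first variant of non-adjacent clusters (odd
  # positions within blocks), filled block-by-block
  cand <- which(pos_in_blk %% 2 == 1)
  cand <- cand[order(pos_in_blk[cand], blk[cand])]
  if (length(cand) < n_causal) {
    stop(sprintf("cannot place %d mutually weakly correlated causal instruments with %d blocks x %d clusters",
                 n_causal, n_blocks, clusters_per_block), call. = FALSE)
  }
  causal_clusters <- cand[seq_len(n_causal)]
  causal <- sort(match(causal_clusters, cluster))
  r2 <- ld$rho[causal, causal]^2
  diag(r2) <- 0
  if (max(r2) > 0.2 + 1e-8) {
    stop(sprintf("causal-instrument correlation constraint violated (max r2 = %.3f); use weaker within_block_rho or more blocks",
                 max(r2)), call. = FALSE)
  }
  attr(ld, "causal_idx") <- causal
  attr(ld, "cluster") <- cluster
  attr(ld, "cluster_chol") <- chol(A)
  ld
}

# save/restore RNG state so generator bookkeeping does not consume the
# caller's stream
#' @noRd
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
#' @noRd
.Random.seed_set <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

# instrument-effect matrix Gamma (J x 3) under the spec
#' @noRd
.effect_matrix <- function(spec, causal) {
  third <- spec$n_causal / 3
  g <- matrix(0, spec$J, 3)
  set1 <- causal[seq_len(third)]
  set2 <- causal[third + seq_len(third)]
  set3 <- causal[2 * third + seq_len(third)]
  g[set1, 1] <- spec$beta_scale
  g[set2, 2] <- spec$beta_scale * spec$xi
  g[set3, 2] <- spec$beta_scale * (1 - spec$xi)
  g[set3, 3] <- spec$beta_scale
  g
}

#' Generate two-sample summary statistics
#'
#' Draws two independent samples of multivariate-normal instruments with
#' the given LD correlation, builds exposures and outcome per the model in
#' [simulation_spec()], and reduces each sample to per-variant univariable
#' regression coefficients and standard errors: exposures regressed in
#' sample 1 (size `n_x`), the outcome in sample 2 (size `n_y`). The direct
#' effects `alpha` are drawn once per replicate (a random-effects reading
#' of the overdispersion model).
#'
#' @param spec a [simulation_spec()].
#' @param ld an [ld_matrix] with `J = spec$J` variants; its `causal_idx`
#'   attribute (from [synthetic_ld()]) designates the causal instruments,
#'   defaulting to the first `n_causal` positions if absent.
#' @return A [regional_summary] with attributes `trait_cor` (the empirical
#'   exposure correlation matrix from sample 1, the usual plug-in for the
#'   risk-factor correlation input) and `gamma` (the true instrument-effect
#'   matrix).
#' @export
generate_two_sample <- function(spec, ld) {
  assert_that(length(ld$ids) == spec$J, "LD matrix dimension must equal spec$J")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  J <- spec$J
  cluster <- attr(ld, "cluster")
  Rc_ld <- attr(ld, "cluster_chol")
  draw_Z <- if (!is.null(cluster) && !is.null(Rc_ld)) {
    d <- ncol(Rc_ld)
    function(n) (matrix(stats::rnorm(n * d), n, d) %*% Rc_ld)[, cluster,
                                                              drop = FALSE]
  } else {
    R <- chol(ld$rho + diag(1e-10, J))
    function(n) matrix(stats::rnorm(n * J), n, J) %*% R
  }
  causal <- attr(ld, "causal_idx") %||% seq_len(spec$n_causal)
  assert_that(length(causal) == spec$n_causal,
              "LD matrix designates a different number of causal instruments than spec$n_causal")
  gamma <- .effect_matrix(spec, causal)
  # error correlation for (V1, V2, V3, U)
  C <- diag(4)
  C[1:3, 1:3][upper.tri(C[1:3, 1:3])] <- spec$err_cor
  C[1:3, 1:3][lower.tri(C[1:3, 1:3])] <- spec$err_cor
  C[4, 1:3] <- C[1:3, 4] <- spec$conf_cor
  Rc <- chol(C)
  alpha <- stats::rnorm(J, 0, sqrt(spec$kappa2 / spec$n_y))

  # sample 1: exposures
  Z1 <- draw_Z(spec$n_x)
  E1 <- matrix(stats::rnorm(spec$n_x * 4), spec$n_x, 4) %*% Rc
  X1 <- Z1 %*% gamma + E1[, 1:3]
  sx <- .marginal_regressions(Z1, X1)

  # sample 2: outcome
  Z2 <- draw_Z(spec$n_y)
  E2 <- matrix(stats::rnorm(spec$n_y * 4), spec$n_y, 4) %*% Rc
  X2 <- Z2 %*% gamma + E2[, 1:3]
  Y <- drop(X2 %*% spec$theta) + drop(Z2 %*% alpha) + E2[, 4]
  sy <- .marginal_regressions(Z2, matrix(Y, ncol = 1))

  variants <- data.frame(id = ld$ids,
                         chrom = "6",
                         pos = 39016557L - 100000L + (seq_len(J) - 1L) * 1000L,
                         effect_allele = "A", other_allele = "G",
                         stringsAsFactors = FALSE)
  out <- regional_summary(variants,
                          beta_x = sx$beta, se_x = sx$se,
                          beta_y = drop(sy$beta), se_y = drop(sy$se),
                          n_x = spec$n_x, n_y = spec$n_y,
                          trait_names = c("X1", "X2", "X3"))
  attr(out, "trait_cor") <- stats::cor(X1)
  attr(out, "gamma") <- gamma
  out
}

# Vectorized per-variant univariable regressions of each column of Yv on
# each column of Z: slope and residual-based standard error.
#' @noRd
.marginal_regressions <- function(Z, Yv) {
  n <- nrow(Z)
  zm <- colMeans(Z)
  ym <- colMeans(Yv)
  szz <- colSums(Z^2) - n * zm^2
  sxy <- crossprod(Z, Yv) - n * tcrossprod(zm, ym)   # J x K
  beta <- sxy / szz
  syy <- colSums(Yv^2) - n * ym^2
  rss <- matrix(syy, nrow(beta), ncol(beta), byrow = TRUE) - beta^2 * szz
  se <- sqrt(pmax(rss, 0) / ((n - 2) * szz))
  list(beta = beta, se = se)
}

#' Run the simulation calibration grid
#'
#' For each cell of the (`xi`, `kappa2`, `n`) grid, generates `reps`
#' two-sample replicates, PC-transforms each at `threshold` using the true
#' instrument correlation matrix and the replicate's empirical risk-factor
#' correlation, fits the unrobust and robust PC-GMM estimators, and
#' computes conditional F-statistics. Aggregates per cell: mean bias and
#' RMSE per risk factor and method, rejection rates of the Wald tests at
#' nominal level 0.05 and of the conditional F-tests at the 0.95
#' chi-squared quantile, mean estimated overdispersion, mean number of
#' retained components, and non-convergence counts. Per-cell seeds are
#' derived from the master seed by a counter, so a grid run is reproducible
#' and cells are independent.
#'
#' @param xi_grid,kappa2_grid,n_grid grid values (n is used for both
#'   samples).
#' @param reps replicates per cell (>= 50 recommended for stable rates).
#' @param threshold explained-variance threshold for component selection
#'   (default 0.9999).
#' @param seed master seed.
#' @param ld optional [ld_matrix]; defaults to `synthetic_ld()` with its
#'   defaults.
#' @param use_sample_ld estimate the LD matrix from the simulated exposure
#'   sample instead of using the generator's true matrix (default `FALSE`:
#'   the true matrix is assumed known, as is standard for reference-panel
#'   analyses).
#' @param nominal test size for the Wald rejection rates (default 0.05).
#' @param fits which analyses to run per replicate (any of `"unrobust"`,
#'   `"robust"`, `"condf"`; default all three). Skipping unneeded analyses
#'   speeds large grids; skipped quantities are `NA` in the output.
#' @return data.frame of class `grid_result`, one row per cell.
#' @export
run_grid <- function(xi_grid = 1, kappa2_grid = 0, n_grid = 20000,
                     reps = 200L, threshold = 0.9999, seed = 1L,
                     ld = NULL, use_sample_ld = FALSE, nominal = 0.05,
                     fits = c("unrobust", "robust", "condf")) {
  assert_that(reps >= 50, "use at least 50 replicates per cell")
  fits <- match.arg(fits, several.ok = TRUE)
  if (is.null(ld)) ld <- synthetic_ld()
  cells <- expand.grid(xi = xi_grid, kappa2 = kappa2_grid, n = n_grid,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell_seed <- (as.integer(seed) + 7919L * ci) %% 2147483647L
    out[[ci]] <- .run_cell(cells$xi[ci], cells$kappa2[ci], cells$n[ci],
                           reps, threshold, cell_seed, ld, use_sample_ld,
                           nominal, fits)
  }
  res <- do.call(rbind, out)
  class(res) <- c("grid_result", class(res))
  res
}

#' @noRd
.run_cell <- function(xi, kappa2, n, reps, threshold, cell_seed, ld,
                      use_sample_ld, nominal, fits) {
  causal <- attr(ld, "causal_idx")
  spec <- simulation_spec(xi = xi, kappa2 = kappa2, n_x = n, n_y = n,
                          J = length(ld$ids),
                          n_causal = if (is.null(causal)) 15L
                          else length(causal))
  set.seed(cell_seed)
  theta_true <- spec$theta
  zcrit <- stats::qnorm(1 - nominal / 2)
  est_u <- est_r <- matrix(NA_real_, reps, 3)
  rej_u <- rej_r <- rej_f <- matrix(NA, reps, 3)
  k2hat <- q_u <- rep(NA_real_, reps)
  npcs <- numeric(reps)
  nonconv <- 0L
  for (r in seq_len(reps)) {
    dat <- generate_two_sample(spec, ld)
    if (use_sample_ld) {
      stop("sample-estimated LD not wired into grid cells; pass the estimate as `ld`")
    }
    tc <- trait_correlation(attr(dat, "trait_cor"), dat$trait_names)
    red <- pc_transform(dat, ld, variance_threshold = threshold,
                        trait_cor = tc)
    npcs[r] <- red$p
    if ("unrobust" %in% fits) {
      fu <- fit_unrobust(red)
      est_u[r, ] <- fu$theta
      rej_u[r, ] <- abs(fu$theta) / fu$se_theta > zcrit
      q_u[r] <- fu$q_stat
      if (!fu$converged) nonconv <- nonconv + 1L
    }
    if ("robust" %in% fits) {
      fr <- fit_robust(red)
      est_r[r, ] <- fr$theta
      rej_r[r, ] <- abs(fr$theta) / fr$se_theta > zcrit
      k2hat[r] <- fr$kappa2
      if (!fr$converged) nonconv <- nonconv + 1L
    }
    if ("condf" %in% fits) {
      cf <- suppressMessages(all_conditional_f(red))
      rej_f[r, ] <- cf$f_stats * cf$df > stats::qchisq(0.95, cf$df)
    }
  }
  rmse <- function(E) sqrt(colMeans(sweep(E, 2, theta_true)^2))
  row <- data.frame(xi = xi, kappa2 = kappa2, n = n, reps = reps,
                    mean_pcs = mean(npcs),
                    mean_kappa2_hat = mean(k2hat),
                    mean_q_unrobust = mean(q_u),
                    nonconverged = nonconv,
                    flagged = nonconv > 0.1 * reps)
  for (k in 1:3) {
    row[[paste0("bias_unrobust_", k)]] <- colMeans(est_u)[k] - theta_true[k]
    row[[paste0("bias_robust_", k)]] <- colMeans(est_r)[k] - theta_true[k]
    row[[paste0("rmse_unrobust_", k)]] <- rmse(est_u)[k]
    row[[paste0("rmse_robust_", k)]] <- rmse(est_r)[k]
    row[[paste0("reject_unrobust_", k)]] <- mean(rej_u[, k])
    row[[paste0("reject_robust_", k)]] <- mean(rej_r[, k])
    row[[paste0("reject_condf_", k)]] <- mean(rej_f[, k])
  }
  if (row$flagged) {
    pcg_log("grid cell (xi=%g, kappa2=%g, n=%d): %d/%d replicates non-converged",
            xi, kappa2, n, nonconv, reps, level = "WARN")
  }
  row
}
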