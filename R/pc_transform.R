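# Dimension reduction: weighted genetic correlation matrix, principal
# component selection, and transformation of marginal variant associations
# into PC-scale multivariable regression coefficients with variance matrices.

#' Weighted genetic correlation matrix
#'
#' Builds the matrix whose principal components are used as instruments:
#' `Psi[i, j] = rho[i, j] * w[i] * w[j]`, where the weight
#' `w[j] = sum_k |beta_x[j, k]| / se_y[j]` aggregates association strength
#' across risk factors and outcome precision, so that components align with
#' variants that carry trait signal rather than with LD structure alone.
#'
#' @param data a [regional_summary] object.
#' @param ld an [ld_matrix] aligned with `data`.
#' @param weights `"trait"` (default, the weight above) or `"none"` (plain
#'   LD correlation matrix).
#' @return J x J symmetric matrix.
#' @export
weighted_correlation_matrix <- function(data, ld, weights = c("trait", "none")) {
  weights <- match.arg(weights)
  assert_that(identical(data$variants$id, ld$ids),
              "data and LD matrix are not aligned")
  if (any(data$se_y <= 0)) stop("se_y must be strictly positive", call. = FALSE)
  w <- if (weights == "trait") {
    rowSums(abs(data$beta_x)) / data$se_y
  } else {
    rep(1, n_variants(data))
  }
  psi <- ld$rho * tcrossprod(w)
  (psi + t(psi)) / 2
}

#' Select principal components by explained variance
#'
#' Eigendecomposes the weighted correlation matrix and retains the smallest
#' number of leading components whose cumulative eigenvalue share reaches
#' `variance_threshold`. Negative eigenvalues (possible after weighting a
#' repaired LD matrix) are excluded from the variance denominator, and
#' components with eigenvalues below `1e-12 * lambda_max` are never
#' retained. Each loading column is scaled so its largest-magnitude entry is
#' positive, making the decomposition deterministic.
#'
#' @param psi J x J symmetric matrix from [weighted_correlation_matrix()].
#' @param variance_threshold required explained-variance fraction in (0, 1].
#' @return List with `loadings` (J x p), `eigenvalues` (length J,
#'   descending) and `p` (number retained).
#' @export
select_components <- function(psi, variance_threshold = 0.999) {
  assert_that(variance_threshold > 0 && variance_threshold <= 1,
              "variance_threshold must be in (0, 1]")
  if (!all(is.finite(psi))) stop("non-finite entries in weighted matrix", call. = FALSE)
  ee <- eigen(psi, symmetric = TRUE)
  lam <- ee$values
  pos <- pmax(lam, 0)
  denom <- sum(pos)
  if (denom <= 0) stop("weighted matrix has no positive eigenvalues", call. = FALSE)
  cum <- cumsum(pos) / denom
  p <- which(cum >= variance_threshold - 1e-12)[1]
  p_max <- sum(lam > 1e-12 * lam[1])
  p <- min(p, p_max)
  L <- ee$vectors[, seq_len(p), drop = FALSE]
  for (j in seq_len(p)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  list(loadings = L, eigenvalues = lam, p = p)
}

#' Risk-factor correlation matrix
#'
#' @param matrix K x K symmetric matrix with unit diagonal and entries in
#'   \[-1, 1\]; defaults to the identity (uncorrelated risk factors).
#' @param trait_names optional labels.
#' @return Object of class `trait_correlation`.
#' @export
trait_correlation <- function(matrix, trait_names = NULL) {
  m <- as.matrix(matrix)
  assert_that(nrow(m) == ncol(m), "trait correlation must be square")
  assert_that(max(abs(m - t(m))) < 1e-8, "trait correlation must be symmetric")
  assert_that(max(abs(diag(m) - 1)) < 1e-8, "trait correlation diagonal must be 1")
  assert_that(max(abs(m)) <= 1 + 1e-8, "trait correlations must lie in [-1, 1]")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8, "trait correlation must be positive semi-definite")
  if (!is.null(trait_names)) dimnames(m) <- list(trait_names, trait_names)
  structure(m, class = c("trait_correlation", "matrix", "array"))
}

#' Transform marginal associations to PC-scale multivariable coefficients
#'
#' With loadings `L` and LD matrix `rho`, the PC-scale Gram matrix is
#' `S = L' rho L` and the multivariable coefficients of each trait on the
#' principal components are `S^{-1} L' beta`. Their variance matrices follow
#' by the sandwich rule from the standard marginal-coefficient covariance
#' `D rho D` (with `D = diag(se)`): `omega_yy = S^{-1} L' D_y rho D_y L
#' S^{-1}`, and the risk-factor blocks analogously, with cross-risk-factor
#' blocks scaled by the trait correlation entries (zero off-diagonals by
#' default, for non-overlapping samples or uncorrelated traits).
#'
#' @param data a [regional_summary] object.
#' @param ld an [ld_matrix] aligned with `data`.
#' @param loadings J x p loadings matrix (from [select_components()]).
#' @param trait_cor a [trait_correlation] (K x K); identity if `NULL`.
#' @param eigenvalues optional eigenvalue vector carried through for
#'   reporting.
#' @param variance_threshold recorded threshold used for selection.
#' @return Object of class `pc_reduction` with the PC-scale coefficients
#'   (`beta_x_pc` p x K, `beta_y_pc` length p), their variance matrices
#'   (`omega_xx` pK x pK in K x K blocks of p x p, `omega_yy` p x p), the
#'   Gram matrix `S`, its inverse `S_inv`, the squared-LD image
#'   `T2 = L' rho rho L`, and bookkeeping fields.
#' @export
transform_associations <- function(data, ld, loadings, trait_cor = NULL,
                                   eigenvalues = NULL,
                                   variance_threshold = NA_real_) {
  L <- as.matrix(loadings)
  J <- n_variants(data)
  p <- ncol(L)
  K <- ncol(data$beta_x)
  assert_that(nrow(L) == J, "loadings rows must match the number of variants")
  rho <- ld$rho
  if (is.null(trait_cor)) trait_cor <- trait_correlation(diag(K), data$trait_names)
  assert_that(nrow(trait_cor) == K, "trait correlation dimension must equal K")
  rhoL <- rho %*% L
  S <- crossprod(L, rhoL)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e12) {
    stop(paste("PC-scale Gram matrix is numerically singular;",
               "lower variance_threshold or prune more aggressively"),
         call. = FALSE)
  }
  S_inv <- chol2inv(chol(S))
  A <- S_inv %*% t(L)                    # p x J projection
  beta_y_pc <- drop(A %*% data$beta_y)
  beta_x_pc <- A %*% data$beta_x
  # Var(beta_hat marginal) = D rho D elementwise: rho * outer(se, se)
  Ay <- A * rep(data$se_y, each = p)     # A %*% D_y
  omega_yy <- Ay %*% rho %*% t(Ay)
  omega_yy <- (omega_yy + t(omega_yy)) / 2
  Ax <- lapply(seq_len(K), function(k) A * rep(data$se_x[, k], each = p))
  omega_xx <- matrix(0, p * K, p * K)
  for (k in seq_len(K)) {
    rk <- rho %*% t(Ax[[k]])
    for (l in seq_len(k)) {
      blk <- trait_cor[k, l] * (Ax[[l]] %*% rk)
      omega_xx[.pc_block(l, p), .pc_block(k, p)] <- blk
      if (l < k) omega_xx[.pc_block(k, p), .pc_block(l, p)] <- t(blk)
      else omega_xx[.pc_block(k, p), .pc_block(k, p)] <-
          (blk + t(blk)) / 2
    }
  }
  T2 <- crossprod(rhoL)
  T2 <- (T2 + t(T2)) / 2
  structure(list(loadings = L, eigenvalues = eigenvalues, p = p,
                 variance_threshold = variance_threshold,
                 beta_x_pc = beta_x_pc, beta_y_pc = beta_y_pc,
                 omega_xx = omega_xx, omega_yy = omega_yy,
                 S = S, S_inv = S_inv, T2 = T2,
                 trait_cor = trait_cor, trait_names = data$trait_names,
                 J = J, n_y = data$n_y),
            class = "pc_reduction")
}

#' @noRd
.pc_block <- function(k, p) ((k - 1L) * p + 1L):(k * p)

#' Extract a p x p covariance block of the PC-scale risk-factor coefficients
#' @param red a `pc_reduction`.
#' @param k,l risk-factor indices.
#' @return p x p matrix `Cov(beta_x_pc[, k], beta_x_pc[, l])`.
#' @export
omega_x_block <- function(red, k, l) {
  red$omega_xx[.pc_block(k, red$p), .pc_block(l, red$p), drop = FALSE]
}

#' @export
print.pc_reduction <- function(x, ...) {
  expl <- if (!is.null(x$eigenvalues)) {
    pos <- pmax(x$eigenvalues, 0)
    sprintf(" explaining %.4f%% of weighted variance",
            100 * sum(pos[seq_len(x$p)]) / sum(pos))
  } else ""
  cat(sprintf("PC reduction: %d components of %d variants%s; %d risk factor(s)\n",
              x$p, x$J, expl, ncol(x$beta_x_pc)))
  invisible(x)
}

#' One-step PC transform of regional summary data
#'
#' Convenience wrapper chaining [weighted_correlation_matrix()],
#' [select_components()] and [transform_associations()].
#'
#' @inheritParams weighted_correlation_matrix
#' @inheritParams select_components
#' @param trait_cor optional [trait_correlation].
#' @return A `pc_reduction`.
#' @export
pc_transform <- function(data, ld, variance_threshold = 0.999,
                         trait_cor = NULL, weights = "trait") {
  psi <- weighted_correlation_matrix(data, ld, weights = weights)
  sel <- select_components(psi, variance_threshold)
  transform_associations(data, ld, sel$loadings, trait_cor = trait_cor,
                         eigenvalues = sel$eigenvalues,
                         variance_threshold = variance_threshold)
}
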