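# Fixture builders shared across test files. Everything is generated in
# code; no stored data files.

# deterministic toy summary data
make_toy_summary <- function(J = 10, K = 2, seed = 1, pos0 = 1000L,
                             trait_names = paste0("T", seq_len(K))) {
  set.seed(seed)
  variants <- data.frame(
    id = sprintf("rs%04d", seq_len(J)),
    chrom = "6",
    pos = pos0 + seq_len(J) * 10L,
    effect_allele = rep(c("A", "C"), length.out = J),
    other_allele = rep(c("G", "T"), length.out = J),
    stringsAsFactors = FALSE)
  regional_summary(variants,
                   beta_x = matrix(rnorm(J * K, 0, 0.1), J, K),
                   se_x = matrix(runif(J * K, 0.01, 0.05), J, K),
                   beta_y = rnorm(J, 0, 0.1),
                   se_y = runif(J, 0.01, 0.05),
                   n_x = 10000, n_y = 20000,
                   trait_names = trait_names)
}

make_ar1_ld <- function(J, rho, ids = sprintf("rs%04d", seq_len(J))) {
  m <- rho^abs(outer(seq_len(J), seq_len(J), "-"))
  ld_matrix(m, ids)
}

# hand-built PC reduction for estimator unit tests; omega blocks default to
# small diagonals, cross-blocks zero
make_reduction <- function(B, by, omega_yy, omega_blocks = NULL,
                           trait_names = NULL, S_inv = NULL, T2 = NULL) {
  B <- as.matrix(B)
  p <- nrow(B)
  K <- ncol(B)
  if (is.null(trait_names)) trait_names <- paste0("T", seq_len(K))
  if (is.null(omega_blocks)) {
    omega_blocks <- lapply(seq_len(K), function(k)
      lapply(seq_len(K), function(l) if (k == l) diag(1e-4, p)
             else matrix(0, p, p)))
  }
  omega_xx <- matrix(0, p * K, p * K)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    omega_xx[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
      omega_blocks[[k]][[l]]
  }
  structure(list(loadings = diag(p), eigenvalues = rep(1, p), p = p,
                 variance_threshold = NA_real_,
                 beta_x_pc = B, beta_y_pc = as.numeric(by),
                 omega_xx = omega_xx, omega_yy = omega_yy,
                 S = diag(p), S_inv = S_inv %||% diag(p),
                 T2 = T2 %||% diag(p),
                 trait_cor = diag(K), trait_names = trait_names,
                 J = p, n_y = 20000),
            class = "pc_reduction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small LD stand-in + matching simulation spec for fast simulation tests
small_sim_ld <- function(seed = 1) {
  synthetic_ld(J = 60, n_blocks = 5, clusters_per_block = 3,
               n_causal = 9, seed = seed)
}

small_sim_spec <- function(xi = 1, kappa2 = 0, n = 3000, seed = NULL) {
  simulation_spec(xi = xi, kappa2 = kappa2, n_x = n, n_y = n,
                  J = 60L, n_causal = 9L, seed = seed)
}

# write a summary-statistics file in the default column convention
write_summary_fixture <- function(data, path = tempfile(fileext = ".tsv")) {
  write_summary_stats(data, path)
  path
}
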