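# Internal numerical and logging helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
pcg_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[pcgmm %s] %s", level, sprintf(fmt, ...)))
}

# Cholesky-based solve for symmetric positive-definite systems; falls back to
# a pivoted eigendecomposition pseudo-solve if the matrix is numerically
# semi-definite (tiny negative eigenvalues after repeated block additions).
#' @noRd
solve_spd <- function(A, b) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) {
    return(backsolve(ch, backsolve(ch, b, transpose = TRUE)))
  }
  ee <- eigen(A, symmetric = TRUE)
  pos <- ee$values > max(ee$values) * 1e-12
  if (!any(pos)) stop("matrix is numerically singular", call. = FALSE)
  V <- ee$vectors[, pos, drop = FALSE]
  V %*% ((crossprod(V, b)) / ee$values[pos])
}

# Quadratic form g' A^{-1} g
#' @noRd
quad_inv <- function(A, g) {
  drop(crossprod(g, solve_spd(A, g)))
}

#' @noRd
inv_spd <- function(A) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) return(chol2inv(ch))
  ee <- eigen(A, symmetric = TRUE)
  pos <- ee$values > max(ee$values) * 1e-12
  V <- ee$vectors[, pos, drop = FALSE]
  V %*% (t(V) / ee$values[pos])
}

# log(sum(exp(x))) without overflow
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Fixed 6-significant-digit formatting for TSV outputs so reruns with the
# same seed are byte-identical.
#' @noRd
fmt_num <- function(x) {
  formatC(signif(x, 6), format = "g", digits = 6)
}

#' @noRd
write_tsv_fixed <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
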