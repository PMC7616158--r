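# LD correlation matrices: construction, file IO and PSD repair.

#' Construct an LD matrix object
#'
#' @param rho J x J symmetric matrix of signed variant correlations with unit
#'   diagonal.
#' @param ids character vector of variant ids matching the row order of the
#'   summary data the matrix will be used with.
#' @param psd_repaired logical; whether a PSD repair has been applied.
#' @param min_eigenvalue_before smallest eigenvalue before repair (NA if no
#'   repair has been attempted).
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(rho, ids = NULL, psd_repaired = FALSE,
                      min_eigenvalue_before = NA_real_) {
  rho <- as.matrix(rho)
  J <- nrow(rho)
  assert_that(ncol(rho) == J, "rho must be square")
  if (max(abs(rho - t(rho))) > 1e-8) {
    stop("LD matrix is asymmetric beyond tolerance 1e-8", call. = FALSE)
  }
  rho <- (rho + t(rho)) / 2
  assert_that(max(abs(diag(rho) - 1)) < 1e-8, "LD matrix diagonal must be 1")
  diag(rho) <- 1
  # allow small overshoots from rounding in estimated panels; repair_psd
  # restores a proper correlation matrix
  assert_that(max(abs(rho)) <= 1 + 0.05, "correlations must lie in [-1, 1]")
  if (is.null(ids)) ids <- rownames(rho) %||% paste0("v", seq_len(J))
  assert_that(length(ids) == J, "ids length must match matrix dimension")
  dimnames(rho) <- list(ids, ids)
  structure(list(ids = as.character(ids), rho = rho,
                 psd_repaired = psd_repaired,
                 min_eigenvalue_before = min_eigenvalue_before),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("LD matrix: %d variants%s\n", length(x$ids),
              if (isTRUE(x$psd_repaired))
                sprintf(" (PSD-repaired; min eigenvalue before %.3g)",
                        x$min_eigenvalue_before) else ""))
  invisible(x)
}

#' @noRd
subset_ld <- function(ld, idx) {
  out <- ld_matrix(ld$rho[idx, idx, drop = FALSE], ld$ids[idx],
                   psd_repaired = ld$psd_repaired,
                   min_eigenvalue_before = ld$min_eigenvalue_before)
  out
}

#' Read an LD matrix from file
#'
#' Two dialects are supported: a square whitespace-delimited matrix whose
#' header row gives the variant ids, or long-format triplets with columns
#' `id1`, `id2`, `r` (signed correlation, not r-squared); missing triplet
#' pairs default to 0 and the diagonal to 1.
#'
#' @param path file path.
#' @param ids optional variant ordering for the triplet dialect; defaults to
#'   first-appearance order.
#' @return An [ld_matrix].
#' @export
read_ld_matrix <- function(path, ids = NULL) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) == 3 && !nrow(df) == ncol(df)) {
    names(df) <- c("id1", "id2", "r")
    if (is.null(ids)) ids <- unique(c(df$id1, df$id2))
    J <- length(ids)
    rho <- diag(J)
    i <- match(df$id1, ids)
    j <- match(df$id2, ids)
    if (anyNA(i) || anyNA(j)) stop("triplet ids not in id set", call. = FALSE)
    rho[cbind(i, j)] <- df$r
    rho[cbind(j, i)] <- df$r
    diag(rho) <- 1
    return(ld_matrix(rho, ids))
  }
  ld_matrix(as.matrix(df), ids = names(df))
}

#' Write an LD matrix as a square delimited file
#'
#' @param ld an [ld_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- as.data.frame(ld$rho)
  names(df) <- ld$ids
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Repair a near-singular LD matrix to positive semi-definiteness
#'
#' Reference-panel correlation matrices for dense cis regions are frequently
#' ill-conditioned and can be indefinite after rounding. If the smallest
#' eigenvalue is below -1e-10, negative eigenvalues are clipped at zero and
#' the matrix is rescaled back to unit diagonal. PSD inputs are returned
#' unchanged (with `psd_repaired = FALSE`).
#'
#' @param ld an [ld_matrix].
#' @return An [ld_matrix] with `psd_repaired` and `min_eigenvalue_before`
#'   recorded.
#' @export
repair_psd <- function(ld) {
  ee <- eigen(ld$rho, symmetric = TRUE)
  min_ev <- min(ee$values)
  if (min_ev >= -1e-10) {
    ld$min_eigenvalue_before <- min_ev
    return(ld)
  }
  lam <- pmax(ee$values, 0)
  R <- ee$vectors %*% (lam * t(ee$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  pcg_log("LD matrix repaired to PSD (min eigenvalue was %.3g)", min_ev)
  ld_matrix(R, ld$ids, psd_repaired = TRUE, min_eigenvalue_before = min_ev)
}
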