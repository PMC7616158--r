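# Reading, validation, harmonization and region filtering of GWAS summary
# statistics and LD matrices for a single gene region.

#' Construct a regional summary-data object
#'
#' Bundles per-variant marginal association estimates for K risk factors and
#' one outcome, together with variant metadata, into a validated container.
#' All matrices must share row order with `variants`.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` (one row per variant, `pos` 1-based).
#' @param beta_x J x K matrix of marginal risk-factor association
#'   coefficients (one column per risk factor).
#' @param se_x J x K matrix of standard errors, strictly positive.
#' @param beta_y length-J vector of marginal outcome associations.
#' @param se_y length-J vector of outcome standard errors, strictly positive.
#' @param n_x per-risk-factor sample sizes (length K, recycled if scalar);
#'   may be `NA` when unknown.
#' @param n_y outcome sample size; may be `NA`.
#' @param trait_names character vector of K risk-factor labels.
#'
#' @return An object of class `regional_summary`.
#' @export
regional_summary <- function(variants, beta_x, se_x, beta_y, se_y,
                             n_x = NA_real_, n_y = NA_real_,
                             trait_names = NULL) {
  beta_x <- as.matrix(beta_x)
  se_x <- as.matrix(se_x)
  J <- nrow(beta_x)
  K <- ncol(beta_x)
  assert_that(is.data.frame(variants) &&
                all(c("id", "chrom", "pos", "effect_allele", "other_allele")
                    %in% names(variants)),
              "variants must have columns id, chrom, pos, effect_allele, other_allele")
  assert_that(nrow(variants) == J, "variants and beta_x row counts differ")
  assert_that(all(dim(se_x) == dim(beta_x)), "se_x and beta_x dimensions differ")
  assert_that(length(beta_y) == J && length(se_y) == J,
              "beta_y/se_y length must equal the number of variants")
  assert_that(all(variants$pos > 0), "variant positions must be positive")
  assert_that(!anyNA(beta_x) && !anyNA(se_x) && !anyNA(beta_y) && !anyNA(se_y),
              "missing values in association estimates; drop or impute before construction")
  bad <- which(se_y <= 0 | apply(se_x, 1, function(s) any(s <= 0)))
  if (length(bad)) {
    stop("non-positive standard error for variant(s): ",
         paste(variants$id[bad], collapse = ", "), call. = FALSE)
  }
  same <- variants$effect_allele == variants$other_allele
  if (any(same)) {
    stop("effect and other allele identical for variant(s): ",
         paste(variants$id[same], collapse = ", "), call. = FALSE)
  }
  if (is.null(trait_names)) trait_names <- colnames(beta_x) %||% paste0("X", seq_len(K))
  colnames(beta_x) <- colnames(se_x) <- trait_names
  n_x <- rep_len(as.numeric(n_x), K)
  structure(list(variants = variants, beta_x = beta_x, se_x = se_x,
                 beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
                 n_x = n_x, n_y = as.numeric(n_y)[1],
                 trait_names = trait_names),
            class = "regional_summary")
}

#' @export
print.regional_summary <- function(x, ...) {
  cat(sprintf("Regional summary data: %d variants, %d risk factor(s) (%s), 1 outcome\n",
              nrow(x$variants), length(x$trait_names),
              paste(x$trait_names, collapse = ", ")))
  invisible(x)
}

#' Number of variants in a regional summary object
#' @param data a `regional_summary` object.
#' @return Integer count of variants.
#' @export
n_variants <- function(data) nrow(data$variants)

.default_column_map <- function() {
  list(variant = "variant", chrom = "chrom", pos = "pos",
       effect_allele = "effect_allele", other_allele = "other_allele",
       beta_out = "beta_out", se_out = "se_out",
       traits = NULL, beta = NULL, se = NULL)
}

#' Read regional GWAS summary statistics
#'
#' Reads a tab- or comma-delimited file with one row per variant. By default
#' columns follow the convention `variant, chrom, pos, effect_allele,
#' other_allele`, per-trait `beta_<name>` / `se_<name>`, and outcome
#' `beta_out` / `se_out`; the trait names are inferred from the `beta_*`
#' columns. Any of this can be overridden through `column_map` (a list with
#' entries `variant`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `beta_out`, `se_out`, and parallel vectors `traits`, `beta`, `se`).
#'
#' Rows with missing association estimates are dropped with a logged count;
#' non-positive standard errors are an error naming the offending variant.
#'
#' @param path file path.
#' @param column_map optional list overriding default column names.
#' @param n_x,n_y optional sample sizes recorded on the returned object.
#' @return A [regional_summary] object.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               n_x = NA_real_, n_y = NA_real_) {
  cm <- utils::modifyList(.default_column_map(), column_map %||% list())
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(cm$traits)) {
    bcols <- setdiff(grep("^beta_", names(df), value = TRUE), cm$beta_out)
    cm$traits <- sub("^beta_", "", bcols)
    cm$beta <- bcols
    cm$se <- paste0("se_", cm$traits)
  }
  needed <- c(cm$variant, cm$chrom, cm$pos, cm$effect_allele, cm$other_allele,
              cm$beta, cm$se, cm$beta_out, cm$se_out)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("summary-statistics file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  beta_x <- as.matrix(df[, cm$beta, drop = FALSE])
  se_x <- as.matrix(df[, cm$se, drop = FALSE])
  beta_y <- df[[cm$beta_out]]
  se_y <- df[[cm$se_out]]
  complete <- stats::complete.cases(beta_x, se_x, beta_y, se_y)
  if (any(!complete)) {
    pcg_log("dropping %d row(s) with missing association estimates",
            sum(!complete))
    df <- df[complete, , drop = FALSE]
    beta_x <- beta_x[complete, , drop = FALSE]
    se_x <- se_x[complete, , drop = FALSE]
    beta_y <- beta_y[complete]
    se_y <- se_y[complete]
  }
  variants <- data.frame(id = as.character(df[[cm$variant]]),
                         chrom = as.character(df[[cm$chrom]]),
                         pos = as.integer(df[[cm$pos]]),
                         effect_allele = toupper(df[[cm$effect_allele]]),
                         other_allele = toupper(df[[cm$other_allele]]),
                         stringsAsFactors = FALSE)
  regional_summary(variants, beta_x, se_x, beta_y, se_y,
                   n_x = n_x, n_y = n_y, trait_names = cm$traits)
}

#' Write regional summary statistics to a delimited file
#'
#' Inverse of [read_summary_stats()] using the default column convention.
#' Numeric fields are written at full double precision so that a write/read
#' round trip preserves them.
#'
#' @param data a `regional_summary` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(data, path) {
  df <- data$variants
  names(df)[names(df) == "id"] <- "variant"
  for (k in seq_along(data$trait_names)) {
    df[[paste0("beta_", data$trait_names[k])]] <- data$beta_x[, k]
    df[[paste0("se_", data$trait_names[k])]] <- data$se_x[, k]
  }
  df$beta_out <- data$beta_y
  df$se_out <- data$se_y
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "pos"
  for (j in which(num)) df[[j]] <- formatC(df[[j]], format = "g", digits = 17)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize summary data to a reference variant list
#'
#' Reorders variants to the reference order and aligns effect alleles. Where
#' the effect/other alleles are swapped relative to the reference, every beta
#' (risk factors and outcome) is sign-flipped. Palindromic variants (A/T or
#' C/G) are retained with a warning since strand cannot be resolved without
#' allele frequencies. Allele pairs incompatible with the reference are an
#' error, as are reference variants absent from the data.
#'
#' @param data a `regional_summary` object.
#' @param reference data.frame with columns `id`, `effect_allele`,
#'   `other_allele` giving the target variant order and allele orientation.
#' @return A harmonized `regional_summary` in reference order.
#' @export
harmonize <- function(data, reference) {
  idx <- match(reference$id, data$variants$id)
  if (anyNA(idx)) {
    stop("variant(s) missing from summary data: ",
         paste(reference$id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  v <- data$variants[idx, , drop = FALSE]
  ea <- toupper(reference$effect_allele)
  oa <- toupper(reference$other_allele)
  same <- v$effect_allele == ea & v$other_allele == oa
  swapped <- v$effect_allele == oa & v$other_allele == ea
  bad <- !(same | swapped)
  if (any(bad)) {
    stop("allele pair incompatible with reference for variant(s): ",
         paste(v$id[bad], collapse = ", "), call. = FALSE)
  }
  pal <- (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
  if (any(pal)) {
    warning(sprintf("%d palindromic variant(s) retained without strand check: %s",
                    sum(pal), paste(v$id[pal], collapse = ", ")), call. = FALSE)
  }
  flip <- ifelse(swapped, -1, 1)
  v$effect_allele <- ea
  v$other_allele <- oa
  regional_summary(v,
                   data$beta_x[idx, , drop = FALSE] * flip,
                   data$se_x[idx, , drop = FALSE],
                   data$beta_y[idx] * flip,
                   data$se_y[idx],
                   n_x = data$n_x, n_y = data$n_y,
                   trait_names = data$trait_names)
}

#' Restrict summary data to a genomic window
#'
#' Retains variants with `start - flank <= pos <= end + flank` on the given
#' chromosome. Coordinates are 1-based and inclusive on both ends (GRCh37
#' convention).
#'
#' @param data a `regional_summary` object.
#' @param chrom chromosome label (matched as string).
#' @param start,end gene start/end positions, `start <= end`.
#' @param flank non-negative flank width in base pairs (default 1e5).
#' @return Filtered `regional_summary`.
#' @export
filter_region <- function(data, chrom, start, end, flank = 1e5) {
  assert_that(start <= end, "start must be <= end")
  assert_that(flank >= 0, "flank must be non-negative")
  keep <- data$variants$chrom == as.character(chrom) &
    data$variants$pos >= start - flank &
    data$variants$pos <= end + flank
  if (!any(keep)) {
    stop("no variants in the requested region; widen the region or flank",
         call. = FALSE)
  }
  subset_summary(data, which(keep))
}

#' @noRd
subset_summary <- function(data, idx) {
  regional_summary(data$variants[idx, , drop = FALSE],
                   data$beta_x[idx, , drop = FALSE],
                   data$se_x[idx, , drop = FALSE],
                   data$beta_y[idx], data$se_y[idx],
                   n_x = data$n_x, n_y = data$n_y,
                   trait_names = data$trait_names)
}

#' Minimum risk-factor association p-value per variant
#'
#' Two-sided Wald p-values (beta/se against the standard normal), minimised
#' across risk factors.
#'
#' @param data a `regional_summary` object.
#' @return Length-J numeric vector.
#' @export
min_trait_pvalue <- function(data) {
  z <- abs(data$beta_x / data$se_x)
  apply(2 * stats::pnorm(-z), 1, min)
}

#' LD-prune and significance-screen variants
#'
#' Greedy pruning by association rank: variants are ordered by their minimum
#' risk-factor p-value (ties broken by position, then id), the best is kept
#' first, and any remaining variant whose squared correlation with an
#' already-kept variant exceeds `r2_max` is removed. Variants whose minimum
#' risk-factor p-value is not below `p_screen` are then dropped. The defaults
#' (`r2_max = 0.95`, `p_screen = 0.05`) match common cis-MR practice.
#'
#' @param data a `regional_summary` object.
#' @param ld an [ld_matrix] aligned with `data`.
#' @param r2_max squared-correlation pruning threshold in (0, 1].
#' @param p_screen significance screen in (0, 1]; variants kept only if
#'   min p-value < `p_screen` (strict).
#' @return List with elements `data` and `ld`, both subset to the surviving
#'   variants.
#' @export
prune_and_screen <- function(data, ld, r2_max = 0.95, p_screen = 0.05) {
  assert_that(r2_max > 0 && r2_max <= 1, "r2_max must be in (0, 1]")
  assert_that(p_screen > 0 && p_screen <= 1, "p_screen must be in (0, 1]")
  assert_that(identical(data$variants$id, ld$ids),
              "data and LD matrix are not aligned")
  J <- n_variants(data)
  pmin_v <- min_trait_pvalue(data)
  ord <- order(pmin_v, data$variants$pos, data$variants$id)
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(ld$rho[j, kept]^2 <= r2_max)) {
      kept <- c(kept, j)
    }
  }
  kept <- kept[pmin_v[kept] < p_screen]
  kept <- sort(kept)
  K <- ncol(data$beta_x)
  if (length(kept) < K + 1) {
    stop(sprintf(paste0("only %d variant(s) survive pruning/screening; at least ",
                        "%d needed to identify %d risk-factor effects"),
                 length(kept), K + 1, K), call. = FALSE)
  }
  if (length(kept) < J) {
    pcg_log("prune_and_screen: %d of %d variants retained", length(kept), J)
  }
  list(data = subset_summary(data, kept), ld = subset_ld(ld, kept))
}
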