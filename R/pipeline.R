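# End-to-end pipeline: read -> harmonize -> filter -> prune -> transform ->
# conditional F -> fit (+ optional colocalization and model averaging),
# driven by a validated configuration, with TSV outputs and a JSON run
# manifest.

#' Validate and normalize a run configuration
#'
#' A configuration is a named list (or a YAML file path) with entries:
#' `summary_path`, `ld_path` (inputs); optional `column_map`; optional
#' `region` (list `chrom`, `start`, `end`, `flank`); thresholds
#' `variance_threshold` (default 0.99), `r2_max` (0.95), `p_screen` (0.05);
#' optional `trait_cor_path` (TSV of the K x K risk-factor correlation
#' matrix; identity if absent); `robust` flag (default `TRUE`); `ci_level`
#' (0.95); `seed` (1); `output_dir` (default `"pcgmm_results"`); optional
#' `coloc` (list `trait1`, `trait2`, optional `p12`, `prior_sd1`,
#' `prior_sd2`, `p12_grid`); optional `bma` (list `prior_p`, `sigma_prior`).
#'
#' @param config named list or path to a YAML file.
#' @return Normalized configuration list; errors on invalid settings before
#'   any computation.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a list or a YAML file path")
  defaults <- list(variance_threshold = 0.99, r2_max = 0.95,
                   p_screen = 0.05, robust = TRUE, ci_level = 0.95,
                   seed = 1L, output_dir = "pcgmm_results",
                   column_map = NULL, region = NULL, trait_cor_path = NULL,
                   coloc = NULL, bma = NULL)
  cfg <- utils::modifyList(defaults, config)
  assert_that(!is.null(cfg$summary_path), "config must name summary_path")
  assert_that(!is.null(cfg$ld_path), "config must name ld_path")
  assert_that(cfg$variance_threshold > 0 && cfg$variance_threshold <= 1,
              "variance_threshold must be in (0, 1]")
  assert_that(cfg$r2_max > 0 && cfg$r2_max <= 1, "r2_max must be in (0, 1]")
  assert_that(cfg$p_screen > 0 && cfg$p_screen <= 1,
              "p_screen must be in (0, 1]")
  assert_that(cfg$ci_level > 0 && cfg$ci_level < 1,
              "ci_level must be in (0, 1)")
  cfg
}

#' Run the full cis-MR pipeline from a configuration
#'
#' Executes the standard analysis sequence: read summary statistics and LD
#' matrix, harmonize the data to the LD variant order, optionally restrict
#' to a genomic window, LD-prune and significance-screen, PSD-repair the LD
#' matrix, PC-transform, compute conditional F-statistics, and fit the
#' (robust by default) PC-GMM model. Writes `estimates.tsv` (estimate, CI,
#' p-value, number of PCs and variants per risk factor), `conditional_f.tsv`,
#' `components.tsv` (eigenvalue table), optional `coloc.tsv` /
#' `coloc_sensitivity.tsv` and `bma_models.tsv` / `bma_inclusion.tsv`, and
#' a `manifest.json` naming inputs and the resolved configuration. Outputs
#' are formatted at 6 significant digits so identical config + inputs +
#' seed reproduce byte-identical files.
#'
#' @param config list or YAML path accepted by [run_config()].
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  set.seed(as.integer(cfg$seed))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- read_summary_stats(cfg$summary_path, column_map = cfg$column_map)
  ld <- read_ld_matrix(cfg$ld_path)
  ref <- dat$variants[match(ld$ids, dat$variants$id), , drop = FALSE]
  if (anyNA(ref$id)) {
    stop("summary_io: LD matrix contains variants absent from the summary data",
         call. = FALSE)
  }
  dat <- harmonize(dat, ref)
  if (!is.null(cfg$region)) {
    keep_ids <- filter_region(dat, cfg$region$chrom, cfg$region$start,
                              cfg$region$end,
                              flank = cfg$region$flank %||% 1e5)$variants$id
    idx <- match(keep_ids, dat$variants$id)
    dat <- subset_summary(dat, idx)
    ld <- subset_ld(ld, match(keep_ids, ld$ids))
  }
  ps <- prune_and_screen(dat, ld, r2_max = cfg$r2_max,
                         p_screen = cfg$p_screen)
  dat <- ps$data
  ld <- repair_psd(ps$ld)
  trait_cor <- if (!is.null(cfg$trait_cor_path)) {
    trait_correlation(as.matrix(utils::read.table(cfg$trait_cor_path,
                                                  header = TRUE)),
                      dat$trait_names)
  } else NULL
  red <- pc_transform(dat, ld, variance_threshold = cfg$variance_threshold,
                      trait_cor = trait_cor)
  condf <- all_conditional_f(red)
  fit <- if (isTRUE(cfg$robust)) fit_robust(red, level = cfg$ci_level)
  else fit_unrobust(red, level = cfg$ci_level)

  paths <- list()
  est <- data.frame(trait = names(fit$theta),
                    estimate = unname(fit$theta),
                    se = unname(fit$se_theta),
                    ci_lower = unname(fit$ci_lower),
                    ci_upper = unname(fit$ci_upper),
                    p_value = unname(fit$pvalue),
                    n_pcs = fit$n_pcs, n_variants = fit$n_variants,
                    kappa2 = fit$kappa2, robust = fit$robust)
  paths$estimates <- write_tsv_fixed(est, file.path(cfg$output_dir, "estimates.tsv"))
  cf <- data.frame(trait = names(condf$f_stats),
                   conditional_f = unname(condf$f_stats),
                   df = condf$df, p_value = unname(condf$pvalues),
                   tier = condf$warning_tier)
  paths$conditional_f <- write_tsv_fixed(cf, file.path(cfg$output_dir, "conditional_f.tsv"))
  pos <- pmax(red$eigenvalues, 0)
  comp <- data.frame(component = seq_along(red$eigenvalues),
                     eigenvalue = red$eigenvalues,
                     cumulative_share = cumsum(pos) / sum(pos),
                     retained = seq_along(red$eigenvalues) <= red$p)
  paths$components <- write_tsv_fixed(comp, file.path(cfg$output_dir, "components.tsv"))

  coloc_res <- NULL
  if (!is.null(cfg$coloc)) {
    k1 <- match(cfg$coloc$trait1, dat$trait_names)
    k2 <- match(cfg$coloc$trait2, dat$trait_names)
    assert_that(!is.na(k1) && !is.na(k2), "coloc traits not found in data")
    d1 <- list(beta = dat$beta_x[, k1], se = dat$se_x[, k1])
    d2 <- list(beta = dat$beta_x[, k2], se = dat$se_x[, k2])
    sd1 <- cfg$coloc$prior_sd1 %||% 0.15
    sd2 <- cfg$coloc$prior_sd2 %||% 0.15
    coloc_res <- colocalize(d1, d2,
                            priors = c(1e-4, 1e-4, cfg$coloc$p12 %||% 1e-5),
                            prior_sd1 = sd1, prior_sd2 = sd2)
    cr <- data.frame(hypothesis = names(coloc_res$posteriors),
                     posterior = unname(coloc_res$posteriors))
    paths$coloc <- write_tsv_fixed(cr, file.path(cfg$output_dir, "coloc.tsv"))
    if (!is.null(cfg$coloc$p12_grid)) {
      sens <- p12_sensitivity(d1, d2, p12_grid = as.numeric(cfg$coloc$p12_grid),
                              prior_sd1 = sd1, prior_sd2 = sd2)
      paths$coloc_sensitivity <-
        write_tsv_fixed(sens, file.path(cfg$output_dir, "coloc_sensitivity.tsv"))
    }
  }

  bma_res <- NULL
  if (!is.null(cfg$bma)) {
    bma_res <- enumerate_bma(red, prior_p = cfg$bma$prior_p %||% 0.1,
                             sigma_prior = cfg$bma$sigma_prior %||% 0.5)
    paths$bma_models <- write_tsv_fixed(bma_res$models,
                                        file.path(cfg$output_dir, "bma_models.tsv"))
    inc <- data.frame(trait = names(bma_res$inclusion),
                      inclusion_probability = unname(bma_res$inclusion))
    paths$bma_inclusion <- write_tsv_fixed(inc,
                                           file.path(cfg$output_dir, "bma_inclusion.tsv"))
  }

  manifest <- list(package = "pcgmm",
                   version = as.character(utils::packageVersion("pcgmm")),
                   inputs = list(summary_path = cfg$summary_path,
                                 ld_path = cfg$ld_path,
                                 trait_cor_path = cfg$trait_cor_path),
                   config = cfg[c("variance_threshold", "r2_max", "p_screen",
                                  "robust", "ci_level", "seed")],
                   n_variants = n_variants(dat),
                   n_pcs = red$p,
                   ld_psd_repaired = ld$psd_repaired)
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths$manifest <- manifest_path
  invisible(list(data = dat, ld = ld, reduction = red, fit = fit,
                 conditional_f = condf, coloc = coloc_res, bma = bma_res,
                 paths = paths))
}
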