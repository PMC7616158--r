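# Reading, harmonization, region filtering, pruning/screening, PSD repair.

test_that("summary statistics round-trip through file IO", {
  dat <- make_toy_summary(J = 253, K = 2, seed = 3)
  path <- write_summary_fixture(dat)
  got <- read_summary_stats(path)
  expect_equal(n_variants(got), 253)
  expect_equal(ncol(got$beta_x), 2)
  expect_identical(got$trait_names, dat$trait_names)
  # numeric fields preserved to at least 10 significant digits
  expect_equal(got$beta_x, dat$beta_x, tolerance = 1e-10)
  expect_equal(got$se_x, dat$se_x, tolerance = 1e-10)
  expect_equal(got$beta_y, dat$beta_y, tolerance = 1e-10)
  expect_equal(got$se_y, dat$se_y, tolerance = 1e-10)
  expect_identical(got$variants$id, dat$variants$id)
})

test_that("reader validates columns, drops incomplete rows, rejects bad SEs", {
  dat <- make_toy_summary(J = 3, K = 1)
  path <- write_summary_fixture(dat)
  expect_equal(n_variants(read_summary_stats(path)), 3)

  # missing mandatory column named in the error
  df <- read.delim(path, check.names = FALSE)
  df$se_out <- NULL
  p2 <- tempfile(fileext = ".tsv")
  write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(p2), "se_out")

  # a missing beta is dropped with a message, not an error
  df <- read.delim(path, check.names = FALSE)
  df$beta_out[2] <- NA
  p3 <- tempfile(fileext = ".tsv")
  write.table(df, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(got <- read_summary_stats(p3), "dropping 1")
  expect_equal(n_variants(got), 2)

  # zero SE is an error naming the variant
  df <- read.delim(path, check.names = FALSE)
  df$se_out[1] <- 0
  p4 <- tempfile(fileext = ".tsv")
  write.table(df, p4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(p4), df$variant[1])
})

test_that("harmonize flips swapped alleles and is idempotent", {
  dat <- make_toy_summary(J = 10, K = 2, seed = 5)
  ref <- dat$variants[, c("id", "effect_allele", "other_allele")]
  flip_rows <- c(2, 5, 9)
  ref[flip_rows, c("effect_allele", "other_allele")] <-
    ref[flip_rows, c("other_allele", "effect_allele")]

  out <- harmonize(dat, ref)
  sign <- ifelse(seq_len(10) %in% flip_rows, -1, 1)
  expect_equal(out$beta_y, dat$beta_y * sign)
  expect_equal(out$beta_x, dat$beta_x * sign, ignore_attr = TRUE)
  expect_equal(out$se_x, dat$se_x, ignore_attr = TRUE)
  expect_identical(out$variants$effect_allele, ref$effect_allele)

  # idempotence: a second pass against the same reference changes nothing
  again <- harmonize(out, ref)
  expect_equal(again$beta_y, out$beta_y)
  expect_equal(again$beta_x, out$beta_x)

  # already-harmonized data returned unchanged
  same <- harmonize(dat, dat$variants)
  expect_equal(same$beta_y, dat$beta_y)

  # reordering to a shuffled reference follows the reference order
  shuf <- dat$variants[c(3, 1, 2, 4:10), ]
  expect_identical(harmonize(dat, shuf)$variants$id, shuf$id)
})

test_that("harmonize errors on missing or incompatible variants, warns on palindromes", {
  dat <- make_toy_summary(J = 5, K = 1)
  ref <- dat$variants
  ref$id[2] <- "rs_absent"
  expect_error(harmonize(dat, ref), "rs_absent")

  ref <- dat$variants
  ref$effect_allele[3] <- "T"
  ref$other_allele[3] <- "C"  # toy data row 3 is A/G: incompatible
  expect_error(harmonize(dat, ref), dat$variants$id[3])

  pal <- dat
  pal$variants$effect_allele[1] <- "A"
  pal$variants$other_allele[1] <- "T"
  expect_warning(harmonize(pal, pal$variants), "palindromic")
})

test_that("filter_region is 1-based and inclusive at both flanked ends", {
  dat <- make_toy_summary(J = 20, K = 1, pos0 = 0L)  # positions 10,20,...,200
  # window [95, 120] with flank 15 -> keep pos in [80, 135]: 80..130 by 10
  out <- filter_region(dat, "6", 95, 120, flank = 15)
  expect_identical(out$variants$pos, seq(80L, 130L, 10L))

  # boundary: pos == start - flank retained, one below dropped
  expect_true(80 %in% filter_region(dat, "6", 95, 120, 15)$variants$pos)
  expect_false(70 %in% filter_region(dat, "6", 95, 120, 15)$variants$pos)
  expect_error(filter_region(dat, "1", 95, 120, 15), "region")
})

test_that("prune_and_screen matches a brute-force oracle of the greedy rule", {
  dat <- make_toy_summary(J = 10, K = 2, seed = 11)
  ld <- make_ar1_ld(10, 0.8)
  r2_max <- 0.5
  p_screen <- 0.6

  # independent brute-force enumeration of the stated rule
  pm <- apply(2 * pnorm(-abs(dat$beta_x / dat$se_x)), 1, min)
  ord <- order(pm, dat$variants$pos, dat$variants$id)
  kept <- integer(0)
  for (j in ord) {
    ok <- TRUE
    for (i in kept) if (ld$rho[i, j]^2 > r2_max) ok <- FALSE
    if (ok) kept <- c(kept, j)
  }
  kept <- sort(kept[pm[kept] < p_screen])

  out <- prune_and_screen(dat, ld, r2_max = r2_max, p_screen = p_screen)
  expect_identical(out$data$variants$id, dat$variants$id[kept])
  expect_identical(out$ld$ids, ld$ids[kept])

  # no surviving pair exceeds the correlation threshold
  r2 <- out$ld$rho^2
  diag(r2) <- 0
  expect_lte(max(r2), r2_max)
})

test_that("prune_and_screen no-op thresholds and forced-choice behaviour", {
  dat <- make_toy_summary(J = 8, K = 2, seed = 2)
  ld <- make_ar1_ld(8, 0.3)
  out <- prune_and_screen(dat, ld, r2_max = 1, p_screen = 1)
  expect_identical(out$data$variants$id, dat$variants$id)

  # two perfectly correlated variants: only the smaller-p one survives
  dat2 <- make_toy_summary(J = 5, K = 1, seed = 7)
  dat2$beta_x[1, 1] <- 0.01   # weak
  dat2$beta_x[2, 1] <- 0.50   # strong twin
  rho <- diag(5)
  rho[1, 2] <- rho[2, 1] <- 1
  ld2 <- ld_matrix(rho, dat2$variants$id)
  out2 <- prune_and_screen(dat2, ld2, r2_max = 0.95, p_screen = 1)
  expect_false("rs0001" %in% out2$data$variants$id)
  expect_true("rs0002" %in% out2$data$variants$id)

  # too few survivors is an identification error
  dat3 <- make_toy_summary(J = 5, K = 1, seed = 8)
  ld3 <- make_ar1_ld(5, 0)
  expect_error(prune_and_screen(dat3, ld3, 0.95, 1e-12), "survive")
})

test_that("repair_psd clips negative eigenvalues and is a no-op on PSD input", {
  idm <- ld_matrix(diag(5))
  out <- repair_psd(idm)
  expect_false(out$psd_repaired)
  expect_equal(out$rho, idm$rho, ignore_attr = TRUE)

  # 2x2 with off-diagonal 1.001 is indefinite; repair restores PSD + unit diag
  m <- matrix(c(1, 1.001, 1.001, 1), 2)
  rep2 <- repair_psd(ld_matrix(m, c("a", "b")))
  expect_true(rep2$psd_repaired)
  expect_equal(diag(rep2$rho), c(1, 1), ignore_attr = TRUE)
  expect_gte(min(eigen(rep2$rho, symmetric = TRUE)$values), -1e-10)
  expect_lt(rep2$min_eigenvalue_before, 0)

  # random indefinite perturbation of an AR(1) matrix
  set.seed(42)
  base <- 0.9^abs(outer(1:50, 1:50, "-"))
  noise <- matrix(rnorm(2500, 0, 0.05), 50)
  noise <- (noise + t(noise)) / 2
  diag(noise) <- 0
  pert <- pmin(pmax(base + noise, -1), 1)
  diag(pert) <- 1
  expect_lt(min(eigen(pert, symmetric = TRUE)$values), 0)  # indefinite
  rep50 <- repair_psd(ld_matrix(pert, as.character(1:50)))
  expect_true(rep50$psd_repaired)
  expect_gte(min(eigen(rep50$rho, symmetric = TRUE)$values), -1e-10)
  expect_equal(max(abs(diag(rep50$rho) - 1)), 0)

  # repairing again is a no-op
  again <- repair_psd(rep50)
  expect_equal(again$rho, rep50$rho, tolerance = 1e-12)

  # asymmetry beyond tolerance is an error
  bad <- diag(3)
  bad[1, 2] <- 0.5
  expect_error(ld_matrix(bad), "asymmetric")
})

test_that("LD matrix file dialects round-trip", {
  ld <- make_ar1_ld(6, 0.7)
  sq <- tempfile(fileext = ".tsv")
  write_ld_matrix(ld, sq)
  got <- read_ld_matrix(sq)
  expect_equal(got$rho, ld$rho, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(got$ids, ld$ids)

  # triplet dialect (signed r)
  tri <- data.frame(id1 = c("a", "a"), id2 = c("b", "c"), r = c(0.5, -0.2))
  tp <- tempfile(fileext = ".tsv")
  write.table(tri, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  lt <- read_ld_matrix(tp, ids = c("a", "b", "c"))
  expect_equal(lt$rho["a", "b"], 0.5)
  expect_equal(lt$rho["c", "a"], -0.2)
  expect_equal(lt$rho["b", "c"], 0)
  expect_equal(diag(lt$rho), rep(1, 3), ignore_attr = TRUE)
})
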