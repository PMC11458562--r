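test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_samples = 60, n_snps = 24, n_causal = 3,
                    missing_rate = 0.02, seed = 4)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth, b$truth)
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(n_causal = 50, n_snps = 20), "n_causal")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("genotypes match the requested MAF and LD structure", {
  # independence case: adjacent r2 vanishes when ld_rho = 0
  cfg0 <- sim_config(n_samples = 5000, n_snps = 40, ld_rho = 0, seed = 1)
  g0 <- simulate_genotypes(cfg0)
  r2 <- vapply(seq_len(39), function(j) {
    ld_r2(g0$dosages[, j], g0$dosages[, j + 1])
  }, numeric(1))
  expect_lt(mean(r2), 0.02)

  # fixed MAF recovered within binomial sampling error
  cfgm <- sim_config(n_samples = 5000, n_snps = 30,
                     maf_range = c(0.3, 0.3), seed = 2)
  gm <- simulate_genotypes(cfgm)
  expect_true(all(abs(minor_allele_freq(gm$dosages) - 0.3) < 0.02))

  # within-block dosage correlation increases with ld_rho
  mean_block_cor <- function(rho, seed) {
    cfg <- sim_config(n_samples = 5000, n_snps = 16, ld_block_size = 4,
                      ld_rho = rho, seed = seed)
    g <- simulate_genotypes(cfg)
    idx <- seq(1, 13, by = 4)
    mean(vapply(idx, function(j) {
      stats::cor(g$dosages[, j], g$dosages[, j + 1])
    }, numeric(1)))
  }
  cors <- vapply(c(0, 0.4, 0.8), function(rho) {
    mean(vapply(1:20, function(s) mean_block_cor(rho, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("generated genotypes are close to Hardy-Weinberg proportions", {
  cfg <- sim_config(n_samples = 5000, n_snps = 200, seed = 3)
  g <- simulate_genotypes(cfg)
  pv <- igscca:::hwe_pvalues(g$dosages)
  expect_lte(mean(pv < 0.05), 0.15)
})

test_that("amyloid positivity hits the configured target rate", {
  co <- simulate_cohort(sim_config(n_samples = 1500, n_snps = 60,
                                   n_causal = 6, seed = 5))
  expect_lt(abs(mean(co$pheno$abeta) - 0.575), 0.05)
})

test_that("planted canonical correlation follows the closed-form ratio", {
  zero_cov <- list(age = 0, sex = 0, education = 0, icv = 0)
  # noiseless limit: projection correlation approaches 1
  cfg1 <- sim_config(n_samples = 400, n_snps = 60, n_causal = 6,
                     noise_sd = 1e-6, path_a = 0, path_b = 0,
                     covariate_effects = zero_cov, seed = 6)
  co1 <- simulate_cohort(cfg1)
  z1 <- standardize_columns(mean_impute(co1$geno$dosages)) %*% co1$truth$u_true
  yv1 <- as.matrix(co1$pheno[, co1$rois]) %*% co1$truth$v_true
  expect_gt(stats::cor(z1, yv1), 0.999)

  # default strength/noise: corr(Xu, Yv) ~ s / sqrt(s^2 + sigma^2) = 0.5
  cfg2 <- sim_config(n_samples = 1000, path_a = 0, path_b = 0,
                     covariate_effects = zero_cov, seed = 7)
  co2 <- simulate_cohort(cfg2)
  z2 <- standardize_columns(mean_impute(co2$geno$dosages)) %*% co2$truth$u_true
  yv2 <- as.matrix(co2$pheno[, co2$rois]) %*% co2$truth$v_true
  expect_lt(abs(stats::cor(z2, yv2) - co2$truth$planted_rho), 0.05)
  expect_equal(co2$truth$planted_rho, 0.5, tolerance = 1e-12)
})

test_that("truth vectors are unit norm with support on the causal set", {
  co <- simulate_cohort(sim_config(n_samples = 50, n_snps = 40,
                                   n_causal = 4, seed = 8))
  expect_equal(sqrt(sum(co$truth$u_true^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(co$truth$v_true^2)), 1, tolerance = 1e-12)
  expect_identical(which(co$truth$u_true != 0),
                   as.integer(co$truth$causal_indices))
})

test_that("summary statistics place causal and decoy SNPs below threshold", {
  cfg0 <- sim_config(n_samples = 30, n_snps = 50, n_causal = 5,
                     decoy_fraction = 0, seed = 9)
  co <- simulate_cohort(cfg0)
  ss0 <- simulate_summary_stats(cfg0, co$truth, co$geno)
  expect_setequal(ss0$snp[ss0$p < 1e-4], co$truth$causal_ids)
  expect_length(filter_by_pvalue(ss0, 1.0, co$geno$snps$id), 50)

  cfg9 <- sim_config(n_samples = 30, n_snps = 50, n_causal = 5,
                     decoy_fraction = 0.9, seed = 9)
  ss9 <- simulate_summary_stats(cfg9, co$truth, co$geno)
  expect_equal(sum(ss9$p < 1e-4), 5 + round(0.9 * 45))
})

test_that("fixture files round-trip and stay mutually consistent", {
  cfg <- sim_config(n_samples = 37, n_snps = 23, n_causal = 3,
                    missing_rate = 0.05, seed = 10)
  co <- simulate_cohort(cfg)
  co$sumstats <- simulate_summary_stats(cfg, co$truth, co$geno)
  co$annotation <- simulate_annotation(co$geno, co$truth, cfg)
  co$gene_sets <- simulate_gene_sets(co$annotation, co$truth, seed = 1)
  out <- withr::local_tempdir()
  paths <- write_fixture(co, out)
  back <- read_plink(file.path(out, "geno"))
  expect_identical(unname(back$dosages), unname(co$geno$dosages))
  pheno <- utils::read.delim(paths[["pheno"]])
  expect_equal(nrow(utils::read.table(paths[["fam"]])), nrow(pheno))
  expect_equal(nrow(utils::read.table(paths[["bim"]])),
               ncol(co$geno$dosages))
  sets <- read_gmt(paths[["gmt"]])
  expect_setequal(sets$planted_causal_pathway,
                  co$gene_sets$planted_causal_pathway)
})

test_that("same-seed fixture writes are byte-identical", {
  cfg <- sim_config(n_samples = 25, n_snps = 12, n_causal = 2, seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co1 <- simulate_cohort(cfg); co2 <- simulate_cohort(cfg)
  write_fixture(co1, d1); write_fixture(co2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
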