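test_that("elastic-net CV tracks signal and stays honest under the null", {
  set.seed(1)
  n <- 300
  x <- matrix(rnorm(n * 8), n, 8)
  y <- drop(x %*% c(2, -1, 0.5, rep(0, 5))) + 1
  fit <- fit_elastic_net_cv(x, y, seed = 1)
  expect_gt(fit$cv_r, 0.99)

  y0 <- rnorm(500)
  x0 <- matrix(rnorm(500 * 8), 500, 8)
  fit0 <- fit_elastic_net_cv(x0, y0, seed = 1)
  expect_lt(abs(fit0$cv_r), 0.15)

  fit_a <- fit_elastic_net_cv(x, y, seed = 7)
  fit_b <- fit_elastic_net_cv(x, y, seed = 7)
  expect_identical(fit_a$cv_r, fit_b$cv_r)

  expect_error(fit_elastic_net_cv(x, rep(1, n)), "constant")
  expect_error(fit_elastic_net_cv(x[1:10, ], y[1:10]), "25")
})

test_that("noise features do not inflate cross-validated r", {
  set.seed(2)
  infl <- vapply(1:8, function(s) {
    set.seed(s)
    n <- 250
    x <- matrix(rnorm(n * 5), n, 5)
    y <- drop(x %*% rnorm(5)) + rnorm(n)
    base <- fit_elastic_net_cv(x, y, repeats = 3, seed = s)$cv_r
    noisy <- fit_elastic_net_cv(cbind(x, matrix(rnorm(n * 10), n, 10)), y,
                                repeats = 3, seed = s)$cv_r
    noisy - base
  }, numeric(1))
  expect_lt(mean(infl), 0.03)
})

test_that("Hittner's z matches an independent hand computation", {
  # identity: equal correlations give z = 0, p = 1
  h0 <- hittner_test(0.4, 0.4, 0.2, 50)
  expect_equal(h0$z, 0)
  expect_equal(h0$p, 1)

  # worked example (r12=0.5, r13=0.3, r23=0.4, n=100) computed step by
  # step from the published formula: z12=atanh(.5)=0.5493061,
  # z13=atanh(.3)=0.3095196, back-transformed mean rm=tanh(0.4294129)
  # =0.4048338, cbar=0.3245980, z=(z12-z13)*sqrt(97/(2-2*cbar))=2.0319461
  h <- hittner_test(0.5, 0.3, 0.4, 100)
  expect_equal(h$z, 2.0319461, tolerance = 1e-6)
  expect_equal(h$p, 2 * pnorm(-2.0319461), tolerance = 1e-6)

  expect_error(hittner_test(0.9, -0.9, 0.9, 50), "positive semi-definite")
  expect_error(hittner_test(1, 0.5, 0.5, 50), "correlations")
})

test_that("Hittner p-values are uniform under the null", {
  set.seed(3)
  r <- matrix(c(1, 0.5, 0.5, 0.5, 1, 0.7, 0.5, 0.7, 1), 3, 3)
  ch <- chol(r)
  ps <- vapply(1:2000, function(i) {
    z <- matrix(rnorm(200 * 3), 200, 3) %*% ch
    hittner_test(cor(z[, 1], z[, 2]), cor(z[, 1], z[, 3]),
                 cor(z[, 2], z[, 3]), 200)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.015)
})

test_that("model comparison is antisymmetric and detects dominance", {
  set.seed(4)
  y <- rnorm(500)
  pa <- y + rnorm(500, 0, 2)
  pb <- y + rnorm(500, 0, 0.5)
  ab <- compare_models(pa, pb, y)
  ba <- compare_models(pb, pa, y)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_lt(ab$p, 0.05)
  same <- compare_models(pa, pa, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(compare_models(pa[1:10], pb, y), "same samples")
})

test_that("cross-group validation mirrors planted signal structure", {
  # identical groups: train and test r agree closely
  set.seed(5)
  cfg <- sim_config(n_samples = 400, n_snps = 40, n_causal = 4, seed = 21)
  co <- simulate_cohort(cfg)
  dos <- mean_impute(co$geno$dosages)
  colnames(dos) <- co$geno$snps$id
  dd <- rbind(dos, dos)
  thick <- rep(rowMeans(co$pheno[, grep("^global", co$rois, value = TRUE)]), 2)
  grp <- rep(c(0, 1), each = 400)
  ids <- co$truth$causal_ids
  ff <- function(snps) dd[, snps, drop = FALSE]
  rep_identical <- cross_group_validate(ff, thick, grp, ids, ids,
                                        repeats = 3, seed = 5)
  expect_lt(max(abs(rep_identical$train_r - rep_identical$test_r)), 0.12)
  expect_true(all(rep_identical$train_lo <= rep_identical$train_r &
                    rep_identical$train_r <= rep_identical$train_hi))
  expect_error(
    cross_group_validate(ff, thick, rep(0, 300), ids, ids),
    "both amyloid groups")
})

test_that("disjoint group signals generalize poorly across groups", {
  ok <- vapply(1:5, function(s) {
    gr <- make_disjoint_groups(n_per_group = 220, n_snps = 120, seed = 40 + s)
    thick <- rowMeans(gr$pheno[, grep("^global", gr$rois, value = TRUE)])
    ff <- function(snps) gr$dosages[, snps, drop = FALSE]
    out <- cross_group_validate(ff, thick, gr$pheno$abeta,
                                gr$causal_ids_a, gr$causal_ids_b,
                                repeats = 3, seed = s)
    all(out$train_r - out$test_r > 0.1)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("the three-model grid runs and orders planted signal sensibly", {
  set.seed(6)
  cfg <- sim_config(n_samples = 260, n_snps = 80, n_causal = 6, seed = 31)
  co <- simulate_cohort(cfg)
  dos <- mean_impute(co$geno$dosages)
  colnames(dos) <- co$geno$snps$id
  thick <- rowMeans(co$pheno[, grep("^global", co$rois, value = TRUE)])
  mg <- model_grid(co$pheno, function(ids) dos[, ids, drop = FALSE],
                   panel_ids = co$geno$snps$id,
                   top_ids = co$truth$causal_ids, outcome = thick,
                   outcome_type = "thickness", repeats = 3, seed = 6)
  expect_identical(mg$summary$model, c("model1", "model2", "model3"))
  expect_true(all(is.finite(mg$summary$cv_r)))
  expect_gt(mg$summary$cv_r[2], mg$summary$cv_r[1])
  expect_false(any(mg$random_snps %in% co$truth$causal_ids))
})
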