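test_that("residualization removes covariate signal and standardizes", {
  set.seed(1)
  n <- 120
  covars <- cbind(age = rnorm(n, 70, 8), icv = rnorm(n, 1450, 140))
  y <- cbind(a = 2.5 - 0.01 * covars[, "age"] + rnorm(n, 0, 0.2),
             b = rnorm(n, 2.2, 0.3))
  adj <- residualize(y, covars)
  expect_true(all(abs(colMeans(adj)) < 1e-10))
  expect_equal(unname(apply(adj, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_lt(max(abs(crossprod(scale(covars, scale = FALSE), adj))) / n, 1e-10)

  # no covariates: plain z-scoring
  adj0 <- residualize(y)
  expect_equal(unname(adj0), unname(scale(y)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # exact linear dependence flagged as degenerate
  y2 <- cbind(lin = 1 + 2 * covars[, "age"], b = y[, "b"])
  adj2 <- residualize(y2, covars)
  expect_true(attr(adj2, "degenerate")[1])

  expect_error(residualize(y, cbind(covars, covars[, 1])), "collinear")
})

test_that("soft thresholding shrinks toward zero elementwise", {
  expect_equal(soft_threshold(c(3, -0.5), 1), c(2, 0))
  v <- c(-2, 0, 0.3, 5)
  expect_equal(soft_threshold(v, 0), v)
  expect_equal(soft_threshold(v, 10), rep(0, 4))
})

test_that("L1-constrained projection meets its budget exactly", {
  set.seed(2)
  w <- rnorm(12)
  # inactive budget: plain normalization
  expect_equal(l1_constrain(w, sqrt(12)), w / sqrt(sum(w^2)))
  # tau = 1: 1-sparse at the largest |entry|
  out1 <- l1_constrain(w, 1)
  expect_equal(sum(out1 != 0), 1)
  expect_equal(which(out1 != 0), which.max(abs(w)))
  expect_equal(abs(out1[out1 != 0]), 1)
  # active budget: unit L2, L1 = tau, matches a fine grid search
  for (tau in c(1.5, 2, 2.5)) {
    out <- l1_constrain(w, tau)
    expect_equal(sqrt(sum(out^2)), 1, tolerance = 1e-9)
    expect_equal(sum(abs(out)), tau, tolerance = 1e-6)
    grid <- seq(0, max(abs(w)), length.out = 20001)
    l1g <- vapply(grid, function(d) {
      s <- soft_threshold(w, d)
      if (all(s == 0)) return(Inf)
      sum(abs(s)) / sqrt(sum(s^2))
    }, numeric(1))
    d_star <- grid[which.min(abs(l1g - tau))]
    s <- soft_threshold(w, d_star)
    expect_lt(abs(sum(abs(out)) - sum(abs(s)) / sqrt(sum(s^2))), 1e-3)
  }
  expect_error(l1_constrain(rep(0, 5), 2), "zero")
})

test_that("rank-1 fit recovers the trivial single-column case", {
  set.seed(3)
  x <- matrix(scale(rnorm(50)), ncol = 1)
  fit <- scca_fit(x, x, tau1 = 1, tau2 = 1)
  expect_equal(fit$rho, 1, tolerance = 1e-12)
  expect_equal(abs(fit$u), 1)
  expect_equal(fit$u, fit$v)
})

test_that("with inactive budgets the fit matches classical CCA", {
  for (s in 1:5) {
    inst <- make_whitened_instance(n = 120, p = 6, q = 4, seed = s)
    fit <- scca_fit(inst$x, inst$y, tau1 = sqrt(6), tau2 = sqrt(4))
    expect_equal(fit$rho, stats::cancor(inst$x, inst$y)$cor[1],
                 tolerance = 1e-6)
  }
})

test_that("objective is monotone and the sign convention is reproducible", {
  set.seed(4)
  x <- standardize_columns(matrix(rnorm(80 * 15), 80, 15))
  y <- standardize_columns(matrix(rnorm(80 * 5), 80, 5))
  f1 <- scca_fit(x, y, tau1 = 2, tau2 = 1.5)
  expect_true(all(diff(f1$objective) >= -1e-10))
  expect_gt(f1$u[which.max(abs(f1$u))], 0)
  f2 <- scca_fit(x, y, tau1 = 2, tau2 = 1.5)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$v, f2$v)
  # invariants on the returned vectors
  expect_equal(sqrt(sum(f1$u^2)), 1, tolerance = 1e-8)
  expect_equal(sqrt(sum(f1$v^2)), 1, tolerance = 1e-8)
  expect_lte(sum(abs(f1$u)), 2 + 1e-6)
  expect_lte(sum(abs(f1$v)), 1.5 + 1e-6)
  expect_equal(f1$rho, stats::cor(x %*% f1$u, y %*% f1$v)[1, 1],
               tolerance = 1e-12)
  expect_error(scca_fit(x * NA, y), "NaN")
})

test_that("independent blocks give non-significant permutation p-values", {
  perm_p <- function(seed) {
    set.seed(seed)
    x <- standardize_columns(matrix(rnorm(300 * 12), 300, 12))
    y <- standardize_columns(matrix(rnorm(300 * 4), 300, 4))
    obs <- scca_fit(x, y, tau1 = 2, tau2 = 2)$rho
    null <- vapply(1:30, function(i) {
      scca_fit(x[sample(300), , drop = FALSE], y, tau1 = 2, tau2 = 2)$rho
    }, numeric(1))
    (1 + sum(null >= obs)) / 31
  }
  ps <- vapply(1:10, perm_p, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("tau tuning prefers sparse budgets for sparse planted signals", {
  set.seed(5)
  grid <- c(2, 4, sqrt(60))
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_samples = 300, n_snps = 60, n_causal = 4,
                      canonical_strength = 0.3, path_a = 0, path_b = 0,
                      seed = 100 + s)
    co <- simulate_cohort(cfg)
    inp <- scca_inputs(co)
    tt <- tune_tau(inp$x, inp$y, grid, n_folds = 3, seed = s)
    tt$tau1 < sqrt(60)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # single-element grid and determinism
  set.seed(6)
  x <- standardize_columns(matrix(rnorm(200), 50, 4))
  y <- standardize_columns(matrix(rnorm(150), 50, 3))
  t1 <- tune_tau(x, y, grid1 = 1.5, grid2 = 1.2, seed = 3)
  expect_equal(t1$tau1, 1.5)
  t2 <- tune_tau(x, y, grid1 = c(1.2, 2), grid2 = 1.2, seed = 3)
  t3 <- tune_tau(x, y, grid1 = c(1.2, 2), grid2 = 1.2, seed = 3)
  expect_identical(t2, t3)
})

test_that("top-k ranking is by |weight| with positional tie-breaks", {
  res <- list(u = c(0.3, -0.5, 0.1))
  snps <- data.frame(id = c("snp1", "snp2", "snp3"), chrom = 1, pos = 1:3)
  top <- top_k_snps(res, snps, 2)
  expect_identical(top$id, c("snp2", "snp1"))
  top_all <- top_k_snps(res, snps, 3)
  expect_setequal(top_all$id, snps$id)
  res0 <- list(u = c(0.3, 0, 0))
  expect_warning(top0 <- top_k_snps(res0, snps, 2), "nonzero")
  expect_identical(top0$id, "snp1")
})

test_that("group-wise SCCA treats identical groups identically", {
  set.seed(7)
  cfg <- sim_config(n_samples = 120, n_snps = 40, n_causal = 4, seed = 12)
  co <- simulate_cohort(cfg)
  dos <- mean_impute(co$geno$dosages)
  colnames(dos) <- co$geno$snps$id
  dd <- rbind(dos, dos)
  yy <- rbind(as.matrix(co$pheno[, co$rois]), as.matrix(co$pheno[, co$rois]))
  cc <- rbind(as.matrix(co$pheno[, c("age", "sex")]),
              as.matrix(co$pheno[, c("age", "sex")]))
  grp <- rep(c(0, 1), each = 120)
  res <- groupwise_scca(dd, co$geno$snps, yy, cc, grp, tau1 = 3, top_k = 5)
  expect_equal(res$negative$fit$u, res$positive$fit$u, tolerance = 1e-9)
  expect_equal(res$negative$fit$rho, res$positive$fit$rho, tolerance = 1e-9)
  expect_identical(res$negative$top$id, res$positive$top$id)
  expect_error(
    groupwise_scca(dd, co$geno$snps, yy, cc, rep(c(0, 1), c(237, 3)),
                   tau1 = 3),
    "positive")
})
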