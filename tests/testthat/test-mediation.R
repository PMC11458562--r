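test_that("logistic association recovers planted odds ratios", {
  set.seed(1)
  est <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 2000
    g <- rbinom(n, 2, 0.3)
    cv <- data.frame(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5),
                     education = rnorm(n, 12, 4))
    y <- rbinom(n, 1, plogis(-0.5 + 0.5 * g + 0.02 * (cv$age - 70)))
    logistic_association(g, y, cv)$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.15)

  # allele flip gives the reciprocal odds ratio
  set.seed(2)
  n <- 800
  g <- rbinom(n, 2, 0.4)
  cv <- data.frame(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5),
                   education = rnorm(n, 12, 4))
  y <- rbinom(n, 1, plogis(-0.2 + 0.4 * g))
  r1 <- logistic_association(g, y, cv)
  r2 <- logistic_association(2 - g, y, cv)
  expect_equal(r1$or, 1 / r2$or, tolerance = 1e-6)

  expect_error(logistic_association(rep(1, 100), rbinom(100, 1, 0.5),
                                    cv[1:100, ]), "monomorphic")
  expect_error(logistic_association(g, rep(1, n), cv), "classes")
})

test_that("null-SNP association p-values are approximately uniform", {
  set.seed(3)
  n <- 1000
  cv <- data.frame(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5),
                   education = rnorm(n, 12, 4))
  y <- rbinom(n, 1, plogis(-0.3 + 0.02 * (cv$age - 70)))
  ps <- vapply(1:200, function(i) {
    logistic_association(rbinom(n, 2, 0.3), y, cv)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("effect decomposition is exact and CIs bracket the estimates", {
  d <- make_med_data(1500, a = 0.8, b = -0.15, cprime = -0.05, seed = 4)
  res <- mediate(d$g, d$m, d$y, d$covars, n_sim = 500, seed = 1)
  expect_equal(res$acme + res$ade, res$total, tolerance = 1e-12)
  expect_true(res$acme_ci[1] <= res$acme && res$acme <= res$acme_ci[2])
  expect_true(res$ade_ci[1] <= res$ade && res$ade <= res$ade_ci[2])
  expect_true(res$total_ci[1] <= res$total && res$total <= res$total_ci[2])
  # determinism under a fixed seed
  res2 <- mediate(d$g, d$m, d$y, d$covars, n_sim = 500, seed = 1)
  expect_identical(res$acme, res2$acme)
  expect_error(mediate(d$g, rep(1, 1500), d$y, d$covars), "constant")
})

test_that("continuous-mediator check mode matches product of coefficients", {
  set.seed(5)
  n <- 5000
  g <- rbinom(n, 2, 0.3)
  covars <- data.frame(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5),
                       education = rnorm(n, 12, 4),
                       icv = rnorm(n, 1450, 140))
  m <- -0.5 + 0.8 * g + rnorm(n)
  y <- 2.5 - 0.15 * m + rnorm(n, 0, 0.3)
  res <- mediate(g, m, y, covars, n_sim = 1000, seed = 2)
  expect_false(res$binary_mediator)
  expect_lt(abs(res$acme - (0.8 * -0.15)) / abs(0.8 * 0.15), 0.05)
})

test_that("planted full mediation is detected as indirect-only", {
  hits <- vapply(1:10, function(s) {
    d <- make_med_data(2000, a = 0.8, b = -0.15, cprime = 0, seed = 50 + s)
    res <- mediate(d$g, d$m, d$y, d$covars, n_sim = 400, seed = s)
    (res$acme_ci[1] > 0 || res$acme_ci[2] < 0) &&
      (res$ade_ci[1] <= 0 && res$ade_ci[2] >= 0)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the screen is deterministic and order-invariant", {
  cfg <- sim_config(n_samples = 250, n_snps = 30, n_causal = 3,
                    path_a = 0.8, path_b = -0.2, seed = 61)
  co <- simulate_cohort(cfg)
  dos <- mean_impute(co$geno$dosages)
  colnames(dos) <- co$geno$snps$id
  panel <- co$geno$snps$id[c(1, 5, 9, 13)]
  rois <- co$rois[1:2]
  s1 <- mediation_screen(dos, panel, co$pheno, rois, n_sim = 150, seed = 3)
  s2 <- mediation_screen(dos, rev(panel), co$pheno, rois, n_sim = 150,
                         seed = 3)
  expect_identical(s1$acme[panel, ], s2$acme[panel, ])
  expect_identical(s1$table, s1$table)
  expect_error(
    mediation_screen(dos, c(panel, "absent"), co$pheno, rois),
    "absent")
})

test_that("a planted mediating SNP dominates the indirect heatmap", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_samples = 600, n_snps = 30, ld_block_size = 3,
                      n_causal = 1, canonical_strength = 0,
                      path_a = 1.0, path_b = -0.25, seed = 70 + s)
    co <- simulate_cohort(cfg)
    dos <- mean_impute(co$geno$dosages)
    colnames(dos) <- co$geno$snps$id
    planted <- co$truth$causal_ids
    panel <- c(planted, co$geno$snps$id[c(5, 11, 17, 23, 29)])
    scr <- mediation_screen(dos, panel, co$pheno, co$rois[c(11, 12)],
                            n_sim = 200, seed = s)
    rowMax <- apply(abs(scr$acme), 1, max)
    names(which.max(rowMax)) == planted
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
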