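#' Elastic-net regression with repeated k-fold cross-validation
#'
#' Hyperparameters are chosen first on the training data: for each mixing
#' value in `alpha_grid`, `glmnet::cv.glmnet` (fixed fold assignment)
#' scores a log-spaced strength path, and the (alpha, lambda) pair with
#' the lowest CV error wins. The selected pair is then evaluated by
#' repeated k-fold cross-validation: per repeat, out-of-fold predictions
#' are pooled and correlated with the observed outcome; `cv_r` is the mean
#' over repeats. The final model is refit on all data.
#'
#' @param features n x f numeric matrix (no missing values).
#' @param outcome numeric n-vector.
#' @param folds folds per repeat (default 5).
#' @param repeats CV repeats (default 10).
#' @param seed RNG seed (fold assignments and glmnet internals).
#' @param alpha_grid elastic-net mixing grid.
#' @return list: `fit` (glmnet at selected lambda), `alpha`, `lambda`,
#'   `cv_r`, `r_per_repeat`.
#' @export
fit_elastic_net_cv <- function(features, outcome, folds = 5, repeats = 10,
                               seed = 1L, alpha_grid = seq(0.1, 1, by = 0.1)) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 25) stop("need at least 25 samples")
  if (stats::sd(outcome) == 0) stop("constant outcome")
  if (anyNA(features) || anyNA(outcome)) stop("missing values in input")

  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  best <- list(err = Inf)
  for (a in alpha_grid) {
    cvf <- glmnet::cv.glmnet(features, outcome, alpha = a, foldid = foldid,
                             nlambda = 50, standardize = TRUE)
    i <- which.min(cvf$cvm)
    if (cvf$cvm[i] < best$err) {
      best <- list(err = cvf$cvm[i], alpha = a, lambda = cvf$lambda[i])
    }
  }

  r_rep <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fid <- sample(rep_len(seq_len(folds), n))
    pred <- numeric(n)
    for (k in seq_len(folds)) {
      tr <- fid != k
      fit <- glmnet::glmnet(features[tr, , drop = FALSE], outcome[tr],
                            alpha = best$alpha, lambda = best$lambda,
                            standardize = TRUE)
      pred[!tr] <- as.numeric(stats::predict(
        fit, features[!tr, , drop = FALSE]))
    }
    r_rep[r] <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, outcome)
  }

  final <- glmnet::glmnet(features, outcome, alpha = best$alpha,
                          lambda = best$lambda, standardize = TRUE)
  list(fit = final, alpha = best$alpha, lambda = best$lambda,
       cv_r = mean(r_rep), r_per_repeat = r_rep)
}

fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Hittner's test for two dependent overlapping correlations
#'
#' Compares `r12` and `r13` measured on the same `n` samples with shared
#' variable 1 (Hittner, May & Silver modification of Dunn & Clark's z):
#' both correlations are Fisher-z transformed, the covariance term is the
#' Dunn-Clark expression evaluated at the back-transformed average of the
#' two z values, and
#' `z = (z12 - z13) * sqrt((n - 3) / (2 - 2*cbar))` is referred to the
#' standard normal (two-sided).
#'
#' @param r12,r13 correlations being compared (shared first variable).
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (>= 10).
#' @return list `z`, `p`.
#' @export
hittner_test <- function(r12, r13, r23, n) {
  stopifnot(n >= 10)
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("correlations must be in (-1, 1)")
  m <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("correlation triple is not positive semi-definite")
  }
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  rm <- tanh((z12 + z13) / 2)
  cbar <- (r23 * (1 - 2 * rm^2) - 0.5 * rm^2 * (1 - 2 * rm^2 - r23^2)) /
    (1 - rm^2)^2
  if (cbar >= 1) {
    stop("correlations too close to 1 for the dependent-correlation test")
  }
  z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * cbar))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare two prediction models on the same samples
#'
#' Delegates to [hittner_test()] with `r12 = cor(pred_a, y)`,
#' `r13 = cor(pred_b, y)` and `r23 = cor(pred_a, pred_b)`.
#'
#' @param pred_a,pred_b predictions from the two models.
#' @param y observed outcome.
#' @return list `z`, `p`, `r_a`, `r_b`.
#' @export
compare_models <- function(pred_a, pred_b, y) {
  if (length(pred_a) != length(y) || length(pred_b) != length(y)) {
    stop("predictions and outcome must cover the same samples")
  }
  r12 <- stats::cor(pred_a, y)
  r13 <- stats::cor(pred_b, y)
  if (isTRUE(all.equal(pred_a, pred_b))) {
    return(list(z = 0, p = 1, r_a = r12, r_b = r13))
  }
  r23 <- stats::cor(pred_a, pred_b)
  eps <- 1e-12
  clamp <- function(r) max(min(r, 1 - eps), -1 + eps)
  h <- hittner_test(clamp(r12), clamp(r13), clamp(r23), length(y))
  list(z = h$z, p = h$p, r_a = r12, r_b = r13)
}

#' Cross-group predictive validation of selected SNPs
#'
#' Two designs: train an elastic net (covariates + the training group's
#' top SNPs) on one amyloid group with repeated k-fold CV, then test on
#' every sample of the other group. Train r is the repeated-CV
#' correlation; test r is the correlation between the refit model's
#' predictions and the held-out group's outcomes. 95% CIs use the Fisher-z
#' approximation.
#'
#' @param features_fun function(ids) returning the feature matrix for a
#'   character vector of SNP IDs plus covariates, over all samples.
#' @param outcome numeric outcome over all samples.
#' @param group binary amyloid status (0/1).
#' @param top_neg,top_pos character vectors of top SNP IDs per group.
#' @param folds,repeats,seed CV controls.
#' @return data frame with one row per design: train/test r and CIs.
#' @export
cross_group_validate <- function(features_fun, outcome, group,
                                 top_neg, top_pos,
                                 folds = 5, repeats = 10, seed = 1L) {
  if (length(unique(group)) < 2) stop("both amyloid groups must be present")
  designs <- list(
    design1 = list(train = group == 0, snps = top_neg),
    design2 = list(train = group == 1, snps = top_pos))
  rows <- lapply(names(designs), function(nm) {
    d <- designs[[nm]]
    xx <- features_fun(d$snps)
    tr <- d$train
    fit <- fit_elastic_net_cv(xx[tr, , drop = FALSE], outcome[tr],
                              folds = folds, repeats = repeats, seed = seed)
    pred_te <- as.numeric(stats::predict(fit$fit, xx[!tr, , drop = FALSE]))
    r_te <- if (stats::sd(pred_te) == 0) 0 else
      stats::cor(pred_te, outcome[!tr])
    ci_tr <- fisher_ci(fit$cv_r, sum(tr))
    ci_te <- fisher_ci(r_te, sum(!tr))
    data.frame(design = nm, n_train = sum(tr), n_test = sum(!tr),
               train_r = fit$cv_r, train_lo = ci_tr[1], train_hi = ci_tr[2],
               test_r = r_te, test_lo = ci_te[1], test_hi = ci_te[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Covariate/SNP model grid within one group
#'
#' Fits the three model specifications used for biomarker prediction:
#' model 1 = covariates only (age, sex, APOE e4 count, plus ICV for the
#' thickness outcome or education for cognitive outcomes); model 2 =
#' model 1 + the group's top SNPs; model 3 = model 1 + an equal number of
#' random panel SNPs (drawn outside the top set). Model pairs are
#' compared with Hittner's test on pooled out-of-fold predictions.
#'
#' @param pheno phenotype data frame (`age`, `sex`, `apoe4`, `education`,
#'   `icv` columns).
#' @param dosage_lookup function(ids) returning a dosage matrix.
#' @param panel_ids candidate-panel SNP IDs (source of random SNPs).
#' @param top_ids the group's top SNPs.
#' @param outcome numeric outcome vector.
#' @param outcome_type `"thickness"` or `"cognitive"` (chooses ICV vs
#'   education in model 1).
#' @param folds,repeats,seed CV controls; the random-SNP draw uses
#'   `seed + 1`.
#' @return list: `summary` data frame (model, cv_r) and `comparisons`
#'   (Hittner z/p for model2 vs model1 and model2 vs model3).
#' @export
model_grid <- function(pheno, dosage_lookup, panel_ids, top_ids, outcome,
                       outcome_type = c("thickness", "cognitive"),
                       folds = 5, repeats = 10, seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  extra <- if (outcome_type == "thickness") "icv" else "education"
  covars <- as.matrix(pheno[, c("age", "sex", "apoe4", extra)])

  set.seed(seed + 1L)
  pool <- setdiff(panel_ids, top_ids)
  rand_ids <- sample(pool, min(length(top_ids), length(pool)))

  specs <- list(model1 = NULL, model2 = top_ids, model3 = rand_ids)
  oof <- list()
  fits <- list()
  for (nm in names(specs)) {
    xx <- if (is.null(specs[[nm]])) covars else
      cbind(covars, dosage_lookup(specs[[nm]]))
    fit <- fit_elastic_net_cv(xx, outcome, folds = folds, repeats = repeats,
                              seed = seed)
    # pooled out-of-fold predictions for model comparison (single split)
    set.seed(seed)
    fid <- sample(rep_len(seq_len(folds), length(outcome)))
    pred <- numeric(length(outcome))
    for (k in seq_len(folds)) {
      tr <- fid != k
      f <- glmnet::glmnet(xx[tr, , drop = FALSE], outcome[tr],
                          alpha = fit$alpha, lambda = fit$lambda,
                          standardize = TRUE)
      pred[!tr] <- as.numeric(stats::predict(f, xx[!tr, , drop = FALSE]))
    }
    oof[[nm]] <- pred
    fits[[nm]] <- fit
  }
  summary <- data.frame(
    model = names(specs),
    cv_r = vapply(fits, `[[`, numeric(1), "cv_r"),
    stringsAsFactors = FALSE, row.names = NULL)
  comparisons <- list(
    model2_vs_model1 = compare_models(oof$model2, oof$model1, outcome),
    model2_vs_model3 = compare_models(oof$model2, oof$model3, outcome))
  list(summary = summary, comparisons = comparisons, random_snps = rand_ids)
}
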