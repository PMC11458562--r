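#' Logistic association of a SNP with CU/AD diagnosis
#'
#' Additive-genotype maximum-likelihood logistic regression of case status
#' on dosage, adjusted for age, sex and education; Wald odds ratio, 95%
#' CI and p-value. MCI-stage samples are expected to be excluded upstream.
#' Complete separation is flagged and a weak ridge fallback estimate
#' (`glmnet`, alpha 0, small lambda) reported in its place.
#'
#' @param dosage numeric dosage vector.
#' @param status binary outcome (1 = case/AD, 0 = control/CU).
#' @param covars data frame or matrix with `age`, `sex`, `education`.
#' @return `association_result` list: `or`, `ci`, `p`, `beta`, `se`,
#'   `n_cases`, `n_controls`, `separation`.
#' @export
logistic_association <- function(dosage, status, covars) {
  if (length(unique(status)) < 2) stop("both outcome classes required")
  if (stats::sd(dosage, na.rm = TRUE) == 0) stop("monomorphic SNP")
  covars <- as.data.frame(covars)
  df <- data.frame(y = status, g = dosage, covars)
  df <- df[stats::complete.cases(df), ]
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  co <- summary(fit)$coefficients
  beta <- co["g", "Estimate"]
  se <- co["g", "Std. Error"]
  separation <- !fit$converged || abs(beta) > 15 || se > 100
  if (separation) {
    xx <- as.matrix(df[, -1, drop = FALSE])
    rf <- glmnet::glmnet(xx, df$y, family = "binomial", alpha = 0,
                         lambda = 0.01)
    beta <- as.numeric(stats::coef(rf))[2]
    se <- NA_real_
  }
  ci <- exp(beta + c(-1, 1) * 1.96 * se)
  out <- list(or = exp(beta), ci = ci,
              p = if (is.na(se)) NA_real_ else
                2 * stats::pnorm(-abs(beta / se)),
              beta = beta, se = se,
              n_cases = sum(df$y == 1), n_controls = sum(df$y == 0),
              separation = separation)
  class(out) <- "association_result"
  out
}

#' Causal mediation of a SNP effect through binary amyloid status
#'
#' Quasi-Bayesian potential-outcomes mediation with a logistic mediator
#' model (`M ~ SNP + covariates`) and a linear outcome model
#' (`Y ~ SNP + M + covariates`), following the simulation-based estimator
#' of the standard mediation framework: `n_sim` parameter vectors are
#' drawn from each model's asymptotic sampling distribution; for each
#' draw the average causal mediation effect is the outcome model's
#' mediator coefficient times the mean shift in mediator probability under
#' the treatment contrast (dosage `control` vs `treat`), the average
#' direct effect is the treatment coefficient, and the total effect is
#' their sum (no treatment-mediator interaction). Percentile CIs; the
#' two-sided p-value is twice the smaller tail fraction of draws crossing
#' zero.
#'
#' When the mediator is not binary, a linear mediator model is used
#' instead and the mediator-probability shift becomes the linear mediator
#' effect (product-of-coefficients check mode).
#'
#' @param dosage treatment (SNP dosage).
#' @param mediator binary amyloid status (or continuous, see above).
#' @param outcome ROI thickness.
#' @param covars covariate data frame (age, sex, education, ICV).
#' @param n_sim parameter draws (default 1000).
#' @param seed RNG seed.
#' @param control,treat treatment contrast (default one-allele increment
#'   0 -> 1).
#' @param level CI level.
#' @return `mediation_result`: `acme`, `ade`, `total`, `prop_mediated`,
#'   CIs, p-values, `n_sim`, `seed`.
#' @export
mediate <- function(dosage, mediator, outcome, covars, n_sim = 1000,
                    seed = 1L, control = 0, treat = 1, level = 0.95) {
  covars <- as.data.frame(covars)
  df <- data.frame(g = dosage, m = mediator, y = outcome, covars)
  if (anyNA(df)) {
    df <- df[stats::complete.cases(df), ]
  }
  n <- nrow(df)
  binary <- all(df$m %in% c(0, 1))
  if (binary && length(unique(df$m)) < 2) stop("mediator is constant")

  cn <- setdiff(names(df), c("g", "m", "y"))
  xm <- as.matrix(cbind(1, df$g, df[, cn, drop = FALSE]))
  xy <- as.matrix(cbind(1, df$g, df$m, df[, cn, drop = FALSE]))
  storage.mode(xm) <- "double"; storage.mode(xy) <- "double"

  mfit <- if (binary) {
    stats::glm.fit(xm, df$m, family = stats::binomial())
  } else {
    stats::lm(df$m ~ xm - 1)
  }
  ofit <- stats::lm(df$y ~ xy - 1)
  if (binary && !mfit$converged) stop("mediator model did not converge")

  if (binary) {
    w <- mfit$weights
    vm <- solve(crossprod(xm * sqrt(w)))
    cm <- mfit$coefficients
  } else {
    sm <- summary(mfit)
    cm <- stats::coef(mfit)
    vm <- sm$sigma^2 * solve(crossprod(xm))
  }
  so <- summary(ofit)
  co <- stats::coef(ofit)
  vo <- so$sigma^2 * solve(crossprod(xy))
  if (any(!is.finite(cm)) || any(!is.finite(co))) stop("degenerate model fit")

  set.seed(seed)
  thm <- MASS::mvrnorm(n_sim, cm, vm)
  tho <- MASS::mvrnorm(n_sim, co, vo)

  xm1 <- xm; xm1[, 2] <- treat
  xm0 <- xm; xm0[, 2] <- control
  if (binary) {
    shift <- colMeans(stats::plogis(xm1 %*% t(thm)) -
                        stats::plogis(xm0 %*% t(thm)))
  } else {
    shift <- thm[, 2] * (treat - control)
  }
  acme_d <- tho[, 3] * shift
  ade_d <- tho[, 2] * (treat - control)
  tot_d <- acme_d + ade_d

  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  pval <- function(d) min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  out <- list(acme = mean(acme_d), ade = mean(ade_d), total = mean(tot_d),
              prop_mediated = mean(acme_d) / mean(tot_d),
              acme_ci = stats::quantile(acme_d, qs, names = FALSE),
              ade_ci = stats::quantile(ade_d, qs, names = FALSE),
              total_ci = stats::quantile(tot_d, qs, names = FALSE),
              acme_p = pval(acme_d), ade_p = pval(ade_d),
              total_p = pval(tot_d),
              n = n, n_sim = n_sim, seed = seed, binary_mediator = binary)
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("ACME  %+0.4f [%+0.4f, %+0.4f] p=%.3f\n", x$acme,
              x$acme_ci[1], x$acme_ci[2], x$acme_p))
  cat(sprintf("ADE   %+0.4f [%+0.4f, %+0.4f] p=%.3f\n", x$ade,
              x$ade_ci[1], x$ade_ci[2], x$ade_p))
  cat(sprintf("Total %+0.4f [%+0.4f, %+0.4f] p=%.3f\n", x$total,
              x$total_ci[1], x$total_ci[2], x$total_p))
  invisible(x)
}

#' Mediation screen over a SNP panel and ROI list
#'
#' Runs [mediate()] for every (SNP, ROI) pair and assembles long-format
#' results plus direct- and indirect-effect matrices with significance
#' marks at unadjusted p < 0.05 (BH-adjusted marks are provided
#' alongside). Per-pair seeds are derived from the sorted SNP/ROI names,
#' so results do not depend on input ordering.
#'
#' @param dosages dosage matrix with SNP-ID column names.
#' @param panel character vector of SNP IDs to screen.
#' @param pheno phenotype data frame holding mediator, covariates and ROI
#'   columns.
#' @param rois character vector of ROI column names.
#' @param covar_cols covariate column names (default age, sex, education,
#'   icv).
#' @param mediator_col mediator column (default `abeta`).
#' @param n_sim draws per pair.
#' @param seed base seed.
#' @return list: `table` (long format), `ade`, `acme`, `ade_p`, `acme_p`
#'   matrices (SNP x ROI), `ade_star`, `acme_star` significance markers.
#' @export
mediation_screen <- function(dosages, panel, pheno, rois,
                             covar_cols = c("age", "sex", "education", "icv"),
                             mediator_col = "abeta", n_sim = 1000,
                             seed = 1L) {
  if (!all(panel %in% colnames(dosages))) {
    stop("panel SNPs missing from genotype data: ",
         paste(setdiff(panel, colnames(dosages)), collapse = ", "))
  }
  snp_rank <- match(panel, sort(panel))
  roi_rank <- match(rois, sort(rois))
  covars <- pheno[, covar_cols, drop = FALSE]
  med <- pheno[[mediator_col]]

  rows <- vector("list", length(panel) * length(rois))
  k <- 0L
  for (i in seq_along(panel)) {
    for (j in seq_along(rois)) {
      pair_seed <- (seed + 7919L * snp_rank[i] + 131L * roi_rank[j]) %%
        2147483647L
      res <- mediate(dosages[, panel[i]], med, pheno[[rois[j]]], covars,
                     n_sim = n_sim, seed = pair_seed)
      k <- k + 1L
      rows[[k]] <- data.frame(
        snp = panel[i], roi = rois[j], acme = res$acme, ade = res$ade,
        total = res$total, prop_mediated = res$prop_mediated,
        acme_lo = res$acme_ci[1], acme_hi = res$acme_ci[2],
        ade_lo = res$ade_ci[1], ade_hi = res$ade_ci[2],
        acme_p = res$acme_p, ade_p = res$ade_p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$acme_q <- stats::p.adjust(tab$acme_p, method = "BH")
  tab$ade_q <- stats::p.adjust(tab$ade_p, method = "BH")

  shape <- function(col) {
    out <- t(matrix(tab[[col]], length(rois), length(panel)))
    dimnames(out) <- list(panel, rois)
    out
  }
  list(table = tab,
       ade = shape("ade"), acme = shape("acme"),
       ade_p = shape("ade_p"), acme_p = shape("acme_p"),
       ade_star = shape("ade_p") < 0.05,
       acme_star = shape("acme_p") < 0.05,
       ade_star_bh = shape("ade_q") < 0.05,
       acme_star_bh = shape("acme_q") < 0.05)
}
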