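#!/usr/bin/env Rscript
# Predictive validation of the selected SNPs. Design 1/2: elastic net on
# one amyloid group's top-10 SNPs (repeated 5-fold CV x10), tested on the
# other group. Then the three-model grid per group (covariates; + top-10
# SNPs; + 10 random panel SNPs) for thickness, MMSE and CDR-SB, with
# Hittner's dependent-correlation comparisons.
source("analysis/common.R")

dat <- load_cohort_files()
wt <- utils::read.delim(file.path(OUT_DIR, "scca_weights.tsv"),
                        comment.char = "#")
panel <- utils::read.delim(file.path(OUT_DIR, "panel.tsv"),
                           comment.char = "#")
top_neg <- wt$id[wt$group == "negative"]
top_pos <- wt$id[wt$group == "positive"]
dos <- mean_impute(dat$geno$dosages)
colnames(dos) <- dat$geno$snps$id
rois <- rois_of(dat$pheno)
thick <- rowMeans(dat$pheno[, grep("^global", rois, value = TRUE)])

cg <- cross_group_validate(function(ids) dos[, ids, drop = FALSE],
                           thick, dat$pheno$abeta, top_neg, top_pos,
                           folds = 5, repeats = 10, seed = SEED)
print(cg)
write_result(cg, "validation_cross_group.tsv")

rows <- list()
for (grp in c("negative", "positive")) {
  sel <- dat$pheno$abeta == (grp == "positive")
  tops <- if (grp == "negative") top_neg else top_pos
  for (oc in c("thickness", "mmse", "cdr_sb")) {
    y <- if (oc == "thickness") thick[sel] else dat$pheno[[oc]][sel]
    mg <- model_grid(dat$pheno[sel, ], function(ids) dos[sel, ids],
                     panel$snp, tops, y,
                     outcome_type = if (oc == "thickness") "thickness"
                     else "cognitive",
                     folds = 5, repeats = 10, seed = SEED)
    df <- cbind(group = grp, outcome = oc, mg$summary)
    df$p_vs_model1 <- ifelse(df$model == "model2",
                             mg$comparisons$model2_vs_model1$p, NA)
    df$p_vs_model3 <- ifelse(df$model == "model2",
                             mg$comparisons$model2_vs_model3$p, NA)
    rows[[length(rows) + 1L]] <- df
    message(sprintf("%s/%s: r = %.2f / %.2f / %.2f (models 1-3)",
                    grp, oc, df$cv_r[1], df$cv_r[2], df$cv_r[3]))
  }
}
write_result(do.call(rbind, rows), "validation_models.tsv")
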