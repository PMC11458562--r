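# igscca

Group-wise sparse canonical correlation analysis (SCCA) for imaging
genetics: an R package plus a numbered analysis workflow that links a
panel of candidate SNP dosages to covariate-adjusted cortical-thickness
phenotypes, separately within amyloid-negative and amyloid-positive
strata, and then validates and interprets the selected variants.

## Who this is for

Biostatisticians and imaging-genetics researchers who want a tested,
fully reproducible implementation of the following analysis chain
without any access to restricted cohort data:

1. **Genotype QC** — sample call rate, heterozygosity outliers,
   identity-by-descent (method-of-moments PI_HAT), marker call rate,
   MAF, exact Hardy-Weinberg test, imputation INFO filter, with an
   auditable removal report.
2. **Candidate selection** — summary-statistic filtering (p < 1e-4) and
   greedy LD clumping to a near-uncorrelated index panel.
3. **Sparse CCA** — rank-1 solver for
   max u'X'Yv s.t. ||u||2 = ||v||2 = 1, ||u||1 <= tau1, ||v||1 <= tau2,
   with exact L1-ball/L2-sphere projections, run per amyloid group and
   pooled; top-10 SNPs by |canonical weight|.
4. **Predictive validation** — elastic net with repeated 5-fold CV
   (x10), cross-group transfer designs, a three-model covariate/SNP
   grid, and Hittner's test for dependent overlapping correlations.
5. **Mediation** — quasi-Bayesian potential-outcomes estimation of each
   SNP's direct and amyloid-mediated effect on every ROI.
6. **Enrichment** — local Fisher-exact gene-set over-representation
   with BH q-values against GMT collections.

A synthetic-cohort generator (`simulate_cohort()`) with planted
canonical and mediation signals defines the reference conditions every
stage is tested under; see `vignettes/igscca-methods.Rmd` for the model,
parameter choices and limitations.

## Worked example

```r
library(igscca)

cfg <- sim_config(seed = 20260926)   # 1125 samples, 344 SNPs, 12 ROIs
cohort <- simulate_cohort(cfg)

dos <- mean_impute(cohort$geno$dosages)
colnames(dos) <- cohort$geno$snps$id
res <- groupwise_scca(
  dos, cohort$geno$snps,
  as.matrix(cohort$pheno[, cohort$rois]),
  as.matrix(cohort$pheno[, c("age", "sex", "education", "icv")]),
  cohort$pheno$abeta, tau1 = 4, top_k = 10)
print(res)
#> [negative] rho = 0.582, top SNPs: snp0037, snp0073, snp0149, ...
#> [positive] rho = 0.578, top SNPs: snp0037, snp0149, snp0073, ...
#> [total]    rho = 0.575, top SNPs: snp0037, snp0149, snp0073, ...

sum(res$negative$top$id %in% cohort$truth$causal_ids)
#> [1] 8
```

The canonical correlation per group is the sample correlation of the
two projections `Xu` and `Yv`; with the default generator the planted
(population) value is 0.50 and the fitted value lands near 0.58 —
sparse fitting inflates it at p = 344. The top-10 list recovers 8 of
the 10 planted causal SNPs in this cohort; `cohort$truth` carries the
ground truth for such checks.

The full analysis is organised as numbered drivers that write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # synthetic study cohort + companions
Rscript analysis/02_qc.R         # QC audit trail
Rscript analysis/03_select.R     # p-filter + LD clumping (311 index SNPs)
Rscript analysis/04_scca.R       # group-wise SCCA, top-10 per group
Rscript analysis/05_validate.R   # cross-group + three-model elastic nets
Rscript analysis/06_mediation.R  # CU/AD association + mediation screen
Rscript analysis/07_enrichment.R # Fisher gene-set over-representation
```

For example, `05_validate.R` prints the per-group model grid
(model 1 = covariates, 2 = + top-10 SNPs, 3 = + 10 random SNPs):

```
negative/thickness: r = 0.41 / 0.45 / 0.39 (models 1-3)
positive/thickness: r = 0.36 / 0.43 / 0.34 (models 1-3)
```

and `07_enrichment.R` finds the planted causal pathway as the only
set at q < 0.05 (p = 2.1e-07 in the amyloid-negative group). A
one-command end-to-end run on a compact cohort is
`run_demo(out_dir, seed)`; it is byte-reproducible under a fixed seed.

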