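#!/usr/bin/env Rscript
# Build the synthetic study cohort: genotypes with block LD, demographics,
# amyloid status, ROI thickness with a planted rank-1 canonical signal,
# cognition, companion summary statistics, SNP->gene annotation and gene
# sets. Everything downstream reads the files written here.
source("analysis/common.R")

cfg <- study_config()
cohort <- simulate_cohort(cfg)
cohort$sumstats <- simulate_summary_stats(cfg, cohort$truth, cohort$geno)
cohort$annotation <- simulate_annotation(cohort$geno, cohort$truth, cfg)
cohort$gene_sets <- simulate_gene_sets(cohort$annotation, cohort$truth,
                                       seed = SEED)
paths <- write_fixture(cohort, DATA_DIR)

message(sprintf("cohort: %d samples, %d SNPs, %d ROIs",
                nrow(cohort$pheno), ncol(cohort$geno$dosages),
                length(cohort$rois)))
message(sprintf("amyloid-positive fraction: %.3f (target 0.575)",
                mean(cohort$pheno$abeta)))
message(sprintf("planted canonical correlation: %.2f",
                cohort$truth$planted_rho))
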