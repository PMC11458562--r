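#!/usr/bin/env Rscript
# Genotype quality control: sample call rate, heterozygosity, then marker
# call rate, MAF, exact HWE and imputation INFO. The relatedness (PI_HAT)
# filter needs genome-wide marker density: at the 344-SNP candidate panel
# the method-of-moments estimator's sampling noise swamps the 0.125
# threshold, so it is disabled here (the demo pipeline and the test suite
# exercise it on denser panels, p >= 2000). The synthetic cohort is clean
# by construction, so removals should be zero; the point is the audit
# trail.
source("analysis/common.R")

dat <- load_cohort_files()
res <- apply_qc(dat$geno, qc_thresholds(ibd_pihat_max = 1))
print(res$report)
write_result(res$report$table, "qc_report.tsv")
message(sprintf("retained %d samples and %d markers",
                nrow(res$geno$dosages), ncol(res$geno$dosages)))
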