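#!/usr/bin/env Rscript
# Candidate selection: p < 1e-4 filter on the companion summary statistics
# followed by greedy LD clumping (r2 >= 0.1 within 250 kb), yielding the
# near-uncorrelated SNP panel the sparse CCA runs on.
source("analysis/common.R")

dat <- load_cohort_files()
panel <- clump(dat$geno, dat$sumstats, 1e-4, 0.1, 250)
print(panel)
hits <- intersect(panel$index_snps, dat$truth$causal_ids)
message(sprintf("panel of %d index SNPs keeps %d/%d planted causal SNPs",
                length(panel$index_snps), length(hits),
                length(dat$truth$causal_ids)))
write_result(data.frame(snp = panel$index_snps,
                        n_members = unname(lengths(panel$clumps))),
             "panel.tsv")
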