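#!/usr/bin/env Rscript
# Gene-set over-representation of the per-group top-10 SNPs' genes against
# the synthetic GMT collection: one-sided Fisher exact tests with
# Haldane-Anscombe odds ratios and Benjamini-Hochberg q-values.
source("analysis/common.R")

dat <- load_cohort_files()
wt <- utils::read.delim(file.path(OUT_DIR, "scca_weights.tsv"),
                        comment.char = "#")
for (grp in c("negative", "positive")) {
  genes <- map_snps_to_genes(wt$id[wt$group == grp], dat$annotation)
  er <- fisher_enrichment(genes, dat$gene_sets,
                          universe = unique(dat$annotation$gene))
  write_result(er, sprintf("enrichment_%s.tsv", grp))
  top <- er[er$q < 0.05, ]
  message(sprintf("%s group: %d sets at q < 0.05; best: %s (p = %.2e)",
                  grp, nrow(top), er$term[1], er$p[1]))
}
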