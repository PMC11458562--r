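# Shared settings for the numbered analysis scripts. Each script is a thin
# driver over the igscca package: run them in order from the repository
# root, e.g.  Rscript analysis/01_simulate.R
library(igscca)

SEED <- 20260926L
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)

# study-scale synthetic cohort: 1125 participants, 344 candidate SNPs,
# 12 cortical-thickness ROIs, planted canonical correlation 0.5
study_config <- function(seed = SEED) sim_config(seed = seed)

stamp <- function() sprintf("analysis seed=%d", SEED)

load_cohort_files <- function() {
  geno <- read_plink(file.path(DATA_DIR, "geno"))
  info <- utils::read.delim(file.path(DATA_DIR, "geno.info.tsv"))
  geno$snps$info_r2 <- info$info_r2[match(geno$snps$id, info$id)]
  list(
    geno = geno,
    pheno = utils::read.delim(file.path(DATA_DIR, "pheno.tsv")),
    sumstats = utils::read.delim(file.path(DATA_DIR, "sumstats.tsv")),
    annotation = utils::read.delim(file.path(DATA_DIR, "annotation.tsv")),
    gene_sets = read_gmt(file.path(DATA_DIR, "sets.gmt")),
    truth = jsonlite::read_json(file.path(DATA_DIR, "truth.json"),
                                simplifyVector = TRUE))
}

rois_of <- function(pheno) grep("_(l|r)$", names(pheno), value = TRUE)

write_result <- function(df, name) {
  con <- file(file.path(OUT_DIR, name), "w")
  writeLines(paste0("# ", stamp()), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  message("wrote ", file.path(OUT_DIR, name))
}
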