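#' Pairwise LD as squared dosage correlation
#'
#' Composite LD: squared Pearson correlation between two dosage columns
#' over their non-missing overlap.
#'
#' @param g1,g2 dosage vectors.
#' @return r2 in `[0, 1]`, or `NA` when either SNP is monomorphic in the
#'   overlap.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(g1[ok]) == 0 || stats::sd(g2[ok]) == 0) return(NA_real_)
  stats::cor(g1[ok], g2[ok])^2
}

#' Filter SNPs by summary-statistic p-value
#'
#' Keeps SNPs with p strictly below the threshold, restricted to those
#' present in the genotype panel.
#'
#' @param stats_df data frame with columns `snp` and `p`.
#' @param threshold p-value threshold (default 1e-4).
#' @param panel_ids SNP IDs present in the genotype panel.
#' @return character vector of passing SNP IDs (panel order).
#' @export
filter_by_pvalue <- function(stats_df, threshold = 1e-4, panel_ids = NULL) {
  stopifnot(nrow(stats_df) > 0, all(c("snp", "p") %in% names(stats_df)))
  if (anyDuplicated(stats_df$snp)) stop("duplicate SNP IDs in summary stats")
  if (any(stats_df$p <= 0 | stats_df$p > 1)) stop("p-values must be in (0, 1]")
  pass <- stats_df$snp[stats_df$p < threshold]
  if (!is.null(panel_ids)) pass <- intersect(panel_ids, pass)
  pass
}

#' Greedy LD clumping of summary statistics
#'
#' PLINK-style clumping: among SNPs passing the p-value filter, iterate in
#' ascending p (ties broken by chromosome, position, then ID); each
#' unassigned SNP becomes an index SNP and absorbs all unassigned passing
#' SNPs on the same chromosome within `window_kb` whose dosage r2 with it
#' is at least `r2_threshold`.
#'
#' @param geno genotype list.
#' @param stats_df summary statistics (`snp`, `chrom`, `pos`, `p`).
#' @param p_threshold association p-value cutoff (default 1e-4).
#' @param r2_threshold LD r2 above which a SNP is absorbed (default 0.1).
#' @param window_kb clump window half-width in kb (default 250).
#' @return `candidate_panel` list: `index_snps` (ordered by p) and
#'   `clumps` (index SNP -> absorbed members).
#' @export
clump <- function(geno, stats_df, p_threshold = 1e-4, r2_threshold = 0.1,
                  window_kb = 250) {
  pass <- filter_by_pvalue(stats_df, p_threshold, geno$snps$id)
  if (length(pass) == 0) {
    out <- list(index_snps = character(0), clumps = list())
    class(out) <- "candidate_panel"
    return(out)
  }
  st <- stats_df[match(pass, stats_df$snp), ]
  ord <- order(st$p, st$chrom, st$pos, st$snp)
  st <- st[ord, ]

  unassigned <- stats::setNames(rep(TRUE, nrow(st)), st$snp)
  gcol <- match(st$snp, geno$snps$id)
  index_snps <- character(0)
  clumps <- list()
  for (i in seq_len(nrow(st))) {
    id <- st$snp[i]
    if (!unassigned[[id]]) next
    unassigned[[id]] <- FALSE
    index_snps <- c(index_snps, id)
    near <- which(unassigned & st$chrom == st$chrom[i] &
                    abs(st$pos - st$pos[i]) <= window_kb * 1000)
    members <- character(0)
    for (j in near) {
      r2 <- ld_r2(geno$dosages[, gcol[i]], geno$dosages[, gcol[j]])
      if (!is.na(r2) && r2 >= r2_threshold) {
        members <- c(members, st$snp[j])
        unassigned[[st$snp[j]]] <- FALSE
      }
    }
    clumps[[id]] <- members
  }
  out <- list(index_snps = index_snps, clumps = clumps)
  class(out) <- "candidate_panel"
  out
}

#' @export
print.candidate_panel <- function(x, ...) {
  cat(sprintf("Candidate panel: %d index SNPs, %d clumped members\n",
              length(x$index_snps), sum(lengths(x$clumps))))
  invisible(x)
}
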