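#' Per-sample and per-marker genotype call rates
#'
#' @param dosages samples x SNPs dosage matrix, `NA` = missing call.
#' @return list with `sample` and `marker` rate vectors in `[0, 1]`.
#' @export
call_rates <- function(dosages) {
  if (is.null(dim(dosages)) || nrow(dosages) == 0 || ncol(dosages) == 0) {
    stop("empty genotype matrix")
  }
  obs <- !is.na(dosages)
  list(sample = rowMeans(obs), marker = colMeans(obs))
}

#' Heterozygosity-outlier samples
#'
#' Flags samples whose heterozygous-call fraction deviates from the cohort
#' mean by more than `sd_mult` standard deviations. The excess-only variant
#' (`one_sided = TRUE`) flags only above-mean deviations.
#'
#' @param dosages dosage matrix.
#' @param sd_mult standard-deviation multiplier (default 5).
#' @param one_sided flag only excess heterozygosity.
#' @param sample_ids optional IDs; defaults to row index.
#' @return character vector of flagged sample IDs (empty when the
#'   heterozygosity rate has zero variance).
#' @export
heterozygosity_outliers <- function(dosages, sd_mult = 5, one_sided = FALSE,
                                    sample_ids = NULL) {
  if (nrow(dosages) < 2) stop("need at least two samples")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(dosages)))
  het <- rowMeans(dosages == 1, na.rm = TRUE)
  s <- stats::sd(het)
  if (!is.finite(s) || s == 0) return(character(0))
  dev <- (het - mean(het)) / s
  flagged <- if (one_sided) dev > sd_mult else abs(dev) > sd_mult
  sample_ids[flagged]
}

#' Minor allele frequency per SNP
#'
#' `min(f, 1 - f)` with `f` the A1-allele frequency among non-missing
#' calls; all-missing columns return `NA`.
#'
#' @param dosages dosage matrix or single column.
#' @return numeric vector of MAFs.
#' @export
minor_allele_freq <- function(dosages) {
  d <- as.matrix(dosages)
  f <- colMeans(d, na.rm = TRUE) / 2
  unname(pmin(f, 1 - f))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the allele counts, sums the probabilities
#' of all heterozygote counts whose conditional probability does not
#' exceed that of the observed count (no mid-p correction). Probabilities
#' are evaluated in log space and normalized, so large samples stay
#' numerically stable.
#'
#' @param n_aa count of A1/A1 homozygotes.
#' @param n_ab heterozygote count.
#' @param n_bb count of A2/A2 homozygotes.
#' @return two-sided exact p-value in `[0, 1]`.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("negative genotype counts")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("no genotyped samples")
  na <- 2 * n_aa + n_ab          # A1 allele count
  r <- min(na, 2 * n - na)       # rarer allele count
  if (r == 0) return(1)
  hets <- seq(r %% 2, r, by = 2)
  # log P(het = h | n, allele counts), up to a shared constant
  logp <- lfactorial(n) - lfactorial((na - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (na + hets) / 2) + hets * log(2)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Per-locus expected identity-by-state probabilities given IBD state,
# from the observed allele counts x (A1) and y (A2) with hypergeometric
# (without-replacement) finite-sample correction, as in the PLINK
# method-of-moments genome procedure.
ibs_expectations <- function(x, y) {
  t4 <- (x + y) * (x + y - 1) * (x + y - 2) * (x + y - 3)
  t3 <- (x + y) * (x + y - 1) * (x + y - 2)
  list(
    e00 = 2 * x * (x - 1) * y * (y - 1) / t4,
    e10 = (4 * x * (x - 1) * (x - 2) * y + 4 * x * y * (y - 1) * (y - 2)) / t4,
    e20 = (x * (x - 1) * (x - 2) * (x - 3) + y * (y - 1) * (y - 2) * (y - 3) +
             4 * x * (x - 1) * y * (y - 1)) / t4,
    e11 = (2 * x * (x - 1) * y + 2 * x * y * (y - 1)) / t3,
    e21 = (x * (x - 1) * (x - 2) + y * (y - 1) * (y - 2) +
             x * (x - 1) * y + x * y * (y - 1)) / t3)
}

#' Pairwise identity-by-descent (PI_HAT)
#'
#' Method-of-moments relatedness estimate: identity-by-state counts per
#' sample pair are compared with their expectations under IBD states 0/1/2
#' at the sample allele frequencies, giving `PI_HAT = P(IBD=2) +
#' 0.5 P(IBD=1)`, clipped to `[0, 1]`. Only loci with complete calls
#' across the current samples enter the calculation; monomorphic loci are
#' dropped.
#'
#' @param dosages dosage matrix.
#' @param sample_ids optional IDs for dimnames.
#' @return symmetric PI_HAT matrix with unit diagonal.
#' @export
ibd_pihat <- function(dosages, sample_ids = NULL) {
  n <- nrow(dosages)
  if (n < 2) stop("need at least two samples")
  complete <- colSums(is.na(dosages)) == 0
  d <- dosages[, complete, drop = FALSE]
  f <- colMeans(d) / 2
  poly <- f > 0 & f < 1
  d <- d[, poly, drop = FALSE]
  if (ncol(d) == 0) stop("no polymorphic complete markers for IBD")

  a0 <- (d == 0) * 1; a1 <- (d == 1) * 1; a2 <- (d == 2) * 1
  ibs2 <- tcrossprod(a0) + tcrossprod(a1) + tcrossprod(a2)
  ibs0 <- tcrossprod(a0, a2) + tcrossprod(a2, a0)
  ibs1 <- ncol(d) - ibs2 - ibs0

  e <- ibs_expectations(colSums(d), 2 * nrow(d) - colSums(d))
  s00 <- sum(e$e00); s10 <- sum(e$e10); s20 <- sum(e$e20)
  s11 <- sum(e$e11); s21 <- sum(e$e21)
  nl <- ncol(d)

  clip01 <- function(m) pmin(pmax(m, 0), 1)
  p0 <- clip01(ibs0 / s00)
  p1 <- clip01((ibs1 - p0 * s10) / s11)
  p2 <- clip01((ibs2 - p0 * s20 - p1 * s21) / nl)
  pihat <- clip01(p2 + 0.5 * p1)
  diag(pihat) <- 1
  if (!is.null(sample_ids)) dimnames(pihat) <- list(sample_ids, sample_ids)
  pihat
}

#' QC thresholds
#'
#' Defaults follow standard array-genotyping practice: sample call rate
#' >= 0.95, heterozygosity within 5 SD, PI_HAT < 0.125, marker call rate
#' >= 0.98, MAF >= 0.01, HWE exact p >= 1e-6 and post-imputation INFO
#' r2 > 0.8.
#'
#' @param sample_call_rate_min,het_sd_mult,ibd_pihat_max,marker_call_rate_min,maf_min,hwe_p_min,info_r2_min filter thresholds.
#' @param het_one_sided flag only excess heterozygosity.
#' @return validated `qc_thresholds` list.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.95, het_sd_mult = 5,
                          ibd_pihat_max = 0.125, marker_call_rate_min = 0.98,
                          maf_min = 0.01, hwe_p_min = 1e-6,
                          info_r2_min = 0.8, het_one_sided = FALSE) {
  th <- list(sample_call_rate_min = sample_call_rate_min,
             het_sd_mult = het_sd_mult, ibd_pihat_max = ibd_pihat_max,
             marker_call_rate_min = marker_call_rate_min, maf_min = maf_min,
             hwe_p_min = hwe_p_min, info_r2_min = info_r2_min,
             het_one_sided = het_one_sided)
  stopifnot(sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            marker_call_rate_min >= 0, marker_call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5, hwe_p_min >= 0, hwe_p_min <= 1,
            het_sd_mult > 0, ibd_pihat_max >= 0, ibd_pihat_max <= 1)
  class(th) <- "qc_thresholds"
  th
}

hwe_pvalues <- function(dosages) {
  apply(dosages, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(NA_real_)
    hwe_exact_test(sum(col == 2), sum(col == 1), sum(col == 0))
  })
}

#' Apply the full genotype QC chain
#'
#' Sample filters run first (call rate, heterozygosity, relatedness), then
#' marker filters on the surviving samples (call rate, MAF, HWE, INFO r2).
#' For each related pair above the PI_HAT threshold the member with the
#' lower call rate is dropped (ties: lexicographically smaller ID),
#' iterating until no pair remains. Every removal is recorded with its
#' stage and the offending value.
#'
#' @param geno genotype list (`dosages`, `sample_ids`, `snps`).
#' @param thresholds a [qc_thresholds()].
#' @return list `geno` (filtered) and `report` (`qc_report`: per-stage ID
#'   lists, counts, and a long-format table).
#' @export
apply_qc <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  d <- geno$dosages
  sid <- geno$sample_ids
  snps <- geno$snps
  rows <- list()
  note <- function(stage, entity, ids, values) {
    if (length(ids) == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, entity = entity, id = ids, value = values,
      stringsAsFactors = FALSE)
  }

  # --- sample stage -------------------------------------------------------
  cr <- call_rates(d)$sample
  drop_cr <- sid[cr < thresholds$sample_call_rate_min]
  note("sample_call_rate", "sample", drop_cr,
       cr[match(drop_cr, sid)])
  keep <- !(sid %in% drop_cr)
  d <- d[keep, , drop = FALSE]; sid <- sid[keep]

  drop_het <- heterozygosity_outliers(d, thresholds$het_sd_mult,
                                      thresholds$het_one_sided, sid)
  het <- rowMeans(d == 1, na.rm = TRUE)
  note("heterozygosity", "sample", drop_het, het[match(drop_het, sid)])
  keep <- !(sid %in% drop_het)
  d <- d[keep, , drop = FALSE]; sid <- sid[keep]

  drop_ibd <- character(0)
  if (nrow(d) >= 2 && thresholds$ibd_pihat_max < 1) {
    pihat <- ibd_pihat(d, sid)
    cr_now <- call_rates(d)$sample
    names(cr_now) <- sid
    active <- sid
    repeat {
      sub <- pihat[active, active, drop = FALSE]
      over <- which(sub >= thresholds$ibd_pihat_max & upper.tri(sub),
                    arr.ind = TRUE)
      if (nrow(over) == 0) break
      # handle the worst pair first for determinism
      vals <- sub[over]
      o <- order(-vals, over[, 1], over[, 2])
      i <- active[over[o[1], 1]]; j <- active[over[o[1], 2]]
      victim <- if (cr_now[i] < cr_now[j]) i
      else if (cr_now[j] < cr_now[i]) j
      else min(i, j)
      note("ibd", "sample", victim, sub[over[o[1], 1], over[o[1], 2]])
      drop_ibd <- c(drop_ibd, victim)
      active <- setdiff(active, victim)
    }
    keep <- !(sid %in% drop_ibd)
    d <- d[keep, , drop = FALSE]; sid <- sid[keep]
  }
  if (nrow(d) == 0) stop("all samples removed by QC")

  # --- marker stage -------------------------------------------------------
  mcr <- call_rates(d)$marker
  drop_mcr <- snps$id[mcr < thresholds$marker_call_rate_min]
  note("marker_call_rate", "marker", drop_mcr, mcr[match(drop_mcr, snps$id)])
  keep <- !(snps$id %in% drop_mcr)
  d <- d[, keep, drop = FALSE]; snps <- snps[keep, , drop = FALSE]

  maf <- minor_allele_freq(d)
  drop_maf <- snps$id[is.na(maf) | maf < thresholds$maf_min]
  note("maf", "marker", drop_maf, maf[match(drop_maf, snps$id)])
  keep <- !(snps$id %in% drop_maf)
  d <- d[, keep, drop = FALSE]; snps <- snps[keep, , drop = FALSE]

  hwe <- hwe_pvalues(d)
  drop_hwe <- snps$id[hwe < thresholds$hwe_p_min]
  note("hwe", "marker", drop_hwe, hwe[match(drop_hwe, snps$id)])
  keep <- !(snps$id %in% drop_hwe)
  d <- d[, keep, drop = FALSE]; snps <- snps[keep, , drop = FALSE]

  drop_info <- character(0)
  if (!is.null(snps$info_r2)) {
    bad <- !is.na(snps$info_r2) & snps$info_r2 <= thresholds$info_r2_min
    drop_info <- snps$id[bad]
    note("info_r2", "marker", drop_info, snps$info_r2[bad])
    d <- d[, !bad, drop = FALSE]; snps <- snps[!bad, , drop = FALSE]
  }
  if (ncol(d) == 0) stop("all markers removed by QC")

  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(0), entity = character(0),
               id = character(0), value = numeric(0))
  removed <- list(sample_call_rate = drop_cr, heterozygosity = drop_het,
                  ibd = drop_ibd, marker_call_rate = drop_mcr,
                  maf = drop_maf, hwe = drop_hwe, info_r2 = drop_info)
  report <- list(removed = removed,
                 counts = vapply(removed, length, integer(1)),
                 table = table)
  class(report) <- "qc_report"

  list(geno = list(dosages = d, sample_ids = sid, snps = snps),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-18s removed %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
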