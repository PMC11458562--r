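# Shared fixture builders; everything is generated in code at test time.

# Genotype fixture with planted QC violations. Counts by stage:
# 3 low-call-rate samples, 1 heterozygosity outlier, 1 duplicate pair,
# 5 MAF<1% markers, 2 HWE-violating markers, 4 poor-INFO markers.
make_qc_fixture <- function(n = 100, p = 5000, seed = 9) {
  set.seed(seed)
  maf <- stats::runif(p, 0.2, 0.45)
  d <- sapply(maf, function(f) stats::rbinom(n, 2, f))
  ids <- sprintf("S%03d", seq_len(n))
  for (i in 1:3) d[i, sample(p, p / 2)] <- NA      # low call rate
  d[10, ] <- 1L                                    # heterozygosity outlier
  d[21, ] <- d[20, ]                               # duplicate pair
  d[, 1:5] <- 0L                                   # monomorphic (MAF 0)
  d[, 6:7] <- 1L                                   # all-het (HWE violation)
  d[10, 1:7] <- c(rep(0L, 5), 1L, 1L)
  d[21, 1:7] <- d[20, 1:7]
  snps <- data.frame(id = sprintf("m%04d", seq_len(p)), chrom = 1L,
                     pos = seq_len(p) * 1000L, a1 = "A", a2 = "G",
                     info_r2 = 1.0, stringsAsFactors = FALSE)
  snps$info_r2[8:11] <- 0.5                        # poor imputation quality
  list(geno = list(dosages = d, sample_ids = ids, snps = snps),
       expected = c(sample_call_rate = 3L, heterozygosity = 1L, ibd = 1L,
                    marker_call_rate = 0L, maf = 5L, hwe = 2L, info_r2 = 4L))
}

# Small random instance whose columns are whitened (empirical within-set
# covariance = identity), so the unconstrained rank-1 cross-product
# solution coincides with the first classical canonical correlation.
make_whitened_instance <- function(n, p, q, seed) {
  set.seed(seed)
  x <- scale(matrix(stats::rnorm(n * p), n, p), scale = FALSE)
  y <- scale(matrix(stats::rnorm(n * q), n, q), scale = FALSE)
  list(x = qr.Q(qr(x)) * sqrt(n - 1), y = qr.Q(qr(y)) * sqrt(n - 1))
}

# Exact HWE p-value by direct enumeration with explicit combinatorial
# weights (independent of the package's normalized log-space recurrence).
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n - na
  r <- min(na, nb)
  if (r == 0) return(1)
  hets <- seq(r %% 2, r, by = 2)
  w <- vapply(hets, function(h) {
    exp(lchoose(n, (na - h) / 2) + lchoose(n - (na - h) / 2, h) +
          h * log(2) - (lchoose(2 * n, na)))
  }, numeric(1))
  w <- w / sum(w)
  obs <- w[hets == n_ab]
  sum(w[w <= obs * (1 + 1e-12)])
}

# One-sided hypergeometric tail by direct summation, as an enrichment
# oracle independent of fisher.test.
hyper_tail_oracle <- function(a, set_size, query_size, universe_size) {
  hi <- min(set_size, query_size)
  sum(stats::dhyper(a:hi, set_size, universe_size - set_size, query_size))
}

# Two-group cohort sharing one SNP panel but with disjoint planted causal
# sets; group membership doubles as amyloid status. The within-group
# canonical correlation is planted at ~0.75 (strength 0.34 at noise 0.3),
# emulating the strong within-group predictive signal of the study design
# this scenario reproduces.
make_disjoint_groups <- function(n_per_group = 250, n_snps = 344,
                                 seed = 1, strength = 0.34) {
  cfg_a <- sim_config(n_samples = n_per_group, n_snps = n_snps,
                      canonical_strength = strength,
                      path_a = 0, path_b = 0, seed = seed)
  cfg_b <- sim_config(n_samples = n_per_group, n_snps = n_snps,
                      canonical_strength = strength,
                      path_a = 0, path_b = 0, seed = seed + 5000L)
  blocks <- igscca:::causal_snp_indices(cfg_a)
  set_a <- blocks
  bs <- cfg_a$ld_block_size  # neighbouring block: disjoint and uncorrelated
  set_b <- ifelse(blocks + bs <= n_snps, blocks + bs, blocks - bs)
  coh_a <- simulate_cohort(cfg_a, causal_indices = set_a)
  coh_b <- simulate_cohort(cfg_b, causal_indices = set_b)
  dos <- rbind(mean_impute(coh_a$geno$dosages), mean_impute(coh_b$geno$dosages))
  colnames(dos) <- coh_a$geno$snps$id
  pheno <- rbind(coh_a$pheno, coh_b$pheno)
  pheno$abeta <- rep(c(0L, 1L), each = n_per_group)
  list(dosages = dos, snps = coh_a$geno$snps, pheno = pheno,
       rois = coh_a$rois, causal_a = set_a, causal_b = set_b,
       causal_ids_a = coh_a$geno$snps$id[set_a],
       causal_ids_b = coh_a$geno$snps$id[set_b])
}

scca_inputs <- function(cohort) {
  xs <- standardize_columns(mean_impute(cohort$geno$dosages))
  colnames(xs) <- cohort$geno$snps$id
  y <- residualize(as.matrix(cohort$pheno[, cohort$rois]),
                   as.matrix(cohort$pheno[, c("age", "sex", "education",
                                              "icv")]))
  list(x = xs, y = y)
}

# Mediation scenario: dosage treatment, binary amyloid mediator, one ROI.
make_med_data <- function(n, a, b, cprime, seed, noise = 0.3) {
  set.seed(seed)
  g <- rbinom(n, 2, 0.3)
  covars <- data.frame(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5),
                       education = rnorm(n, 12, 4),
                       icv = rnorm(n, 1450, 140))
  m <- rbinom(n, 1, plogis(-0.3 + a * g + 0.01 * (covars$age - 70)))
  y <- 2.5 + b * m + cprime * g - 0.005 * (covars$age - 70) +
    rnorm(n, 0, noise)
  list(g = g, m = m, y = y, covars = covars)
}
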