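#' Configuration for the synthetic imaging-genetics cohort
#'
#' Collects every knob of the generator in one validated list. Defaults
#' emulate the structure of a memory-clinic amyloid cohort: ~1125
#' participants split into amyloid-negative/positive groups, a panel of 344
#' near-uncorrelated candidate SNPs in small LD blocks, and 12 lobar /
#' global cortical-thickness ROIs carrying a planted rank-1 canonical
#' signal plus SNP -> amyloid -> thickness mediation paths.
#'
#' The planted canonical correlation is `canonical_strength /
#' sqrt(canonical_strength^2 + noise_sd^2)`; the default strength is
#' calibrated so this equals 0.5 at the default residual noise of 0.30 mm.
#'
#' @param n_samples number of participants.
#' @param n_snps number of SNPs in the candidate panel.
#' @param n_rois number of cortical-thickness ROIs (12 gives named lobar +
#'   cingulate + global measures per hemisphere).
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho latent AR(1) correlation within a block, in `[0, 1)`.
#' @param maf_range range the per-SNP minor allele frequency is drawn from.
#' @param n_causal number of causal SNPs (one per block, spread evenly).
#' @param canonical_strength scale (mm) of the planted rank-1 thickness
#'   signal along `u_true`/`v_true`.
#' @param path_a per-causal-allele log-odds on amyloid positivity.
#' @param path_b amyloid -> thickness effect (mm, applied to every ROI).
#' @param path_c direct causal-allele -> thickness effect (mm per allele);
#'   default 0 because the canonical term already encodes the direct
#'   SNP -> thickness association (set it for explicit mediation
#'   scenarios).
#' @param covariate_effects named list of per-ROI slopes for `age` (per
#'   year), `sex` (female vs male, mm), `education` (per year) and `icv`
#'   (per cm3).
#' @param noise_sd residual thickness noise (mm).
#' @param abeta_target target marginal amyloid-positivity fraction; the
#'   logistic intercept is calibrated by bisection to reach it.
#' @param missing_rate genotype missingness rate.
#' @param decoy_fraction fraction of non-causal SNPs given sub-threshold
#'   summary-statistic p-values by [simulate_summary_stats()].
#' @param seed integer RNG seed; identical config + seed reproduces output
#'   exactly.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 1125, n_snps = 344, n_rois = 12,
                       ld_block_size = 4, ld_rho = 0.2,
                       maf_range = c(0.05, 0.5), n_causal = 10,
                       canonical_strength = 0.3 / sqrt(3),
                       path_a = 0.3, path_b = -0.1, path_c = 0,
                       covariate_effects = list(age = -0.010, sex = -0.030,
                                                education = 0.002,
                                                icv = 0.0002),
                       noise_sd = 0.3, abeta_target = 0.575,
                       missing_rate = 0, decoy_fraction = 0.9, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_rois = as.integer(n_rois),
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              maf_range = maf_range, n_causal = as.integer(n_causal),
              canonical_strength = canonical_strength, path_a = path_a,
              path_b = path_b, path_c = path_c,
              covariate_effects = covariate_effects, noise_sd = noise_sd,
              abeta_target = abeta_target, missing_rate = missing_rate,
              decoy_fraction = decoy_fraction, seed = as.integer(seed))
  if (cfg$n_samples < 1 || cfg$n_snps < 1 || cfg$n_rois < 1 ||
      cfg$ld_block_size < 1) {
    stop("dimensions must be positive")
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (cfg$n_causal > cfg$n_snps) stop("n_causal must not exceed n_snps")
  if (cfg$noise_sd < 0 || cfg$canonical_strength < 0) {
    stop("noise_sd and canonical_strength must be nonnegative")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  class(cfg) <- "sim_config"
  cfg
}

roi_labels <- function(q) {
  if (q == 12) {
    as.vector(outer(c("frontal", "temporal", "parietal", "occipital",
                      "cingulate", "global"), c("l", "r"),
                    function(a, b) paste(a, b, sep = "_")))
  } else {
    sprintf("roi_%02d", seq_len(q))
  }
}

roi_baseline <- function(labels) {
  base <- c(frontal = 2.55, temporal = 2.75, parietal = 2.45,
            occipital = 2.10, cingulate = 2.60, global = 2.50)
  lobes <- sub("_[lr]$", "", labels)
  out <- base[lobes]
  out[is.na(out)] <- 2.5
  unname(out)
}

# Planted imaging canonical vector: loads every ROI with emphasis on the
# global means, then frontal/parietal, mirroring an AD atrophy gradient.
# Negative sign: higher causal-allele burden means thinner cortex, so the
# amyloid-mediated path (a > 0, b < 0, uniform across ROIs) reinforces
# rather than cancels the canonical signal.
v_true_pattern <- function(labels) {
  w <- c(frontal = 0.30, temporal = 0.25, parietal = 0.30, occipital = 0.15,
         cingulate = 0.20, global = 0.40)
  lobes <- sub("_[lr]$", "", labels)
  raw <- unname(w[lobes])
  raw[is.na(raw)] <- 0.25
  -raw / l2norm(raw)
}

causal_snp_indices <- function(cfg) {
  n_blocks <- ceiling(cfg$n_snps / cfg$ld_block_size)
  k <- cfg$n_causal
  if (k == 0) return(integer(0))
  blocks <- unique(pmin(n_blocks, floor(seq(1, n_blocks, length.out = k))))
  i <- 1L
  while (length(blocks) < k) {  # fall back when blocks are scarce
    cand <- setdiff(seq_len(n_blocks), blocks)
    if (length(cand) == 0) stop("not enough LD blocks for n_causal")
    blocks <- sort(c(blocks, cand[1]))
  }
  idx <- (blocks - 1L) * cfg$ld_block_size + 1L
  idx[idx <= cfg$n_snps]
}

#' Simulate a panel of SNP dosages with block LD
#'
#' Draws a latent Gaussian with block-diagonal AR(1) correlation
#' (`ld_rho`, `ld_block_size`) and thresholds each column at the Hardy-
#' Weinberg cutpoints implied by its minor allele frequency, yielding
#' additive dosages in `{0, 1, 2}` (count of the A1 allele). SNP metadata
#' places each block contiguously: 5 kb spacing within a block and 500 kb
#' between blocks, cycling through autosomes.
#'
#' @param config a [sim_config()].
#' @return genotype list: `dosages` (n x p matrix, NA = missing),
#'   `sample_ids`, `snps` data frame (`id`, `chrom`, `pos`, `a1`, `a2`,
#'   `info_r2`, `maf_true`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_snps
  bs <- config$ld_block_size
  n_blocks <- ceiling(p / bs)

  z <- matrix(NA_real_, n, p)
  chol_cache <- list()
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * bs + 1L):min(b * bs, p)
    m <- length(cols)
    key <- as.character(m)
    if (is.null(chol_cache[[key]])) {
      s <- config$ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
      chol_cache[[key]] <- chol(s)
    }
    z[, cols] <- matrix(stats::rnorm(n * m), n, m) %*% chol_cache[[key]]
  }

  maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  # cutpoints for dosage = count of the (minor) A1 allele under HWE
  q0 <- stats::qnorm((1 - maf)^2)            # below: dosage 0
  q1 <- stats::qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
  d <- (sweep(z, 2, q0, ">") + sweep(z, 2, q1, ">")) * 1
  storage.mode(d) <- "integer"

  if (config$missing_rate > 0) {
    d[stats::runif(n * p) < config$missing_rate] <- NA_integer_
  }

  block_of <- rep(seq_len(n_blocks), each = bs)[seq_len(p)]
  within <- sequence(rle(block_of)$lengths) - 1L
  chrom <- ((block_of - 1L) %% 22L) + 1L
  block_on_chrom <- (block_of - 1L) %/% 22L
  pos <- 1000000L + block_on_chrom * 500000L + within * 5000L
  snps <- data.frame(id = sprintf("snp%04d", seq_len(p)), chrom = chrom,
                     pos = pos, a1 = "A", a2 = "G", info_r2 = 1.0,
                     maf_true = maf, stringsAsFactors = FALSE)

  list(dosages = d,
       sample_ids = sprintf("S%04d", seq_len(n)),
       snps = snps)
}

calibrate_intercept <- function(lp, target) {
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Simulate a full synthetic cohort
#'
#' Generates genotypes, demographic covariates, amyloid status, ROI
#' thickness with a planted rank-1 canonical signal and mediation paths,
#' and cognition. The amyloid logistic model uses the causal-SNP dosages
#' (`path_a` per allele) plus APOE e4 and age terms, with its intercept
#' calibrated by bisection so the marginal positivity rate matches
#' `abeta_target`. Thickness is
#' `baseline + covariates + strength * (X u_true) v_true' + b * Abeta +
#'  c' * (causal dosage sum) + N(0, noise_sd^2)`,
#' where `X` is the column-standardized dosage matrix. MMSE and CDR-SB are
#' noisy linear functions of mean global thickness.
#'
#' @param config a [sim_config()].
#' @param causal_indices optional SNP indices overriding the default
#'   evenly-spread causal set (used e.g. to plant disjoint signals in two
#'   cohorts sharing one panel).
#' @return list with `geno`, `pheno` (data frame) and `truth`
#'   (`causal_indices`, unit-norm `u_true`/`v_true`, path coefficients,
#'   planted canonical correlation).
#' @export
simulate_cohort <- function(config, causal_indices = NULL) {
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  n <- config$n_samples
  q <- config$n_rois

  age <- stats::rnorm(n, 70.2, 8.5)
  sex <- stats::rbinom(n, 1, 0.585)                 # 1 = female
  education <- pmax(0, round(stats::rnorm(n, 12, 4.5)))
  icv <- stats::rnorm(n, 1450, 140)                 # cm3
  apoe4 <- sample(0:2, n, replace = TRUE, prob = c(0.565, 0.344, 0.091))

  causal <- if (is.null(causal_indices)) causal_snp_indices(config) else
    as.integer(causal_indices)
  stopifnot(all(causal >= 1 & causal <= config$n_snps))
  u_true <- numeric(config$n_snps)
  if (length(causal)) u_true[causal] <- 1 / sqrt(length(causal))
  labels <- roi_labels(q)
  v_true <- v_true_pattern(labels)

  d_complete <- mean_impute(geno$dosages)
  xc_raw <- d_complete[, causal, drop = FALSE]
  causal_sum <- if (length(causal)) rowSums(xc_raw) else numeric(n)

  lp <- config$path_a * (causal_sum - mean(causal_sum)) +
    1.0 * (apoe4 - mean(apoe4)) + 0.015 * (age - mean(age))
  b0 <- calibrate_intercept(lp, config$abeta_target)
  abeta <- stats::rbinom(n, 1, stats::plogis(b0 + lp))
  if (length(unique(abeta)) < 2) {
    stop("degenerate amyloid model: all samples share one status")
  }

  xs <- standardize_columns(d_complete)
  z <- drop(xs %*% u_true)

  ce <- config$covariate_effects
  base <- roi_baseline(labels)
  fixed <- (ce$age %||% 0) * (age - 70) + (ce$sex %||% 0) * sex +
    (ce$education %||% 0) * (education - 12) +
    (ce$icv %||% 0) * (icv - 1450)
  y <- matrix(rep(base, each = n), n, q) + fixed +
    config$canonical_strength * tcrossprod(z, v_true) +
    config$path_b * abeta + config$path_c * causal_sum +
    matrix(stats::rnorm(n * q), n, q) * config$noise_sd
  colnames(y) <- labels

  gl <- grep("^global", labels)
  g <- rowMeans(y[, if (length(gl)) gl else seq_len(q), drop = FALSE])
  gz <- (g - mean(g)) / stats::sd(g)
  mmse <- pmin(30, pmax(0, round(24 + 2.75 * gz + stats::rnorm(n, 0, 4.76))))
  cdr_sb <- pmin(18, pmax(0, round((2.9 - 1.55 * gz +
                                      stats::rnorm(n, 0, 2.68)) * 2) / 2))

  sev <- -gz + 0.9 * abeta + stats::rnorm(n, 0, 0.8)
  cuts <- stats::quantile(sev, c(310, 310 + 368) / 1125)
  diagnosis <- cut(sev, c(-Inf, cuts, Inf), labels = c("CU", "aMCI", "DAT"))

  pheno <- data.frame(sample_id = geno$sample_ids, age = age, sex = sex,
                      education = education, icv = icv, apoe4 = apoe4,
                      abeta = abeta, diagnosis = as.character(diagnosis),
                      mmse = mmse, cdr_sb = cdr_sb,
                      stringsAsFactors = FALSE)
  pheno <- cbind(pheno, as.data.frame(y))

  truth <- list(causal_indices = causal,
                causal_ids = geno$snps$id[causal],
                u_true = u_true, v_true = v_true,
                path_a = config$path_a, path_b = config$path_b,
                path_c = config$path_c,
                planted_rho = config$canonical_strength /
                  sqrt(config$canonical_strength^2 + config$noise_sd^2))

  list(geno = geno, pheno = pheno, truth = truth, rois = labels,
       config = config)
}

#' Simulate GWAS summary statistics for the panel
#'
#' Causal SNPs receive p-values strictly below 1e-4 (log-uniform down to
#' 1e-8); a `decoy_fraction` of the non-causal SNPs also fall below the
#' threshold, and the remainder are Uniform(1e-4, 1). This emulates the
#' candidate-SNP filter applied to external meta-analysis statistics.
#'
#' @param config a [sim_config()].
#' @param truth truth list from [simulate_cohort()].
#' @param geno genotype list (for SNP metadata).
#' @return data frame `snp`, `chrom`, `pos`, `p`.
#' @export
simulate_summary_stats <- function(config, truth, geno) {
  set.seed(config$seed + 1L)
  p <- config$n_snps
  pv <- stats::runif(p, 1e-4, 1)
  causal <- truth$causal_indices
  pv[causal] <- 10^-stats::runif(length(causal), 4.1, 8)
  noncausal <- setdiff(seq_len(p), causal)
  n_decoy <- round(config$decoy_fraction * length(noncausal))
  if (n_decoy > 0) {
    decoys <- sample(noncausal, n_decoy)
    pv[decoys] <- 10^-stats::runif(n_decoy, 4.1, 8)
  }
  data.frame(snp = geno$snps$id, chrom = geno$snps$chrom,
             pos = geno$snps$pos, p = pv, stringsAsFactors = FALSE)
}

#' Synthetic SNP-to-gene annotation
#'
#' Assigns every LD block a synthetic gene symbol so enrichment can run on
#' generated cohorts; causal SNPs map to genes `CAUSAL01 ...`.
#'
#' @param geno genotype list.
#' @param truth truth list.
#' @param config a [sim_config()].
#' @return data frame `snp`, `gene`.
#' @export
simulate_annotation <- function(geno, truth, config) {
  p <- config$n_snps
  block <- (seq_len(p) - 1L) %/% config$ld_block_size + 1L
  gene <- sprintf("GENE%03d", block)
  causal_blocks <- block[truth$causal_indices]
  for (i in seq_along(causal_blocks)) {
    gene[block == causal_blocks[i]] <- sprintf("CAUSAL%02d", i)
  }
  data.frame(snp = geno$snps$id, gene = gene, stringsAsFactors = FALSE)
}

#' Synthetic gene-set collection
#'
#' Builds a small GMT-style collection over the synthetic gene universe:
#' one planted set holding the causal genes (plus a few bystanders) and
#' random sets of comparable size.
#'
#' @param annotation data frame from [simulate_annotation()].
#' @param truth truth list.
#' @param n_random number of random decoy sets.
#' @param seed RNG seed.
#' @return named list of character vectors with attribute `ontology`.
#' @export
simulate_gene_sets <- function(annotation, truth, n_random = 30, seed = 1L) {
  set.seed(seed)
  universe <- unique(annotation$gene)
  causal_genes <- unique(annotation$gene[annotation$snp %in% truth$causal_ids])
  planted <- unique(c(causal_genes,
                      sample(setdiff(universe, causal_genes),
                             min(3, length(setdiff(universe, causal_genes))))))
  sets <- list(planted_causal_pathway = planted)
  for (i in seq_len(n_random)) {
    sets[[sprintf("random_set_%02d", i)]] <-
      sample(universe, min(length(universe), sample(5:15, 1)))
  }
  attr(sets, "ontology") <- stats::setNames(
    rep(c("BP", "MF", "CC"), length.out = length(sets)), names(sets))
  sets
}

#' Write a synthetic cohort to disk as analysis-ready files
#'
#' Emits PLINK1 bed/bim/fam, a phenotype TSV, a summary-statistic TSV, an
#' annotation TSV, a GMT file and a truth JSON (whichever components are
#' present in `cohort`). Reading the PLINK trio back reproduces the dosage
#' matrix exactly, including missing calls.
#'
#' @param cohort list with `geno`, `pheno`, `truth` and optionally
#'   `sumstats`, `annotation`, `gene_sets`.
#' @param out_dir output directory (created if absent).
#' @return named character vector of written paths.
#' @export
write_fixture <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  prefix <- file.path(out_dir, "geno")
  write_plink(cohort$geno, prefix)
  paths <- c(paths, bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
             fam = paste0(prefix, ".fam"))
  info <- file.path(out_dir, "geno.info.tsv")
  utils::write.table(cohort$geno$snps[, c("id", "info_r2")], info,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, info = info)
  ph <- file.path(out_dir, "pheno.tsv")
  utils::write.table(cohort$pheno, ph, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, pheno = ph)
  if (!is.null(cohort$sumstats)) {
    ss <- file.path(out_dir, "sumstats.tsv")
    utils::write.table(cohort$sumstats, ss, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, sumstats = ss)
  }
  if (!is.null(cohort$annotation)) {
    an <- file.path(out_dir, "annotation.tsv")
    utils::write.table(cohort$annotation, an, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, annotation = an)
  }
  if (!is.null(cohort$gene_sets)) {
    gmt <- file.path(out_dir, "sets.gmt")
    write_gmt(cohort$gene_sets, gmt)
    paths <- c(paths, gmt = gmt)
  }
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(cohort$truth, tj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, truth = tj)
  paths
}
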