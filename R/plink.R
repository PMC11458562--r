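#' Write a genotype matrix as PLINK1 binary (bed/bim/fam)
#'
#' Emits the classic three-file PLINK1 format: a SNP-major `.bed` with the
#' magic bytes `0x6C 0x1B` and mode byte `0x01`, a six-column `.bim`
#' (chrom, id, cM, 1-based pos, allele1, allele2) and a six-column `.fam`.
#' Dosages are stored as counts of allele 1 (A1): two-bit codes 00 = two A1
#' alleles, 10 = heterozygote, 11 = zero A1 alleles, 01 = missing.
#'
#' @param geno genotype object as returned by [simulate_genotypes()]: a list
#'   with `dosages` (samples x SNPs, values 0/1/2/NA), `sample_ids`, and
#'   `snps` data frame (`id`, `chrom`, `pos`, `a1`, `a2`, optional `info_r2`).
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return invisibly, the three file paths.
#' @export
write_plink <- function(geno, prefix) {
  d <- geno$dosages
  n <- nrow(d)
  p <- ncol(d)
  stopifnot(length(geno$sample_ids) == n, nrow(geno$snps) == p)

  # two-bit code per genotype, indexed by dosage (NA -> 01b = 1)
  code <- matrix(1L, n, p)
  code[!is.na(d) & d == 2] <- 0L  # hom A1
  code[!is.na(d) & d == 1] <- 2L  # het
  code[!is.na(d) & d == 0] <- 3L  # hom A2

  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, p))
  # pack 4 samples per byte, first sample in the low-order bits
  idx <- seq_len(bytes_per_snp) * 4L
  packed <- code[idx - 3L, , drop = FALSE] +
    4L * code[idx - 2L, , drop = FALSE] +
    16L * code[idx - 1L, , drop = FALSE] +
    64L * code[idx, , drop = FALSE]

  bed <- paste0(prefix, ".bed")
  con <- file(bed, "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(packed)), con)
  close(con)

  bim <- data.frame(chrom = geno$snps$chrom, id = geno$snps$id, cm = 0,
                    pos = geno$snps$pos, a1 = geno$snps$a1, a2 = geno$snps$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = geno$sample_ids, iid = geno$sample_ids,
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read PLINK1 binary genotypes
#'
#' Counterpart of [write_plink()]; only SNP-major mode (`0x01`) is supported.
#' Returns dosages as counts of the `.bim` allele-1 column with `NA` for
#' missing calls.
#'
#' @param prefix path prefix of the bed/bim/fam trio.
#' @return genotype list with `dosages`, `sample_ids`, `snps`.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  n <- nrow(fam)
  p <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)

  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK1 bed file: ", prefix, ".bed")
  }
  raw <- readBin(con, "raw", bytes_per_snp * p)
  if (length(raw) != bytes_per_snp * p) stop("truncated bed file")

  v <- as.integer(raw)
  # unpack two-bit fields, low-order first
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
  dim(codes) <- c(4L * bytes_per_snp, p)
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)  # 00,01,10,11 -> dosage of A1
  dosages <- matrix(lut[codes + 1L], n, p)

  snps <- bim[, c("id", "chrom", "pos", "a1", "a2")]
  list(dosages = dosages, sample_ids = as.character(fam$V2), snps = snps)
}
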