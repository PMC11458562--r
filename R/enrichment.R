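#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member genes. The
#' description field is kept as the ontology tag (BP/MF/CC) when it looks
#' like one.
#'
#' @param path GMT file.
#' @return named list of gene vectors with attribute `ontology`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  ont <- ifelse(desc %in% c("BP", "MF", "CC"), desc, "NA")
  attr(sets, "ontology") <- stats::setNames(ont, names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene vectors (attribute `ontology` used for
#'   the description column when present).
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  ont <- attr(sets, "ontology") %||%
    stats::setNames(rep("NA", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, ont[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Map SNPs to gene symbols through an annotation table
#'
#' Joins SNP IDs to their mapped/nearest gene labels, deduplicates, and
#' preserves the order of first appearance. SNPs absent from the
#' annotation are dropped with a message.
#'
#' @param snps character vector of SNP IDs.
#' @param annotation data frame with columns `snp`, `gene`.
#' @return character vector of gene symbols.
#' @export
map_snps_to_genes <- function(snps, annotation) {
  stopifnot(all(c("snp", "gene") %in% names(annotation)))
  if (nrow(annotation) == 0) stop("empty SNP-to-gene annotation")
  if (length(snps) == 0) return(character(0))
  hit <- match(snps, annotation$snp)
  if (anyNA(hit)) {
    message("SNPs without annotation (dropped): ",
            paste(snps[is.na(hit)], collapse = ", "))
  }
  unique(annotation$gene[hit[!is.na(hit)]])
}

#' Fisher-exact gene-set over-representation
#'
#' For each set, builds the 2x2 table (query-in-set, query-out-of-set,
#' set-only, remainder of the universe) and computes the one-sided
#' (over-representation) Fisher exact p-value; the odds ratio is the
#' sample cross-product ratio with a Haldane-Anscombe 0.5 correction when
#' any cell is zero. Rows are sorted by ascending p with
#' Benjamini-Hochberg q-values.
#'
#' @param query character vector of gene symbols.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background gene universe; defaults to the union of all
#'   set members.
#' @return data frame: `term`, `ontology`, `n_overlap`, `overlap_genes`,
#'   `odds_ratio`, `p`, `q`.
#' @export
fisher_enrichment <- function(query, sets, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(sets))
  query <- intersect(unique(query), universe)
  if (length(query) == 0) stop("query has no genes in the universe")
  ont <- attr(sets, "ontology") %||%
    stats::setNames(rep("NA", length(sets)), names(sets))

  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    a <- length(intersect(query, s))
    b <- length(query) - a
    cc <- length(s) - a
    d <- length(universe) - a - b - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, 2),
                            alternative = "greater")$p.value
    orr <- if (a == 0 || b == 0 || cc == 0 || d == 0) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      (a * d) / (b * cc)
    }
    data.frame(term = nm, ontology = unname(ont[nm]), n_overlap = a,
               overlap_genes = paste(intersect(query, s), collapse = ";"),
               odds_ratio = orr, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p p-values in `(0, 1]`.
#' @return q-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}
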