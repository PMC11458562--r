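#' Column-standardize a numeric matrix
#'
#' Centers each column to mean zero and scales to unit (n-1) variance.
#' Constant columns are centered but left unscaled (and flagged), so that
#' downstream cross-products stay finite.
#'
#' @param x numeric matrix.
#' @return matrix with attribute `constant` marking zero-variance columns.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- !is.finite(sdv) | sdv < .Machine$double.eps^0.5
  sdv[const] <- 1
  out <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  attr(out, "constant") <- const
  out
}

l2norm <- function(x) sqrt(sum(x^2))

#' Mean-impute missing dosages per SNP
#'
#' Missing genotype calls are replaced by the per-SNP mean dosage among
#' observed samples. SNPs that are entirely missing raise an error.
#'
#' @param dosages numeric matrix (samples x SNPs), NA for missing calls.
#' @return complete numeric matrix.
#' @export
mean_impute <- function(dosages) {
  dosages <- as.matrix(dosages)
  nmiss <- colSums(is.na(dosages))
  if (any(nmiss == nrow(dosages))) {
    stop("cannot impute SNPs with no observed calls: ",
         paste(utils::head(which(nmiss == nrow(dosages))), collapse = ", "))
  }
  if (any(nmiss > 0)) {
    mu <- colMeans(dosages, na.rm = TRUE)
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- mu[idx[, 2]]
  }
  dosages
}

# drop S3 classes recursively so plain lists serialize to JSON
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

# md5 of an in-memory object via its canonical JSON serialization; used for
# config hashes in pipeline manifests (file content hashes use tools::md5sum).
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
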