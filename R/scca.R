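#' Residualize imaging features against covariates
#'
#' Per-column ordinary-least-squares residuals against an intercept plus
#' the covariate matrix, then z-scored. Columns whose residual variance is
#' (near) zero are flagged as degenerate and left centered but unscaled.
#'
#' @param y_raw n x q matrix of ROI measures.
#' @param covars n x c covariate matrix or data frame (may have zero
#'   columns).
#' @return z-scored residual matrix with attribute `degenerate`.
#' @export
residualize <- function(y_raw, covars = NULL) {
  y_raw <- as.matrix(y_raw)
  n <- nrow(y_raw)
  if (is.null(covars) || NCOL(covars) == 0) {
    x <- matrix(1, n, 1)
  } else {
    covars <- as.matrix(covars)
    storage.mode(covars) <- "double"
    x <- cbind(1, covars)
  }
  if (n <= ncol(x)) stop("need more samples than covariates")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[seq(qx$rank + 1, ncol(x))]]
    stop("collinear covariate columns: ",
         paste(bad %||% "(unnamed)", collapse = ", "))
  }
  res <- qr.resid(qx, y_raw)
  out <- standardize_columns(res)
  attr(out, "degenerate") <- attr(out, "constant")
  attr(out, "constant") <- NULL
  colnames(out) <- colnames(y_raw)
  out
}

#' Soft-thresholding operator
#'
#' `sign(a) * max(|a| - c, 0)`, elementwise.
#'
#' @param a numeric vector.
#' @param c nonnegative threshold.
#' @return shrunken vector.
#' @export
soft_threshold <- function(a, c) {
  stopifnot(c >= 0)
  sign(a) * pmax(abs(a) - c, 0)
}

#' Project a vector onto the unit L2 sphere subject to an L1 budget
#'
#' Returns `S(w, delta) / ||S(w, delta)||_2` where the soft threshold
#' `delta` is zero when the plain normalization already satisfies
#' `||.||_1 <= tau`, and otherwise is found by bisection so the output's
#' L1 norm equals `tau`. This is the exact maximizer of `<w, u>` over
#' `{u : ||u||_2 <= 1, ||u||_1 <= tau}` used inside the sparse CCA
#' updates. At `tau = 1` the solution is the 1-sparse unit vector at the
#' largest `|w|` entry.
#'
#' @param w nonzero numeric vector.
#' @param tau L1 budget, `1 <= tau <= sqrt(length(w))` is meaningful.
#' @return unit-L2 vector with `||.||_1 <= tau + 1e-6`.
#' @export
l1_constrain <- function(w, tau) {
  if (all(w == 0)) stop("cannot project the zero vector")
  if (tau < 1) stop("tau must be at least 1")
  u <- w / l2norm(w)
  if (sum(abs(u)) <= tau) return(u)
  if (tau == 1) {
    out <- numeric(length(w))
    i <- which.max(abs(w))
    out[i] <- sign(w[i])
    return(out)
  }
  f <- function(delta) {
    s <- soft_threshold(w, delta)
    sum(abs(s)) / l2norm(s) - tau
  }
  lo <- 0
  hi <- max(abs(w)) * (1 - 1e-12)
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (!is.finite(v) || v > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-14 * max(abs(w))) break
  }
  s <- soft_threshold(w, (lo + hi) / 2)
  s / l2norm(s)
}

#' Rank-1 sparse canonical correlation fit
#'
#' Alternating maximization of `u' X' Y v` subject to unit L2 norms and L1
#' budgets `tau1` (SNP side) and `tau2` (imaging side): each update is the
#' closed-form L1-constrained projection of the cross-product against the
#' other side's current vector. Initialized from the leading singular pair
#' of `X'Y` (deterministic) or a seeded random direction. The returned
#' sign convention makes the largest-magnitude entry of `u` positive.
#'
#' @param x standardized n x p matrix (SNP dosages).
#' @param y standardized / residualized n x q matrix (imaging).
#' @param tau1,tau2 L1 budgets; defaults are the inactive bounds
#'   `sqrt(p)`, `sqrt(q)`.
#' @param max_iter,tol convergence controls (relative objective change).
#' @param init `"svd"` or `"random"`.
#' @param seed RNG seed for random init.
#' @return `scca_result`: `u`, `v`, `rho` (sample correlation of the
#'   projections), `objective` trace, `n_iter`, `converged`.
#' @export
scca_fit <- function(x, y, tau1 = sqrt(ncol(x)), tau2 = sqrt(ncol(y)),
                     max_iter = 200, tol = 1e-6, init = c("svd", "random"),
                     seed = NULL) {
  init <- match.arg(init)
  x <- as.matrix(x); y <- as.matrix(y)
  if (anyNA(x) || anyNA(y)) stop("NaN/NA in input matrices")
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 3, tol > 0)
  cxy <- crossprod(x, y)

  if (init == "svd") {
    sv <- svd(cxy, nu = 1, nv = 1)
    v <- drop(sv$v)
  } else {
    if (!is.null(seed)) set.seed(seed)
    v <- stats::rnorm(ncol(y))
    v <- v / l2norm(v)
  }
  v <- l1_constrain(v, tau2)

  obj <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    u <- l1_constrain(drop(cxy %*% v), tau1)
    v <- l1_constrain(drop(crossprod(cxy, u)), tau2)
    obj <- c(obj, drop(t(u) %*% cxy %*% v))
    if (it > 1) {
      rel <- abs(obj[it] - obj[it - 1]) / max(abs(obj[it - 1]), 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  imax <- which.max(abs(u))
  if (u[imax] < 0) { u <- -u; v <- -v }
  xu <- drop(x %*% u); yv <- drop(y %*% v)
  rho <- if (stats::sd(xu) == 0 || stats::sd(yv) == 0) 0 else
    stats::cor(xu, yv)

  out <- list(u = u, v = v, rho = rho, objective = obj,
              n_iter = length(obj), converged = converged,
              tau1 = tau1, tau2 = tau2,
              snp_ids = colnames(x), roi_labels = colnames(y))
  class(out) <- "scca_result"
  out
}

#' @export
print.scca_result <- function(x, ...) {
  cat(sprintf(
    "Sparse CCA: rho = %.3f, %d/%d nonzero SNP weights, %d iterations%s\n",
    x$rho, sum(x$u != 0), length(x$u), x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Select the L1 budgets by cross-validated projection correlation
#'
#' Grid search over `(tau1, tau2)` pairs maximizing the mean out-of-fold
#' correlation of `X u` and `Y v`; ties go to the sparser (smaller) pair.
#'
#' @param x,y standardized matrices.
#' @param grid1,grid2 candidate budgets for each side.
#' @param n_folds folds (default 5).
#' @param seed RNG seed for the fold split.
#' @return list `tau1`, `tau2`, `cv` (mean out-of-fold correlation grid).
#' @export
tune_tau <- function(x, y, grid1, grid2 = sqrt(ncol(y)), n_folds = 5,
                     seed = 1L) {
  stopifnot(length(grid1) >= 1, length(grid2) >= 1)
  set.seed(seed)
  n <- nrow(x)
  fold <- sample(rep_len(seq_len(n_folds), n))
  cv <- matrix(NA_real_, length(grid1), length(grid2))
  for (i in seq_along(grid1)) {
    for (j in seq_along(grid2)) {
      r <- vapply(seq_len(n_folds), function(k) {
        tr <- fold != k
        fit <- scca_fit(x[tr, , drop = FALSE], y[tr, , drop = FALSE],
                        grid1[i], grid2[j])
        xu <- x[!tr, , drop = FALSE] %*% fit$u
        yv <- y[!tr, , drop = FALSE] %*% fit$v
        if (stats::sd(xu) == 0 || stats::sd(yv) == 0) 0 else
          stats::cor(xu, yv)
      }, numeric(1))
      cv[i, j] <- mean(r)
    }
  }
  best <- which(cv == max(cv), arr.ind = TRUE)
  o <- order(grid1[best[, 1]] + grid2[best[, 2]], grid1[best[, 1]])
  list(tau1 = grid1[best[o[1], 1]], tau2 = grid2[best[o[1], 2]], cv = cv)
}

#' Top-k SNPs by absolute canonical weight
#'
#' @param result `scca_result`.
#' @param snps SNP metadata data frame (`id`, `chrom`, `pos`) aligned with
#'   `result$u`.
#' @param k number of SNPs to report.
#' @return data frame `id`, `chrom`, `pos`, `weight`, ranked by `|weight|`
#'   descending (ties by chrom, pos, id); shorter than `k` with a warning
#'   when fewer weights are nonzero.
#' @export
top_k_snps <- function(result, snps, k = 10) {
  stopifnot(k <= length(result$u), nrow(snps) == length(result$u))
  ord <- order(-abs(result$u), snps$chrom, snps$pos, snps$id)
  nz <- sum(result$u != 0)
  if (nz < k) {
    warning(sprintf("only %d nonzero weights; returning %d SNPs", nz, nz))
    k <- nz
  }
  sel <- ord[seq_len(k)]
  data.frame(id = snps$id[sel], chrom = snps$chrom[sel], pos = snps$pos[sel],
             weight = result$u[sel], stringsAsFactors = FALSE)
}

#' Group-wise sparse CCA over amyloid strata
#'
#' Runs covariate residualization of the imaging block and [scca_fit()]
#' independently within each group and on the pooled sample. Only the
#' imaging side is covariate-adjusted; genotype columns are standardized
#' per group (an `adjust_x` flag residualizes X too).
#'
#' @param dosages complete dosage matrix restricted to the candidate panel
#'   (columns named by SNP ID).
#' @param snps SNP metadata aligned with the columns.
#' @param y_raw raw ROI thickness matrix.
#' @param covars covariate matrix/data frame.
#' @param group binary vector (0 = negative, 1 = positive).
#' @param tau1,tau2 L1 budgets.
#' @param top_k SNPs to report per group.
#' @param adjust_x also residualize the genotype block.
#' @param min_per_covar required samples per covariate (+1) per group.
#' @return list of `scca_result` + top-k tables for `negative`, `positive`
#'   and `total`.
#' @export
groupwise_scca <- function(dosages, snps, y_raw, covars, group,
                           tau1 = 4, tau2 = sqrt(ncol(y_raw)),
                           top_k = 10, adjust_x = FALSE, min_per_covar = 3) {
  stopifnot(length(group) == nrow(dosages))
  groups <- list(negative = group == 0, positive = group == 1,
                 total = rep(TRUE, length(group)))
  need <- min_per_covar * (NCOL(covars) + 1)
  out <- list()
  for (nm in names(groups)) {
    idx <- groups[[nm]]
    if (sum(idx) < max(need, 3)) {
      stop(sprintf("group '%s' too small (%d samples)", nm, sum(idx)))
    }
    cg <- if (is.null(covars)) NULL else covars[idx, , drop = FALSE]
    yg <- residualize(y_raw[idx, , drop = FALSE], cg)
    xg <- if (adjust_x) residualize(dosages[idx, , drop = FALSE], cg) else
      standardize_columns(dosages[idx, , drop = FALSE])
    fit <- scca_fit(xg, yg, tau1 = tau1, tau2 = tau2)
    out[[nm]] <- list(fit = fit, top = top_k_snps(fit, snps, top_k))
  }
  class(out) <- "groupwise_scca"
  out
}

#' @export
print.groupwise_scca <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("[%s] rho = %.3f, top SNPs: %s\n", nm, x[[nm]]$fit$rho,
                paste(utils::head(x[[nm]]$top$id, 5), collapse = ", ")))
  }
  invisible(x)
}
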