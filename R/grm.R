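new_grm <- function(A, ids, pair_counts = NULL, snp_set = "all", m = NA_integer_) {
  structure(list(A = A, ids = ids, pair_counts = pair_counts,
                 snp_set = snp_set, m = m), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, snp_set '%s' (%s SNPs)\n",
              nrow(x$A), x$snp_set,
              ifelse(is.na(x$m), "?", format(x$m))))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.2e\n",
              mean(diag(x$A)), mean(x$A[upper.tri(x$A)])))
  invisible(x)
}

#' Compute a genetic relationship matrix
#'
#' GCTA-style GRM over a SNP partition. With genotype dosage \eqn{x_{ij}}
#' and counted-allele frequency \eqn{p_i} estimated on the analysis sample,
#' the off-diagonal between individuals j and k is
#' \deqn{A_{jk} = \frac{1}{N_{jk}} \sum_i
#'   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)}}
#' over pairwise non-missing SNPs, and the diagonal uses the
#' inbreeding-adjusted form
#' \deqn{A_{jj} = 1 + \frac{1}{N_j} \sum_i
#'   \frac{x_{ij}^2 - (1 + 2 p_i) x_{ij} + 2 p_i^2}{2 p_i (1 - p_i)}.}
#' Missing calls are excluded pairwise (per-pair denominators), not
#' imputed. Monomorphic SNPs in the mask are skipped with a warning.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param snp_mask logical or integer index over SNPs (NULL = all).
#' @param snp_set label stored with the result.
#' @param diagonal \code{"gcta"} (inbreeding-adjusted, default) or
#'   \code{"crossprod"} (plain standardized cross-product); the two agree
#'   in expectation under Hardy-Weinberg equilibrium.
#' @return a \code{grm} object: \code{A} (n x n), \code{ids},
#'   \code{pair_counts}, \code{snp_set}, \code{m} (SNPs used).
#' @export
compute_grm <- function(g, snp_mask = NULL, snp_set = "all",
                        diagonal = c("gcta", "crossprod")) {
  diagonal <- match.arg(diagonal)
  idx <- if (is.null(snp_mask)) seq_len(n_snps(g))
         else if (is.logical(snp_mask)) which(snp_mask)
         else as.integer(snp_mask)
  if (length(idx) == 0)
    stop_snpher("snpher_precondition_error", "empty SNP mask")
  X <- g$calls[, idx, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!all(poly)) {
    warning(sprintf("skipping %d monomorphic SNPs in GRM", sum(!poly)))
    X <- X[, poly, drop = FALSE]; p <- p[poly]
  }
  m <- ncol(X)
  if (m == 0) stop_snpher("snpher_precondition_error", "no polymorphic SNPs in mask")
  n <- nrow(X)
  denom <- 2 * p * (1 - p)
  has_na <- anyNA(X)
  W <- sweep(sweep(X, 2, 2 * p), 2, sqrt(denom), "/")
  if (!has_na) {
    A <- tcrossprod(W) / m
    Npair <- matrix(m, n, n)
  } else {
    obs <- !is.na(X)
    W[!obs] <- 0
    Npair <- tcrossprod(obs * 1)
    A <- tcrossprod(W) / pmax(Npair, 1)
  }
  diag_terms <- sweep(X^2 - sweep(X, 2, 1 + 2 * p, "*"), 2, 2 * p^2, "+")
  diag_terms <- sweep(diag_terms, 2, denom, "/")
  if (diagonal == "gcta") {
    diag(A) <- 1 + rowMeans(diag_terms, na.rm = TRUE)
  }
  new_grm(A, g$samples, pair_counts = Npair,
          snp_set = snp_set, m = m)
}

#' Principal components of a GRM
#'
#' Top-k eigenvectors of the relatedness matrix ordered by eigenvalue,
#' with each component's sign fixed so its largest-magnitude loading is
#' positive.
#'
#' @param grm a \code{grm} object.
#' @param k number of components (k < n).
#' @return list with \code{vectors} (n x k), \code{values} (length k) and
#'   \code{ids}.
#' @export
grm_pca <- function(grm, k) {
  n <- nrow(grm$A)
  if (k >= n) stop_snpher("snpher_precondition_error", "need k < n")
  if (any(!is.finite(grm$A)))
    stop_snpher("snpher_precondition_error", "non-finite entries in GRM")
  ee <- eigen(grm$A, symmetric = TRUE)
  V <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(vectors = V, values = ee$values[seq_len(k)], ids = grm$ids)
}

#' Write principal components in the GCTA .eigenvec dialect
#'
#' @param pca result of \code{\link{grm_pca}}.
#' @param path output file (whitespace-delimited FID IID pc1..pck).
#' @return \code{path}, invisibly.
#' @export
write_eigenvec <- function(pca, path) {
  utils::write.table(cbind(pca$ids, as.data.frame(pca$vectors)), path,
                     quote = FALSE, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
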