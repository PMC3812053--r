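#' Bivariate AI-REML genetic correlation for disjoint samples
#'
#' Stacks two case-control traits measured on disjoint individuals that
#' share a SNP panel into one mixed model. The phenotypic covariance is
#' built from within- and cross-sample GRM blocks scaled by
#' \eqn{(\sigma^2_{g1}, \sigma^2_{g2}, \sigma_{g12})} plus trait-specific
#' residuals; the residual covariance is structurally zero because no
#' individual carries both traits. The genetic correlation is
#' \eqn{r_g = \sigma_{g12} / \sqrt{\sigma^2_{g1}\sigma^2_{g2}}} with a
#' delta-method standard error from the inverse average-information
#' matrix. Estimates with \eqn{|r_g| > 1} are clamped and flagged, not
#' silently truncated.
#'
#' @param G the genotype source for the combined sample: a
#'   \code{\link{genotype_matrix}} containing both samples (see
#'   \code{\link{combine_genotypes}}) or a precomputed \code{grm} on the
#'   combined sample.
#' @param pheno1,pheno2 data.frames with \code{fid}, \code{iid},
#'   \code{status} (0/1); sample sets must be disjoint.
#' @param X1,X2 optional per-trait covariate matrices (row order matching
#'   \code{pheno1}/\code{pheno2}); intercepts are always included per
#'   trait.
#' @param options passed to the AI-REML optimizer (see
#'   \code{\link{reml_fit}}); additionally \code{fix_cov = TRUE} fits the
#'   null model with the genetic covariance pinned at zero.
#' @return an object of class \code{bivar_fit}: \code{sigma2} (named
#'   vector g1, g2, cov_g12, e1, e2), \code{se_sigma2}, \code{rg},
#'   \code{se_rg}, \code{rg_clamped}, \code{h2_observed} per trait,
#'   \code{loglik}, \code{converged}, \code{n1}, \code{n2}.
#' @export
bivar_reml_fit <- function(G, pheno1, pheno2, X1 = NULL, X2 = NULL,
                           options = list()) {
  k1 <- paste(pheno1$fid, pheno1$iid)
  k2 <- paste(pheno2$fid, pheno2$iid)
  overlap <- intersect(k1, k2)
  if (length(overlap))
    stop_snpher("snpher_precondition_error",
                "samples carry both traits: %s",
                paste(utils::head(overlap, 5), collapse = ", "))
  grm <- if (inherits(G, "grm")) G else compute_grm(G)
  kk <- paste(grm$ids$fid, grm$ids$iid)
  i1 <- match(k1, kk); i2 <- match(k2, kk)
  if (anyNA(i1) || anyNA(i2))
    stop_snpher("snpher_precondition_error",
                "phenotype ids missing from the genotype source")
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  ord <- c(i1, i2)
  A <- grm$A[ord, ord]
  e1 <- c(rep(1, n1), rep(0, n2)); e2 <- 1 - e1
  designs <- list(A * tcrossprod(e1),
                  A * tcrossprod(e2),
                  A * (tcrossprod(e1, e2) + tcrossprod(e2, e1)),
                  diag(e1), diag(e2))
  y <- c(pheno1$status, pheno2$status)
  X1f <- prep_X(X1, n1); X2f <- prep_X(X2, n2)
  X <- matrix(0, n, ncol(X1f) + ncol(X2f))
  X[seq_len(n1), seq_len(ncol(X1f))] <- X1f
  X[n1 + seq_len(n2), ncol(X1f) + seq_len(ncol(X2f))] <- X2f

  v1 <- stats::var(pheno1$status); v2 <- stats::var(pheno2$status)
  if (v1 == 0 || v2 == 0)
    stop_snpher("snpher_precondition_error", "a phenotype has zero variance")
  init <- options$init %||% c(v1 / 2, v2 / 2, 0, v1 / 2, v2 / 2)
  fixed <- rep(FALSE, 5)
  if (isTRUE(options$fix_cov)) { init[3] <- 0; fixed[3] <- TRUE }
  opt <- options; opt$fixed <- fixed
  engine <- ai_engine_dense(designs, y, X)
  res <- ai_reml(engine, init, var_p = (v1 + v2) / 2, n = n,
                 constraint = c("nonneg", "nonneg", "free", "nonneg", "nonneg"),
                 options = opt)
  s <- res$sigma
  rg_raw <- s[3] / sqrt(s[1] * s[2])
  clamped <- abs(rg_raw) > 1
  rg <- max(-1, min(1, rg_raw))
  # delta method on (g1, g2, c)
  se_rg <- NA_real_
  if (!isTRUE(options$fix_cov) && all(is.finite(res$cov[1:3, 1:3]))) {
    gr <- c(-rg_raw / (2 * s[1]), -rg_raw / (2 * s[2]), 1 / sqrt(s[1] * s[2]))
    se_rg <- sqrt(max(0, crossprod(gr, res$cov[1:3, 1:3] %*% gr)))
  }
  labels <- c("V(G1)", "V(G2)", "C(G12)", "V(e1)", "V(e2)")
  structure(list(sigma2 = stats::setNames(s, labels),
                 se_sigma2 = stats::setNames(res$se, labels),
                 cov_sigma2 = res$cov,
                 rg = rg, rg_raw = rg_raw, se_rg = as.numeric(se_rg),
                 rg_clamped = clamped,
                 h2_observed = c(trait1 = s[1] / (s[1] + s[4]),
                                 trait2 = s[2] / (s[2] + s[5])),
                 loglik = res$logL, n_iter = res$n_iter,
                 converged = res$converged, boundary_flags = res$boundary,
                 n1 = n1, n2 = n2), class = "bivar_fit")
}

#' @export
print.bivar_fit <- function(x, ...) {
  cat("bivariate AI-REML fit\n")
  for (i in seq_along(x$sigma2))
    cat(sprintf("  %-7s %10.6f (se %.6f)\n", names(x$sigma2)[i],
                x$sigma2[i], x$se_sigma2[i]))
  cat(sprintf("  rg %.4f (se %.4f)%s\n", x$rg, x$se_rg,
              if (x$rg_clamped) " [clamped]" else ""))
  cat(sprintf("  logL %.4f (%s)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Likelihood-ratio test for zero genetic correlation
#'
#' Statistic \eqn{2(\ell_{free} - \ell_{r_g = 0})}, compared to
#' \eqn{\chi^2_1} (two-sided convention); the one-sided halved p-value is
#' reported alongside since the covariance parameter is interior (not a
#' boundary).
#'
#' @param fit_free unconstrained \code{bivar_fit}.
#' @param fit_rg0 the same data fitted with \code{options$fix_cov = TRUE}.
#' @return list with \code{statistic}, \code{p} (two-sided chi-square 1),
#'   \code{p_one_sided}.
#' @export
rg_lrt <- function(fit_free, fit_rg0) {
  if (fit_free$n1 != fit_rg0$n1 || fit_free$n2 != fit_rg0$n2)
    stop_snpher("snpher_precondition_error", "fits are on different samples")
  stat <- max(0, 2 * (fit_free$loglik - fit_rg0$loglik))
  p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  list(statistic = stat, p = p, p_one_sided = p / 2)
}
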