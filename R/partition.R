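#' Build a MAF-bin partition specification
#'
#' Half-open bins (lo, hi] at the given edges (defaults
#' \code{\link{default_maf_edges}}: 0.001-0.05, >0.05-0.1, >0.1-0.2,
#' >0.2-0.3, >0.3-0.4, >0.4-0.5). SNPs with MAF at or below the first
#' edge are excluded and reported; a MAF exactly on an upper edge falls
#' in the lower bin.
#'
#' @param g a \code{\link{genotype_matrix}} (MAF from the analysis
#'   sample).
#' @param edges strictly increasing breakpoints within (0, 0.5].
#' @return a \code{partition_spec}: \code{kind}, \code{labels},
#'   \code{masks} (list of logical), \code{excluded} (SNP ids below the
#'   first edge), \code{edges}.
#' @export
make_maf_bins <- function(g, edges = default_maf_edges()) {
  if (any(diff(edges) <= 0) || any(edges <= 0) || any(edges > 0.5))
    stop_snpher("snpher_config_error",
                "edges must be strictly increasing within (0, 0.5]")
  maf <- g$maf
  nb <- length(edges) - 1
  labels <- sprintf("maf(%g,%g]", edges[-length(edges)], edges[-1])
  masks <- lapply(seq_len(nb), function(k)
    !is.na(maf) & maf > edges[k] & maf <= edges[k + 1])
  empty <- vapply(masks, function(m) !any(m), TRUE)
  if (any(empty))
    warning(sprintf("empty MAF bins: %s", paste(labels[empty], collapse = ", ")))
  structure(list(kind = "maf_bins", labels = labels, masks = masks,
                 edges = edges,
                 excluded = g$snps$id[!is.na(maf) & maf <= edges[1]]),
            class = "partition_spec")
}

#' Build an annotation partition specification
#'
#' One mask per named annotation; a complement partition covering SNPs in
#' none of them is appended automatically so the partition covers the
#' panel. Masks must be disjoint.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param labels annotation names present in \code{g$annotations}.
#' @param complement_label name for the automatic complement partition.
#' @return a \code{partition_spec}.
#' @export
make_annotation_partition <- function(g, labels,
                                      complement_label = "complement") {
  missing_l <- setdiff(labels, names(g$annotations))
  if (length(missing_l))
    stop_snpher("snpher_precondition_error", "unknown annotations: %s",
                paste(missing_l, collapse = ", "))
  masks <- g$annotations[labels]
  cover <- Reduce(`+`, masks)
  if (any(cover > 1))
    stop_snpher("snpher_precondition_error", "annotation masks overlap")
  comp <- cover == 0
  if (any(comp)) {
    masks <- c(masks, stats::setNames(list(comp), complement_label))
    labels <- c(labels, complement_label)
  }
  structure(list(kind = "annotation", labels = labels, masks = masks,
                 excluded = character(0)),
            class = "partition_spec")
}

#' Build a by-chromosome partition specification
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return a \code{partition_spec} with one mask per chromosome present.
#' @export
make_chromosome_partition <- function(g) {
  chrs <- sort(unique(g$snps$chr))
  masks <- lapply(chrs, function(c) g$snps$chr == c)
  structure(list(kind = "chromosome", labels = paste0("chr", chrs),
                 masks = masks, chromosomes = chrs, excluded = character(0)),
            class = "partition_spec")
}

#' Joint multi-GRM partitioned REML
#'
#' Builds one GRM per partition and fits all of them jointly by AI-REML,
#' so linkage between partitions is absorbed by the joint model. Each
#' partition's observed-scale heritability is converted to the liability
#' scale with the shared transform factor; shares of total are computed
#' against the sum of the genetic components of the same joint model.
#' Partitions with no SNPs are dropped with a notice; partitions with
#' fewer than 50 SNPs trigger a warning but are fitted.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param spec a \code{partition_spec}.
#' @param y 0/1 phenotype.
#' @param X covariates (see \code{\link{reml_fit}}).
#' @param K population prevalence for the liability transform (NULL skips
#'   the transform).
#' @param options optimizer options.
#' @return a \code{partition_result}: \code{table} (per-partition SNP
#'   counts, variances, SEs, observed and liability h2, shares),
#'   \code{fit} (the joint \code{vc_fit}), \code{factor}, \code{total_h2}.
#' @export
partitioned_reml <- function(g, spec, y, X = NULL, K = NULL,
                             options = list()) {
  sizes <- vapply(spec$masks, sum, 0L)
  keep <- sizes > 0
  if (sum(keep) < 1)
    stop_snpher("snpher_precondition_error", "no non-empty partitions")
  if (any(!keep))
    message(sprintf("dropping empty partitions: %s",
                    paste(spec$labels[!keep], collapse = ", ")))
  small <- keep & sizes < 50
  if (any(small))
    warning(sprintf("partitions with <50 SNPs: %s",
                    paste(spec$labels[small], collapse = ", ")))
  labels <- spec$labels[keep]
  grms <- lapply(which(keep), function(k)
    compute_grm(g, spec$masks[[k]], snp_set = spec$labels[k]))
  fit <- reml_fit(grms, y, X, options = options)
  m <- length(grms)
  sg <- fit$sigma2[seq_len(m)]
  tot_g <- sum(sg)
  shares <- if (tot_g > 0) sg / tot_g else rep(NA_real_, m)
  h2_obs <- fit$h2_observed$per_component
  se_obs <- fit$h2_observed$se_per_component
  fac <- NA_real_; h2_liab <- se_liab <- rep(NA_real_, m)
  total_h2 <- fit$h2_observed$total
  if (!is.null(K)) {
    lp <- liability_params(K, mean(y))
    tr <- observed_to_liability(h2_obs, se_obs, lp)
    h2_liab <- tr$h2_liab; se_liab <- tr$se_liab; fac <- tr$factor
    total_h2 <- observed_to_liability(fit$h2_observed$total,
                                      fit$h2_observed$se_total, lp)$h2_liab
  }
  tab <- data.frame(partition = labels, n_snps = sizes[keep],
                    frac_snps = sizes[keep] / sum(sizes[keep]),
                    sigma2 = unname(sg), se_sigma2 = unname(fit$se_sigma2[seq_len(m)]),
                    h2_observed = unname(h2_obs), se_h2_observed = unname(se_obs),
                    h2_liability = unname(h2_liab), se_h2_liability = unname(se_liab),
                    share = unname(shares), stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit, factor = fac, total_h2 = total_h2,
                 K = K), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("joint partitioned REML\n")
  print(x$table, digits = 4)
  cat(sprintf("total h2 %.4f (logL %.3f, %s)\n", x$total_h2, x$fit$loglik,
              if (x$fit$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Per-chromosome heritability analysis
#'
#' \code{mode = "separate"} fits one single-GRM REML per chromosome (each
#' against its own residual) and reports the summed total;
#' \code{mode = "joint"} fits all chromosome GRMs in one model. Absent
#' chromosomes are skipped with a notice.
#'
#' @inheritParams partitioned_reml
#' @param mode \code{"separate"} or \code{"joint"}.
#' @return for \code{"separate"}: list with \code{table} (chromosome,
#'   n_snps, h2 observed/liability, SE, LRT p) and \code{summed_h2};
#'   for \code{"joint"}: a \code{partition_result}.
#' @export
per_chromosome_analysis <- function(g, y, X = NULL,
                                    mode = c("separate", "joint"),
                                    K = NULL, options = list()) {
  mode <- match.arg(mode)
  spec <- make_chromosome_partition(g)
  if (mode == "joint")
    return(partitioned_reml(g, spec, y, X, K = K, options = options))
  lp <- if (!is.null(K)) liability_params(K, mean(y)) else NULL
  rows <- lapply(seq_along(spec$labels), function(k) {
    mask <- spec$masks[[k]]
    grm_k <- compute_grm(g, mask, snp_set = spec$labels[k])
    fit <- reml_fit(grm_k, y, X, options = options)
    null_ll <- reml_null_loglik(y, prep_X(X, length(y)))
    lrt_p <- 0.5 * stats::pchisq(max(0, 2 * (fit$loglik - null_ll)), 1,
                                 lower.tail = FALSE)
    h2o <- fit$h2_observed$total; seo <- fit$h2_observed$se_total
    if (!is.null(lp)) {
      tr <- observed_to_liability(h2o, seo, lp)
      h2l <- tr$h2_liab; sel <- tr$se_liab
    } else { h2l <- h2o; sel <- seo }
    data.frame(chromosome = spec$chromosomes[k], n_snps = sum(mask),
               h2_observed = h2o, se_observed = seo,
               h2_liability = h2l, se_liability = sel, lrt_p = lrt_p)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, summed_h2 = sum(tab$h2_liability),
       summed_h2_observed = sum(tab$h2_observed))
}

# restricted log-likelihood of the covariates-only model (sigma_g = 0),
# profiled residual variance; used for single-component LRTs
reml_null_loglik <- function(y, X) {
  n <- length(y); p <- ncol(X)
  qr_x <- qr(X)
  res <- qr.resid(qr_x, y)
  s2 <- sum(res^2) / (n - p)
  R <- qr.R(qr_x)
  # -0.5 [ n log s2 + log|X'X / s2| + (n - p) ] with X'X from R'R
  as.numeric(-0.5 * (n * log(s2) + (2 * sum(log(abs(diag(R)))) - p * log(s2)) +
                     (n - p)))
}

#' Expected per-chromosome heritability under a uniform polygenic model
#'
#' Expected heritability proportional to each chromosome's weight (SNP or
#' gene count): \eqn{E_c = h^2 w_c / \sum w}. If observed estimates and
#' SEs are supplied, chromosomes with \eqn{|obs - exp| > 1.96 \, se} are
#' flagged.
#'
#' @param total_h2 genome-wide heritability.
#' @param weights per-chromosome weights, sum > 0.
#' @param observed,se optional observed per-chromosome estimates and SEs.
#' @return data.frame with \code{weight}, \code{expected} and, when
#'   observed values are given, \code{observed}, \code{se},
#'   \code{deviates}.
#' @export
expected_chromosome_h2 <- function(total_h2, weights, observed = NULL,
                                   se = NULL) {
  if (sum(weights) <= 0)
    stop_snpher("snpher_precondition_error", "weights must sum > 0")
  expd <- total_h2 * weights / sum(weights)
  out <- data.frame(weight = weights, expected = expd)
  if (!is.null(observed)) {
    out$observed <- observed
    out$se <- se
    out$deviates <- abs(observed - expd) > 1.96 * se
  }
  out
}

#' Correlation between chromosome length and heritability
#'
#' Pearson correlation with a two-sided p-value; optionally repeated
#' leaving one chromosome out at a time.
#'
#' @param observed_h2 per-chromosome heritability estimates (>= 3 values).
#' @param lengths chromosome lengths (same order).
#' @param leave_one_out also compute each leave-one-out correlation?
#' @return list with \code{r}, \code{p} and optionally
#'   \code{leave_one_out} (data.frame dropped / r / p).
#' @export
chromosome_length_correlation <- function(observed_h2, lengths,
                                          leave_one_out = FALSE) {
  if (length(observed_h2) < 3)
    stop_snpher("snpher_precondition_error", "need at least 3 chromosomes")
  if (stats::sd(observed_h2) == 0 || stats::sd(lengths) == 0)
    return(list(r = NA_real_, p = NA_real_, flag = "zero variance"))
  ct <- stats::cor.test(observed_h2, lengths)
  out <- list(r = unname(ct$estimate), p = ct$p.value)
  if (leave_one_out) {
    loo <- lapply(seq_along(observed_h2), function(i) {
      cti <- stats::cor.test(observed_h2[-i], lengths[-i])
      data.frame(dropped = i, r = unname(cti$estimate), p = cti$p.value)
    })
    out$leave_one_out <- do.call(rbind, loo)
  }
  out
}

#' Write a partition result table as TSV
#'
#' @param result a \code{partition_result}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_partition_table <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
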