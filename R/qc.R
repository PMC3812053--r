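#' Default QC thresholds
#'
#' The stringent SNP- and sample-level thresholds used throughout:
#' differential case/control missingness p < 0.05, Hardy-Weinberg exact
#' p < 0.05, platform-association p < 0.001 after adjustment for ten
#' principal components, sample call rate >= 99.9%, and pairwise
#' relatedness (pi-hat, operationalized as the GRM off-diagonal) <= 0.05.
#'
#' @param diff_missingness_p,hwe_p,platform_p,sample_call_rate,pihat_max,n_platform_pcs
#'   threshold overrides.
#' @return a named list of thresholds.
#' @export
qc_thresholds <- function(diff_missingness_p = 0.05, hwe_p = 0.05,
                          platform_p = 0.001, sample_call_rate = 0.999,
                          pihat_max = 0.05, n_platform_pcs = 10) {
  ps <- c(diff_missingness_p, hwe_p, platform_p)
  if (any(ps <= 0 | ps >= 1))
    stop_snpher("snpher_config_error", "p thresholds must lie in (0, 1)")
  if (sample_call_rate <= 0 || sample_call_rate > 1)
    stop_snpher("snpher_config_error", "sample_call_rate must lie in (0, 1]")
  list(diff_missingness_p = diff_missingness_p, hwe_p = hwe_p,
       platform_p = platform_p, sample_call_rate = sample_call_rate,
       pihat_max = pihat_max, n_platform_pcs = n_platform_pcs)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value
#' is the sum of probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed table
#' (no mid-p adjustment). Monomorphic sites return 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (min(n_AA, n_Aa, n_aa) < 0 || n_AA + n_Aa + n_aa < 1)
    stop_snpher("snpher_precondition_error", "counts must be >= 0 with total >= 1")
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa          # minor-ish allele count (either is fine)
  if (n_a == 0 || n_a == 2 * n) return(1.0)
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)   # feasible heterozygote counts
  # P(het = h | n, rare) up to a constant, via log factorials
  logp <- lgamma(n + 1) - lgamma(hets + 1) -
    lgamma((rare - hets) / 2 + 1) - lgamma(n - (rare + hets) / 2 + 1) +
    hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  if (is.na(obs))  # observed het count infeasible for these allele counts
    stop_snpher("snpher_precondition_error", "inconsistent genotype counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Differential missingness test
#'
#' Two-sided Fisher exact test on the 2x2 missing / non-missing by
#' case / control table. A degenerate table (no observations) returns 1.
#'
#' @param miss_cases,tot_cases missing and total calls in cases.
#' @param miss_controls,tot_controls same for controls.
#' @return p-value.
#' @export
differential_missingness_test <- function(miss_cases, tot_cases,
                                          miss_controls, tot_controls) {
  if (miss_cases > tot_cases || miss_controls > tot_controls)
    stop_snpher("snpher_precondition_error", "missing count exceeds total")
  if (tot_cases == 0 || tot_controls == 0) return(1.0)
  tab <- matrix(c(miss_cases, tot_cases - miss_cases,
                  miss_controls, tot_controls - miss_controls), 2)
  stats::fisher.test(tab)$p.value
}

#' Per-SNP platform-association scan
#'
#' For each SNP, logistic regression of platform membership on genotype
#' dosage plus principal components; the Wald p-value of the genotype term
#' screens for batch/platform artifacts. Constant genotypes and
#' non-convergent or separated fits are flagged (flagged SNPs are treated
#' as failing QC by \code{\link{run_qc}} when their p is below threshold
#' or the fit failed).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param platform_labels two-level factor/character over samples.
#' @param pcs optional n x k matrix of covariate PCs.
#' @return data.frame with \code{snp}, \code{p}, \code{flag}.
#' @export
platform_association_scan <- function(g, platform_labels, pcs = NULL) {
  lev <- unique(platform_labels)
  if (length(lev) != 2)
    stop_snpher("snpher_precondition_error", "need exactly two platform groups")
  yy <- as.integer(platform_labels == lev[2])
  n <- n_samples(g)
  base <- if (is.null(pcs)) matrix(1, n, 1) else cbind(1, as.matrix(pcs))
  if (ncol(base) > 1) {
    # massive batch artifacts can make the PCs themselves separate the
    # platforms, leaving no genotype term to test; fall back to the
    # unadjusted scan in that case
    null_fit <- suppressWarnings(stats::glm.fit(base, yy,
                                                family = stats::binomial()))
    if (all(abs(null_fit$fitted.values - yy) < 1e-3)) {
      warning("principal components separate the platform groups; scanning without PC adjustment")
      base <- matrix(1, n, 1)
    }
  }
  m <- n_snps(g)
  p_out <- rep(NA_real_, m); flag <- character(m)
  for (j in seq_len(m)) {
    x <- g$calls[, j]
    ok <- !is.na(x)
    if (stats::sd(x[ok]) == 0) {
      p_out[j] <- 1; flag[j] <- "constant"
      next
    }
    Xj <- cbind(base[ok, , drop = FALSE], x[ok])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(Xj, yy[ok], family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      p_out[j] <- 0; flag[j] <- "nonconverged"
      next
    }
    # Wald test from the unscaled covariance of the IRLS fit
    covb <- tryCatch({
      cp <- chol2inv(qr.R(fit$qr))
      out <- matrix(NA_real_, ncol(Xj), ncol(Xj))
      piv <- fit$qr$pivot
      out[piv, piv] <- cp
      out
    }, error = function(e) NULL)
    if (is.null(covb)) { p_out[j] <- 0; flag[j] <- "singular"; next }
    se <- sqrt(diag(covb))[ncol(Xj)]
    if (!is.finite(se) || se > 100) { p_out[j] <- 0; flag[j] <- "separation"; next }
    zstat <- fit$coefficients[ncol(Xj)] / se
    p_out[j] <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
    flag[j] <- ""
  }
  data.frame(snp = g$snps$id, p = p_out, flag = flag, stringsAsFactors = FALSE)
}

#' Sample call-rate filter
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param threshold minimum non-missing genotype fraction per sample.
#' @return character vector of kept \code{iid}s.
#' @export
sample_call_rate_filter <- function(g, threshold = 0.999) {
  rate <- rowMeans(!is.na(g$calls))
  g$samples$iid[rate >= threshold]
}

#' Greedy relatedness pruning
#'
#' Iteratively removes the individual involved in the largest number of
#' pairs whose relatedness (GRM off-diagonal, the pi-hat proxy) exceeds
#' the threshold until no such pair remains. Ties are broken by priority
#' (cases are kept over controls) and then by lexicographic id (the
#' later-sorting id is removed).
#'
#' @param grm a \code{grm} object.
#' @param pihat_max relatedness threshold.
#' @param priority optional logical vector (TRUE = preferentially kept,
#'   e.g. case status), aligned with \code{grm$ids}.
#' @return integer indices (into \code{grm$ids}) of kept individuals.
#' @export
prune_related <- function(grm, pihat_max = 0.05, priority = NULL) {
  n <- nrow(grm$A)
  priority <- priority %||% rep(FALSE, n)
  adj <- grm$A > pihat_max
  diag(adj) <- FALSE
  keep <- rep(TRUE, n)
  ids <- grm$ids$iid
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE]) * keep
    if (max(deg) == 0) break
    cand <- which(deg == max(deg))
    # drop non-priority first, then the lexicographically last id
    cand <- cand[order(priority[cand], -xtfrm(ids[cand]))]
    drop <- cand[1]
    keep[drop] <- FALSE
    adj[drop, ] <- FALSE; adj[, drop] <- FALSE
  }
  which(keep)
}

#' Run the full QC pipeline
#'
#' Fixed filter order: SNP missingness/monomorphism, differential
#' missingness between cases and controls, Hardy-Weinberg exact test
#' (pooled sample by default, controls-only optionally), platform
#' association scan (when platform labels are given), sample call rate,
#' and relatedness pruning. Each dropped SNP or sample records exactly one
#' primary reason: the first failing test in this order. Running the
#' pipeline on its own output changes nothing.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param phenotype 0/1 vector aligned with samples (1 = case).
#' @param thresholds from \code{\link{qc_thresholds}}.
#' @param platform_labels optional two-level vector for the platform scan.
#' @param hwe_mode \code{"pooled"} or \code{"controls"}.
#' @param snp_call_rate minimum per-SNP call rate (default 0.95).
#' @return list of class \code{qc_report}: \code{genotypes} (filtered),
#'   \code{phenotype} (filtered), \code{snp_table}, \code{sample_table},
#'   \code{n_snps_kept}, \code{n_samples_kept}.
#' @export
run_qc <- function(g, phenotype, thresholds = qc_thresholds(),
                   platform_labels = NULL, hwe_mode = c("pooled", "controls"),
                   snp_call_rate = 0.95) {
  hwe_mode <- match.arg(hwe_mode)
  m0 <- n_snps(g); n0 <- n_samples(g)
  snp_reason <- character(m0); sample_reason <- character(n0)
  snp_keep0 <- seq_len(m0); sample_keep0 <- seq_len(n0)
  pvals0 <- NULL
  gg <- g; ph <- phenotype; pl <- platform_labels
  # iterate SNP- and sample-level passes to a fixed point so that the
  # reported filters are self-consistent on the final analysis set (and a
  # second invocation of run_qc drops nothing)
  for (pass in 1:5) {
    one <- qc_pass(gg, ph, thresholds, pl, hwe_mode, snp_call_rate)
    if (pass == 1) pvals0 <- one$pvals
    sdrop <- one$snp_reason != ""
    idrop <- one$sample_reason != ""
    snp_reason[snp_keep0[sdrop]] <- one$snp_reason[sdrop]
    sample_reason[sample_keep0[idrop]] <- one$sample_reason[idrop]
    if (!any(sdrop) && !any(idrop)) break
    snp_keep0 <- snp_keep0[!sdrop]
    sample_keep0 <- sample_keep0[!idrop]
    gg <- subset_genotypes(gg, samples = which(!idrop), snps = which(!sdrop))
    ph <- ph[!idrop]
    if (!is.null(pl)) pl <- pl[!idrop]
  }
  structure(list(
    genotypes = gg,
    phenotype = ph,
    snp_table = cbind(pvals0, dropped_reason = snp_reason),
    sample_table = data.frame(fid = g$samples$fid, iid = g$samples$iid,
                              dropped_reason = sample_reason,
                              stringsAsFactors = FALSE),
    n_snps_kept = length(snp_keep0), n_samples_kept = length(sample_keep0)),
    class = "qc_report")
}

qc_pass <- function(g, phenotype, thresholds, platform_labels, hwe_mode,
                    snp_call_rate) {
  m <- n_snps(g); n <- n_samples(g)
  reason <- character(m)
  pvals <- data.frame(snp = g$snps$id, p_missingness = NA_real_,
                      p_hwe = NA_real_, p_platform = NA_real_,
                      stringsAsFactors = FALSE)

  call_rate <- colMeans(!is.na(g$calls))
  mono <- g$maf == 0 | is.na(g$maf)
  reason[call_rate < snp_call_rate] <- "snp_call_rate"
  reason[reason == "" & mono] <- "monomorphic"

  is_case <- phenotype == 1
  miss <- is.na(g$calls)
  mc <- colSums(miss[is_case, , drop = FALSE])
  mt <- colSums(miss[!is_case, , drop = FALSE])
  nc <- sum(is_case); nt <- sum(!is_case)
  for (j in which(reason == "")) {
    pvals$p_missingness[j] <-
      if (mc[j] + mt[j] == 0) 1
      else differential_missingness_test(mc[j], nc, mt[j], nt)
  }
  reason[reason == "" & !is.na(pvals$p_missingness) &
           pvals$p_missingness < thresholds$diff_missingness_p] <- "diff_missingness"

  hwe_rows <- if (hwe_mode == "pooled") rep(TRUE, n) else !is_case
  for (j in which(reason == "")) {
    x <- g$calls[hwe_rows, j]
    x <- x[!is.na(x)]
    pvals$p_hwe[j] <- hwe_exact_test(sum(x == 2), sum(x == 1), sum(x == 0))
  }
  reason[reason == "" & !is.na(pvals$p_hwe) &
           pvals$p_hwe < thresholds$hwe_p] <- "hwe"

  if (!is.null(platform_labels)) {
    keep_j <- which(reason == "")
    sub <- subset_genotypes(g, snps = keep_j)
    pcs <- NULL
    if (thresholds$n_platform_pcs > 0) {
      grm_all <- compute_grm(sub)
      pcs <- grm_pca(grm_all, min(thresholds$n_platform_pcs,
                                  n_samples(sub) - 1))$vectors
    }
    scan <- platform_association_scan(sub, platform_labels, pcs)
    pvals$p_platform[keep_j] <- scan$p
    fails <- scan$p < thresholds$platform_p | scan$flag %in%
      c("nonconverged", "singular", "separation")
    reason[keep_j][fails] <- "platform"
  }

  snp_keep <- reason == ""
  sample_reason <- character(n)
  if (any(snp_keep)) {
    g2 <- subset_genotypes(g, snps = which(snp_keep))
    rate <- rowMeans(!is.na(g2$calls))
    sample_reason[rate < thresholds$sample_call_rate] <- "sample_call_rate"
    pre_keep <- which(sample_reason == "")
    if (length(pre_keep) == 0)
      stop_snpher("snpher_precondition_error",
                  "every sample fails the %.4f call-rate threshold",
                  thresholds$sample_call_rate)
    g3 <- subset_genotypes(g2, samples = pre_keep)
    grm3 <- compute_grm(g3)
    kept_rel <- prune_related(grm3, thresholds$pihat_max,
                              priority = phenotype[pre_keep] == 1)
    rel_drop <- setdiff(seq_along(pre_keep), kept_rel)
    sample_reason[pre_keep[rel_drop]] <- "relatedness"
  } else {
    stop_snpher("snpher_precondition_error",
                "QC dropped every SNP; thresholds are incompatible with these data")
  }
  list(snp_reason = reason, sample_reason = sample_reason, pvals = pvals)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: kept %d SNPs, %d samples\n",
              x$n_snps_kept, x$n_samples_kept))
  st <- table(x$snp_table$dropped_reason)
  st <- st[names(st) != ""]
  if (length(st)) cat("  SNP drops:", paste(sprintf("%s=%d", names(st), st),
                                            collapse = ", "), "\n")
  ss <- table(x$sample_table$dropped_reason)
  ss <- ss[names(ss) != ""]
  if (length(ss)) cat("  sample drops:", paste(sprintf("%s=%d", names(ss), ss),
                                               collapse = ", "), "\n")
  invisible(x)
}

#' Write the QC report tables as TSV
#'
#' @param report a \code{qc_report}.
#' @param prefix output prefix; writes \code{<prefix>.snps.tsv} and
#'   \code{<prefix>.samples.tsv}.
#' @return \code{prefix}, invisibly.
#' @export
write_qc_report <- function(report, prefix) {
  utils::write.table(report$snp_table, paste0(prefix, ".snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$sample_table, paste0(prefix, ".samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
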