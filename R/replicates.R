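#' Replicate simulation studies for pipeline validation
#'
#' Each function simulates a series of independent case-control datasets
#' under an \code{\link{architecture}}, runs the corresponding analysis
#' pipeline on every replicate, and summarizes the estimates. They are the
#' package's standard way to verify, by parameter recovery, that the
#' GRM + AI-REML + liability-transform chain behaves as expected under a
#' given genetic architecture and ascertainment scheme.
#'
#' @param arch an \code{\link{architecture}}.
#' @param n_cases,n_controls ascertained sample composition per replicate.
#' @param n_snps SNP panel size.
#' @param n_reps number of replicates.
#' @param seed integer master seed; replicate r uses derived seeds.
#' @param n_pcs number of GRM PCs used as fixed effects (0 = intercept
#'   only).
#' @param maf_spectrum spectrum for the simulated panel.
#' @param options optimizer options passed through.
#' @return \code{replicate_univariate_recovery}: list with \code{per_rep}
#'   (data.frame of per-replicate observed- and liability-scale estimates)
#'   and \code{mean_h2_liab}, \code{sd_h2_liab}.
#' @name replicate_studies
NULL

#' @rdname replicate_studies
#' @export
replicate_univariate_recovery <- function(arch, n_cases, n_controls,
                                          n_snps = 5000, n_reps = 10,
                                          seed = 1, n_pcs = 0,
                                          maf_spectrum = maf_uniform(),
                                          options = list()) {
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- (seed %% 100000L) * 10000L + r * 131L
    cfg <- sim_config(n_snps = n_snps, maf_spectrum = maf_spectrum,
                      n_cases = n_cases, n_controls = n_controls, seed = s)
    g <- simulate_genotypes(cfg)
    ps <- simulate_liability_phenotype(g, arch, seed = s + 1L)
    rep <- run_univariate_study(ps$genotypes, ps$phenotype,
                                K = arch$prevalence_K, n_pcs = n_pcs,
                                options = options)
    data.frame(rep = r, h2_obs = rep$h2_obs, se_obs = rep$se_obs,
               h2_liab = rep$h2_liab, se_liab = rep$se_liab,
               converged = rep$fit$converged)
  })
  per <- do.call(rbind, rows)
  list(per_rep = per, mean_h2_liab = mean(per$h2_liab),
       sd_h2_liab = stats::sd(per$h2_liab))
}

#' @rdname replicate_studies
#' @param n1_cases,n1_controls,n2_cases,n2_controls per-trait sample
#'   compositions for the bivariate design.
#' @return \code{replicate_bivariate_recovery}: list with \code{per_rep}
#'   (per-replicate \code{rg}, \code{se_rg}) and \code{mean_rg}.
#' @export
replicate_bivariate_recovery <- function(arch, n1_cases, n1_controls,
                                         n2_cases, n2_controls,
                                         n_snps = 5000, n_reps = 10,
                                         seed = 1, options = list()) {
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- (seed %% 100000L) * 10000L + r * 151L
    cfg <- sim_config(n_snps = n_snps, n_cases = n1_cases,
                      n_controls = n1_controls, seed = s)
    g1 <- simulate_genotypes(cfg, id_prefix = "A")
    g2 <- clone_panel(g1, n2_cases, n2_controls, seed = s + 1L,
                      id_prefix = "B")
    bv <- simulate_bivariate(g1, g2, arch, seed = s + 2L)
    G <- combine_genotypes(bv$trait1$genotypes, bv$trait2$genotypes)
    p1 <- data.frame(bv$trait1$genotypes$samples, status = bv$trait1$phenotype)
    p2 <- data.frame(bv$trait2$genotypes$samples, status = bv$trait2$phenotype)
    fit <- bivar_reml_fit(G, p1, p2, options = options)
    data.frame(rep = r, rg = fit$rg, se_rg = fit$se_rg,
               h2_obs1 = fit$h2_observed[["trait1"]],
               h2_obs2 = fit$h2_observed[["trait2"]],
               converged = fit$converged)
  })
  per <- do.call(rbind, rows)
  list(per_rep = per, mean_rg = mean(per$rg), sd_rg = stats::sd(per$rg))
}

#' @rdname replicate_studies
#' @param edges MAF bin edges for the joint partitioned fit.
#' @return \code{replicate_maf_recovery}: list with \code{per_rep}
#'   (per-replicate share of each bin), \code{mean_shares} and
#'   \code{mean_rare_share} (share of the lowest bin).
#' @export
replicate_maf_recovery <- function(arch, n_cases, n_controls,
                                   n_snps = 5000, n_reps = 10, seed = 1,
                                   edges = default_maf_edges(),
                                   maf_spectrum = maf_binned(),
                                   options = list()) {
  nb <- length(edges) - 1
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- (seed %% 100000L) * 10000L + r * 163L
    cfg <- sim_config(n_snps = n_snps, maf_spectrum = maf_spectrum,
                      n_cases = n_cases, n_controls = n_controls, seed = s)
    g <- simulate_genotypes(cfg)
    ps <- simulate_liability_phenotype(g, arch, seed = s + 1L)
    spec <- suppressWarnings(make_maf_bins(ps$genotypes, edges))
    res <- partitioned_reml(ps$genotypes, spec, ps$phenotype,
                            K = arch$prevalence_K, options = options)
    shares <- stats::setNames(rep(NA_real_, nb), spec$labels)
    shares[res$table$partition] <- res$table$share
    cbind(data.frame(rep = r), as.data.frame(as.list(shares),
                                             check.names = FALSE))
  })
  per <- do.call(rbind, rows)
  ms <- colMeans(per[, -1, drop = FALSE], na.rm = TRUE)
  list(per_rep = per, mean_shares = ms, mean_rare_share = unname(ms[1]))
}

#' @rdname replicate_studies
#' @param genic_fraction fraction of panel SNPs flagged genic.
#' @return \code{replicate_annotation_recovery}: list with \code{per_rep}
#'   and \code{mean_share} (share of the first annotation partition).
#' @export
replicate_annotation_recovery <- function(arch, n_cases, n_controls,
                                          n_snps = 5000, n_reps = 10,
                                          seed = 1, genic_fraction = 0.5,
                                          options = list()) {
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- (seed %% 100000L) * 10000L + r * 173L
    cfg <- sim_config(n_snps = n_snps, n_cases = n_cases,
                      n_controls = n_controls,
                      annotation_probs = c(genic = genic_fraction), seed = s)
    g <- simulate_genotypes(cfg)
    ps <- simulate_liability_phenotype(g, arch, seed = s + 1L)
    spec <- make_annotation_partition(ps$genotypes, "genic", "intergenic")
    res <- partitioned_reml(ps$genotypes, spec, ps$phenotype,
                            K = arch$prevalence_K, options = options)
    data.frame(rep = r,
               share = res$table$share[res$table$partition == "genic"],
               h2_total = res$total_h2)
  })
  per <- do.call(rbind, rows)
  list(per_rep = per, mean_share = mean(per$share))
}
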