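#' Run the full univariate heritability study
#'
#' End-to-end flow for one case-control trait: optional QC, GRM, principal
#' components, AI-REML with intercept plus top PCs as fixed effects,
#' boundary-aware likelihood-ratio test, and conversion of the
#' observed-scale estimate to the liability scale at prevalence K with
#' the realized sample case fraction.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param phenotype 0/1 vector (1 = case) aligned with samples.
#' @param K population prevalence.
#' @param n_pcs number of GRM principal components used as covariates
#'   (default 20).
#' @param qc run \code{\link{run_qc}} first? (logical, default FALSE for
#'   clean simulated inputs).
#' @param qc_thresholds thresholds when \code{qc = TRUE}.
#' @param platform_labels optional platform labels forwarded to QC.
#' @param options optimizer options.
#' @return list of class \code{study_report}: \code{fit}, \code{lrt},
#'   \code{h2_liab}, \code{se_liab}, \code{factor}, \code{K}, \code{P},
#'   \code{n}, \code{n_snps}, \code{qc} (the \code{qc_report} or NULL).
#' @export
run_univariate_study <- function(g, phenotype, K, n_pcs = 20,
                                 qc = FALSE, qc_thresholds = qc_thresholds(),
                                 platform_labels = NULL, options = list()) {
  if (length(phenotype) != n_samples(g))
    stop_snpher("snpher_precondition_error",
                "phenotype length %d != %d samples", length(phenotype), n_samples(g))
  if (stats::var(phenotype) == 0)
    stop_snpher("snpher_precondition_error", "phenotype has zero variance")
  qc_rep <- NULL
  if (qc) {
    qc_rep <- run_qc(g, phenotype, thresholds = qc_thresholds,
                     platform_labels = platform_labels)
    g <- qc_rep$genotypes
    phenotype <- qc_rep$phenotype
  }
  grm <- compute_grm(g)
  X <- NULL
  if (n_pcs > 0) X <- grm_pca(grm, min(n_pcs, n_samples(g) - 2))$vectors
  fit <- reml_fit(grm, phenotype, X, options = options)
  null_ll <- reml_null_loglik(phenotype, prep_X(X, length(phenotype)))
  lrt_stat <- max(0, 2 * (fit$loglik - null_ll))
  lrt <- list(statistic = lrt_stat,
              p_mixture = 0.5 * stats::pchisq(lrt_stat, 1, lower.tail = FALSE),
              p_chisq1 = stats::pchisq(lrt_stat, 1, lower.tail = FALSE))
  P <- mean(phenotype)
  lp <- liability_params(K, P)
  tr <- observed_to_liability(fit$h2_observed$total, fit$h2_observed$se_total, lp)
  structure(list(fit = fit, lrt = lrt, h2_obs = fit$h2_observed$total,
                 se_obs = fit$h2_observed$se_total,
                 h2_liab = tr$h2_liab, se_liab = tr$se_liab,
                 factor = tr$factor, K = K, P = P,
                 n = length(phenotype), n_snps = n_snps(g), qc = qc_rep),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("univariate study: n = %d (%d cases), %d SNPs\n",
              x$n, round(x$P * x$n), x$n_snps))
  cat(sprintf("  h2 observed  %.4f (se %.4f)\n", x$h2_obs, x$se_obs))
  cat(sprintf("  h2 liability %.4f (se %.4f)  [K = %g, P = %.4f, factor %.4f]\n",
              x$h2_liab, x$se_liab, x$K, x$P, x$factor))
  cat(sprintf("  LRT %.3f, p = %.3g (boundary mixture) / %.3g (chi-square 1)\n",
              x$lrt$statistic, x$lrt$p_mixture, x$lrt$p_chisq1))
  invisible(x)
}

#' Permutation null of the univariate analysis
#'
#' Permutes case/control labels among the analysis samples (preserving
#' case and control counts; covariates stay attached to individuals),
#' refits the REML model for each permutation, and summarizes the
#' liability-scale estimates. The GRM and its eigendecomposition are
#' computed once and shared across permutations.
#'
#' @inheritParams run_univariate_study
#' @param n_perm number of permutations (default 10).
#' @param seed integer seed for the permutation stream.
#' @return list: \code{per_perm} (data.frame h2_obs, h2_liab, lrt_p),
#'   \code{mean_h2_liab}, \code{sd_h2_liab}.
#' @export
permutation_null <- function(g, phenotype, K, n_perm = 10, seed = 1,
                             n_pcs = 20, options = list()) {
  if (n_perm < 1) stop_snpher("snpher_config_error", "n_perm must be >= 1")
  grm <- compute_grm(g)
  X <- NULL
  if (n_pcs > 0) X <- grm_pca(grm, min(n_pcs, n_samples(g) - 2))$vectors
  Xf <- prep_X(X, length(phenotype))
  P <- mean(phenotype)
  lp <- liability_params(K, P)
  set.seed(stream_seed(seed, "perm"))
  rows <- lapply(seq_len(n_perm), function(b) {
    yp <- sample(phenotype)
    fit <- reml_fit(grm, yp, X, options = options)
    null_ll <- reml_null_loglik(yp, Xf)
    stat <- max(0, 2 * (fit$loglik - null_ll))
    tr <- observed_to_liability(fit$h2_observed$total,
                                fit$h2_observed$se_total, lp)
    data.frame(perm = b, h2_obs = fit$h2_observed$total,
               h2_liab = tr$h2_liab, se_liab = tr$se_liab,
               lrt_p = 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE),
               boundary = fit$boundary_flags[1])
  })
  per <- do.call(rbind, rows)
  list(per_perm = per, mean_h2_liab = mean(per$h2_liab),
       sd_h2_liab = stats::sd(per$h2_liab),
       mean_h2_obs = mean(per$h2_obs))
}

#' Platform dummy case-control analysis
#'
#' Treats platform membership as the phenotype within a control-only
#' sample and runs the univariate pipeline. On clean data the estimate
#' sits at the variance floor; injected platform artifacts inflate it,
#' and QC should restore the null.
#'
#' @param g a \code{\link{genotype_matrix}} of controls.
#' @param platform_labels two-level vector over samples.
#' @inheritParams run_univariate_study
#' @return a \code{study_report} (liability transform at K = sample
#'   fraction, i.e. no ascertainment correction).
#' @export
platform_dummy_analysis <- function(g, platform_labels, n_pcs = 20,
                                    qc = FALSE,
                                    qc_thresholds = qc_thresholds(),
                                    options = list()) {
  lev <- unique(platform_labels)
  if (length(lev) != 2)
    stop_snpher("snpher_precondition_error", "need exactly two platform groups")
  y <- as.integer(platform_labels == lev[2])
  run_univariate_study(g, y, K = mean(y), n_pcs = n_pcs, qc = qc,
                       qc_thresholds = qc_thresholds,
                       platform_labels = if (qc) platform_labels else NULL,
                       options = options)
}

#' Write a JSON run manifest
#'
#' Records package version, R version, seed, timestamp and any
#' caller-supplied settings next to a pipeline's outputs, so a run can be
#' reproduced exactly.
#'
#' @param path output JSON file.
#' @param seed the seed the run used.
#' @param settings named list of run settings worth recording.
#' @return \code{path}, invisibly.
#' @export
write_run_manifest <- function(path, seed, settings = list()) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop_snpher("snpher_config_error", "jsonlite is required for manifests")
  manifest <- c(list(
    package = "snpher",
    version = as.character(utils::packageVersion("snpher")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    settings)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Age-of-onset split analysis
#'
#' Splits cases at an onset cutoff (early: onset <= cutoff; adult:
#' onset > cutoff), analyzes each case subset against the full control
#' set, and reports how many cases were excluded for missing onset.
#'
#' @inheritParams run_univariate_study
#' @param onset numeric onset age per sample (NA for controls and for
#'   cases with missing onset).
#' @param cutoff onset threshold (default 16).
#' @return list: \code{early}, \code{adult} (each a \code{study_report}
#'   or NULL when the stratum is empty), \code{n_early}, \code{n_adult},
#'   \code{n_missing_onset}.
#' @export
age_of_onset_split <- function(g, phenotype, onset, K, cutoff = 16,
                               n_pcs = 20, options = list()) {
  is_case <- phenotype == 1
  if (all(is.na(onset[is_case])))
    stop_snpher("snpher_precondition_error", "all cases have missing onset")
  early_case <- is_case & !is.na(onset) & onset <= cutoff
  adult_case <- is_case & !is.na(onset) & onset > cutoff
  missing_case <- is_case & is.na(onset)
  ctrl <- !is_case
  fit_stratum <- function(case_mask) {
    if (!any(case_mask)) return(NULL)
    sel <- which(case_mask | ctrl)
    run_univariate_study(subset_genotypes(g, samples = sel),
                         phenotype[sel], K, n_pcs = n_pcs,
                         options = options)
  }
  early <- fit_stratum(early_case)
  adult <- fit_stratum(adult_case)
  if (is.null(adult)) message("adult-onset stratum is empty")
  if (is.null(early)) message("early-onset stratum is empty")
  list(early = early, adult = adult,
       n_early = sum(early_case), n_adult = sum(adult_case),
       n_missing_onset = sum(missing_case))
}
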