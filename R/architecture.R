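#' Genetic architecture of a simulated liability-threshold trait
#'
#' An architecture fixes the truth underlying a simulation: total
#' narrow-sense heritability on the liability scale, population prevalence
#' K, how the genetic variance is split over SNP partitions, and how many
#' causal SNPs carry each partition's share. Bivariate architectures add a
#' genetic correlation and the second trait's heritability and prevalence.
#'
#' @param name identifier.
#' @param h2_liability true liability-scale heritability in [0, 1].
#' @param prevalence_K population prevalence in (0, 1).
#' @param partition_shares named numeric vector of genetic-variance shares;
#'   must sum to 1. Names refer to SNP partitions: \code{"all"}, an
#'   annotation name, or a MAF bin label \code{"maf_bin1"} ...
#'   \code{"maf_bin6"} (bins at the default edges, see
#'   \code{\link{default_maf_edges}}).
#' @param n_causal_per_partition named integer vector, causal SNP count per
#'   partition; every partition with positive share needs at least one.
#' @param rg genetic correlation in [-1, 1] for bivariate architectures,
#'   or NULL.
#' @param h2_liability2,prevalence_K2 second-trait truth for bivariate
#'   architectures.
#' @return an object of class \code{architecture}.
#' @export
architecture <- function(name, h2_liability, prevalence_K,
                         partition_shares = c(all = 1),
                         n_causal_per_partition = NULL,
                         rg = NULL, h2_liability2 = NULL,
                         prevalence_K2 = NULL) {
  if (h2_liability < 0 || h2_liability > 1)
    stop_snpher("snpher_config_error", "h2_liability must lie in [0, 1]")
  if (prevalence_K <= 0 || prevalence_K >= 1)
    stop_snpher("snpher_config_error", "prevalence_K must lie in (0, 1)")
  if (abs(sum(partition_shares) - 1) > 1e-12)
    stop_snpher("snpher_config_error", "partition_shares must sum to 1 (got %g)",
                sum(partition_shares))
  if (is.null(n_causal_per_partition)) {
    n_causal_per_partition <- ifelse(partition_shares > 0, 100L, 0L)
    names(n_causal_per_partition) <- names(partition_shares)
  }
  if (!setequal(names(n_causal_per_partition), names(partition_shares)))
    stop_snpher("snpher_config_error", "n_causal_per_partition names must match partition_shares")
  n_causal_per_partition <- n_causal_per_partition[names(partition_shares)]
  if (any(partition_shares > 0 & n_causal_per_partition < 1))
    stop_snpher("snpher_config_error", "every partition with positive share needs n_causal >= 1")
  if (!is.null(rg) && abs(rg) > 1)
    stop_snpher("snpher_config_error", "rg must lie in [-1, 1]")
  structure(list(name = name, h2_liability = h2_liability,
                 prevalence_K = prevalence_K,
                 partition_shares = partition_shares,
                 n_causal_per_partition = n_causal_per_partition,
                 rg = rg, h2_liability2 = h2_liability2,
                 prevalence_K2 = prevalence_K2),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf("architecture '%s': h2_liability = %.3g, K = %.3g\n",
              x$name, x$h2_liability, x$prevalence_K))
  cat("  shares:", paste(sprintf("%s=%.3g", names(x$partition_shares),
                                 x$partition_shares), collapse = ", "), "\n")
  if (!is.null(x$rg))
    cat(sprintf("  bivariate: rg = %.3g, h2_2 = %.3g, K2 = %.3g\n",
                x$rg, x$h2_liability2, x$prevalence_K2))
  invisible(x)
}

#' Shipped architecture presets
#'
#' Presets whose true values are the study estimates for Tourette Syndrome
#' (TS) and obsessive-compulsive disorder (OCD): TS liability heritability
#' 0.58 at prevalence 0.008; OCD 0.37 at prevalence 0.025; a rare-MAF
#' (0.001-0.05) tranche carrying 21% of TS genetic variance and 0% of OCD
#' genetic variance; genic shares of 53% (TS) and 40% (OCD); a TS-OCD
#' genetic correlation of 0.41; and an early-onset OCD stratum at 0.43.
#' MAF-profile presets spread the non-rare variance over the five common
#' bins in proportion to the corresponding reported bin contributions.
#'
#' @param name one of \code{"TS_GLOBAL"}, \code{"OCD_GLOBAL"},
#'   \code{"TS_MAF"}, \code{"OCD_MAF"}, \code{"TS_GENIC"},
#'   \code{"OCD_GENIC"}, \code{"TSOCD_BIVAR"}, \code{"OCD_EARLY"}.
#' @return an \code{architecture}.
#' @export
architecture_preset <- function(name) {
  maf_labels <- paste0("maf_bin", 1:6)
  # reported per-bin contributions; rare-bin shares pinned at 0.21 / 0
  ts_bins <- c(0.21, 0.03, 0.18, 0.20, 0.26, 0.11)
  ts_shares <- c(0.21, ts_bins[-1] / sum(ts_bins[-1]) * 0.79)
  ocd_bins <- c(0, 0.11, 0.23, 0.03, 0.31, 0.31)
  ocd_shares <- c(0, ocd_bins[-1] / sum(ocd_bins[-1]))
  names(ts_shares) <- names(ocd_shares) <- maf_labels
  maf_causal <- stats::setNames(c(60L, 60L, 60L, 60L, 60L, 60L), maf_labels)
  ocd_maf_causal <- maf_causal
  ocd_maf_causal["maf_bin1"] <- 0L
  switch(name,
    TS_GLOBAL = architecture("TS_GLOBAL", 0.58, 0.008,
                             c(all = 1), c(all = 500L)),
    OCD_GLOBAL = architecture("OCD_GLOBAL", 0.37, 0.025,
                              c(all = 1), c(all = 500L)),
    TS_MAF = architecture("TS_MAF", 0.58, 0.008, ts_shares, maf_causal),
    OCD_MAF = architecture("OCD_MAF", 0.37, 0.025, ocd_shares, ocd_maf_causal),
    TS_GENIC = architecture("TS_GENIC", 0.58, 0.008,
                            c(genic = 0.53, intergenic = 0.47),
                            c(genic = 250L, intergenic = 250L)),
    OCD_GENIC = architecture("OCD_GENIC", 0.37, 0.025,
                             c(genic = 0.40, intergenic = 0.60),
                             c(genic = 250L, intergenic = 250L)),
    TSOCD_BIVAR = architecture("TSOCD_BIVAR", 0.58, 0.008,
                               c(all = 1), c(all = 500L),
                               rg = 0.41, h2_liability2 = 0.37,
                               prevalence_K2 = 0.025),
    OCD_EARLY = architecture("OCD_EARLY", 0.43, 0.025,
                             c(all = 1), c(all = 500L)),
    stop_snpher("snpher_config_error", "unknown preset '%s'", name)
  )
}

#' Write / read architectures as YAML
#'
#' @param arch an \code{architecture}.
#' @param path file path.
#' @return \code{read_architecture_yaml} returns an \code{architecture};
#'   \code{write_architecture_yaml} returns \code{path} invisibly.
#' @export
write_architecture_yaml <- function(arch, path) {
  x <- unclass(arch)
  x$partition_shares <- as.list(x$partition_shares)
  x$n_causal_per_partition <- as.list(x$n_causal_per_partition)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_architecture_yaml
#' @export
read_architecture_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  architecture(x$name, x$h2_liability, x$prevalence_K,
               unlist(x$partition_shares),
               unlist(x$n_causal_per_partition),
               rg = x$rg, h2_liability2 = x$h2_liability2,
               prevalence_K2 = x$prevalence_K2)
}

#' Default MAF bin edges
#'
#' Bin edges used for MAF partitioning and for the \code{maf_bin*}
#' partition labels: (0.001, 0.05], (0.05, 0.1], (0.1, 0.2], (0.2, 0.3],
#' (0.3, 0.4], (0.4, 0.5].
#' @return numeric vector of 7 breakpoints.
#' @export
default_maf_edges <- function() c(0.001, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
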