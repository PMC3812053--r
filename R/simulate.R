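#' MAF spectrum specifications
#'
#' A spectrum describes the distribution from which per-SNP allele
#' frequencies are drawn. Support must lie within (0.001, 0.5]: frequencies
#' below 0.001 are not simulated (the lowest bin edge used for rare-variant
#' partitioning) and the counted allele is always the minor one at draw
#' time.
#'
#' \code{maf_uniform(min, max)} draws uniformly; \code{maf_point(p)} fixes
#' every SNP at p; \code{maf_binned(edges, weights)} picks a bin with the
#' given weights and draws uniformly within it (used to reproduce a GWAS
#' array's bin occupancy).
#'
#' @param min,max,p,edges,weights spectrum parameters.
#' @return a \code{maf_spectrum} object.
#' @export
maf_uniform <- function(min = 0.01, max = 0.5) {
  check_maf_support(c(min, max))
  if (min >= max) stop_snpher("snpher_config_error", "need min < max")
  structure(list(kind = "uniform", min = min, max = max), class = "maf_spectrum")
}

#' @rdname maf_uniform
#' @export
maf_point <- function(p) {
  check_maf_support(p)
  structure(list(kind = "point", p = p), class = "maf_spectrum")
}

#' @rdname maf_uniform
#' @export
maf_binned <- function(edges = default_maf_edges(),
                       weights = c(0.051, 0.125, 0.245, 0.208, 0.189, 0.182)) {
  check_maf_support(edges)
  if (length(weights) != length(edges) - 1)
    stop_snpher("snpher_config_error", "need one weight per bin")
  structure(list(kind = "binned", edges = edges, weights = weights / sum(weights)),
            class = "maf_spectrum")
}

check_maf_support <- function(x) {
  if (any(x < 0.001 - 1e-12) || any(x > 0.5 + 1e-12))
    stop_snpher("snpher_config_error",
                "MAF spectrum support must lie within (0.001, 0.5]")
  invisible(x)
}

draw_maf <- function(spec, n) {
  switch(spec$kind,
         uniform = stats::runif(n, spec$min, spec$max),
         point = rep(spec$p, n),
         binned = {
           b <- sample.int(length(spec$weights), n, replace = TRUE,
                           prob = spec$weights)
           stats::runif(n, spec$edges[b], spec$edges[b + 1])
         })
}

#' Simulation configuration
#'
#' @param n_snps number of SNPs on the panel.
#' @param maf_spectrum a \code{\link{maf_uniform}}-style spectrum.
#' @param n_cases,n_controls ascertained sample composition.
#' @param chromosome_weights 22 fractions summing to 1 (defaults
#'   proportional to autosome physical length).
#' @param annotation_probs named fractions; each SNP gets each annotation
#'   independently with the given probability.
#' @param seed integer RNG seed.
#' @return a \code{sim_config} object.
#' @export
sim_config <- function(n_snps = 5000, maf_spectrum = maf_uniform(),
                       n_cases = 261, n_controls = 1739,
                       chromosome_weights = NULL,
                       annotation_probs = c(), seed = 1) {
  if (n_snps < 1) stop_snpher("snpher_config_error", "n_snps must be >= 1")
  if (!inherits(maf_spectrum, "maf_spectrum"))
    stop_snpher("snpher_config_error", "maf_spectrum must be a maf_spectrum object")
  w <- chromosome_weights %||% (autosome_lengths() / sum(autosome_lengths()))
  if (length(w) != 22 || abs(sum(w) - 1) > 1e-8)
    stop_snpher("snpher_config_error", "chromosome_weights must be 22 fractions summing to 1")
  if (any(annotation_probs < 0 | annotation_probs > 1))
    stop_snpher("snpher_config_error", "annotation_probs must lie in [0, 1]")
  structure(list(n_snps = as.integer(n_snps), maf_spectrum = maf_spectrum,
                 n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 chromosome_weights = w, annotation_probs = annotation_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a biallelic genotype panel in Hardy-Weinberg equilibrium
#'
#' Draws per-SNP allele frequencies from the configured MAF spectrum and
#' genotypes as Binomial(2, p) (linkage equilibrium). Chromosome labels are
#' assigned by the chromosome weights and annotation flags independently by
#' the annotation probabilities. Deterministic given the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_samples number of individuals; defaults to
#'   \code{n_cases + n_controls}.
#' @param id_prefix prefix for generated sample ids.
#' @return a \code{\link{genotype_matrix}} with the generating allele
#'   frequency stored in \code{attr(, "p_gen")}.
#' @export
simulate_genotypes <- function(config, n_samples = NULL, id_prefix = "S") {
  n <- n_samples %||% (config$n_cases + config$n_controls)
  m <- config$n_snps
  set.seed(stream_seed(config$seed, "genotypes"))
  p <- draw_maf(config$maf_spectrum, m)
  chr <- sort(sample.int(22, m, replace = TRUE, prob = config$chromosome_weights))
  pos <- integer(m)
  for (c in unique(chr)) {
    i <- which(chr == c)
    pos[i] <- sort(sample.int(2e8, length(i)))
  }
  calls <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  ann <- lapply(config$annotation_probs, function(q) stats::runif(m) < q)
  snps <- data.frame(id = sprintf("snp%06d", seq_len(m)), chr = chr, pos = pos,
                     a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, sample_ids(n, id_prefix), snps, annotations = ann)
  attr(g, "p_gen") <- p
  attr(g, "sim_config") <- config
  g
}

# map architecture partition labels onto SNP masks of a panel
resolve_partition_masks <- function(g, labels, maf_edges = default_maf_edges()) {
  p <- attr(g, "p_gen") %||% g$freq
  maf <- pmin(p, 1 - p)
  masks <- list()
  for (lab in labels) {
    if (lab == "all") {
      masks[[lab]] <- rep(TRUE, n_snps(g))
    } else if (lab %in% names(g$annotations)) {
      masks[[lab]] <- g$annotations[[lab]]
    } else if (grepl("^maf_bin[0-9]+$", lab)) {
      k <- as.integer(sub("maf_bin", "", lab))
      if (k >= length(maf_edges))
        stop_snpher("snpher_config_error", "MAF bin %d beyond edge list", k)
      masks[[lab]] <- maf > maf_edges[k] & maf <= maf_edges[k + 1]
    } else if (lab == "intergenic" && "genic" %in% names(g$annotations)) {
      masks[[lab]] <- !g$annotations[["genic"]]
    } else {
      stop_snpher("snpher_precondition_error",
                  "partition '%s' is not resolvable on this panel", lab)
    }
  }
  masks
}

# draw causal ids and effect sizes on the standardized-genotype scale:
# each causal SNP in partition j has expected effect variance
# share_j * h2 / n_j; the drawn vector is rescaled within each partition so
# the summed squared effects equal share_j * h2 exactly, pinning each
# replicate's genetic variance decomposition at the architecture's truth
draw_causal_effects <- function(g, arch, h2, exact = TRUE) {
  masks <- resolve_partition_masks(g, names(arch$partition_shares))
  idx <- integer(0); part <- character(0); sds <- numeric(0); beta <- numeric(0)
  for (lab in names(arch$partition_shares)) {
    nc <- arch$n_causal_per_partition[[lab]]
    if (nc == 0) next
    avail <- which(masks[[lab]])
    if (length(avail) < nc)
      stop_snpher("snpher_precondition_error",
                  "partition '%s' has %d SNPs but needs %d causal",
                  lab, length(avail), nc)
    pick <- sample(avail, nc)
    target <- arch$partition_shares[[lab]] * h2
    b <- stats::rnorm(nc, 0, sqrt(target / nc))
    if (exact && target > 0 && sum(b^2) > 0)
      b <- b * sqrt(target / sum(b^2))
    idx <- c(idx, pick)
    part <- c(part, rep(lab, nc))
    sds <- c(sds, rep(sqrt(target / max(nc, 1)), nc))
    beta <- c(beta, b)
  }
  list(idx = idx, partition = part, beta = beta, sd = sds)
}

#' Simulate a case-control phenotype under the liability-threshold model
#'
#' Causal effects are drawn per partition on the standardized-genotype
#' scale so each partition contributes its share of the liability-scale
#' genetic variance. Liability is genetic value plus an independent normal
#' residual (total variance 1); individuals whose liability exceeds
#' \eqn{\Phi^{-1}(1-K)} are affected. A population is generated in chunks
#' until the case quota is reached; controls are sampled uniformly from the
#' unaffected (reservoir sampling), reproducing case-control ascertainment
#' at population prevalence K with an enriched sample case fraction.
#'
#' Genotypes for non-causal SNPs are independent of the phenotype and are
#' therefore drawn only for the ascertained individuals, which keeps
#' low-prevalence ascertainment cheap without changing the sampling
#' distribution.
#'
#' @param g a panel from \code{\link{simulate_genotypes}} (provides SNP
#'   frequencies, annotations and the target sample composition).
#' @param arch an \code{\link{architecture}}.
#' @param seed integer seed for the effect/residual/ascertainment streams.
#' @param n_cases,n_controls override the panel's configured composition.
#' @param chunk_size,max_chunks population chunking controls.
#' @param causal a pre-drawn causal set (internal, used by the bivariate
#'   generator); NULL draws one.
#' @param id_prefix prefix for ascertained sample ids.
#' @return a list of class \code{phenotype_set}: \code{genotypes} (the
#'   ascertained \code{genotype_matrix}), \code{phenotype} (1 = case,
#'   0 = control), \code{genetic_value}, \code{liability},
#'   \code{prevalence_realized}, \code{truth} (causal id, partition,
#'   effect), and \code{arch}.
#' @export
simulate_liability_phenotype <- function(g, arch, seed,
                                         n_cases = NULL, n_controls = NULL,
                                         chunk_size = 10000, max_chunks = 100,
                                         causal = NULL, id_prefix = "S") {
  cfg <- attr(g, "sim_config")
  n_cases <- n_cases %||% cfg$n_cases
  n_controls <- n_controls %||% cfg$n_controls
  K <- arch$prevalence_K
  Tthr <- stats::qnorm(1 - K)
  h2 <- arch$h2_liability

  set.seed(stream_seed(seed, "effects"))
  if (is.null(causal)) causal <- draw_causal_effects(g, arch, h2)
  p <- (attr(g, "p_gen") %||% g$freq)
  pc <- p[causal$idx]
  scale_c <- sqrt(2 * pc * (1 - pc))

  set.seed(stream_seed(seed, "ascertain"))
  nc_tot <- length(causal$idx)
  cases_X <- matrix(0L, 0, nc_tot); cases_g <- numeric(0); cases_l <- numeric(0)
  res_X <- matrix(0L, n_controls, nc_tot); res_g <- numeric(n_controls)
  res_l <- numeric(n_controls); res_filled <- 0L; n_unaff_seen <- 0L
  n_pop <- 0L; n_aff <- 0L
  for (chunk in seq_len(max_chunks)) {
    Xc <- matrix(stats::rbinom(chunk_size * nc_tot, 2L, rep(pc, each = chunk_size)),
                 nrow = chunk_size)
    W <- sweep(sweep(Xc, 2, 2 * pc), 2, scale_c, "/")
    gval <- as.numeric(W %*% causal$beta)
    liab <- gval + stats::rnorm(chunk_size, 0, sqrt(max(0, 1 - h2)))
    aff <- liab > Tthr
    n_pop <- n_pop + chunk_size
    n_aff <- n_aff + sum(aff)
    if (nrow(cases_X) < n_cases && any(aff)) {
      take <- which(aff)[seq_len(min(sum(aff), n_cases - nrow(cases_X)))]
      cases_X <- rbind(cases_X, Xc[take, , drop = FALSE])
      cases_g <- c(cases_g, gval[take]); cases_l <- c(cases_l, liab[take])
    }
    un <- which(!aff)
    for (i in un) {
      n_unaff_seen <- n_unaff_seen + 1L
      if (res_filled < n_controls) {
        res_filled <- res_filled + 1L
        res_X[res_filled, ] <- Xc[i, ]; res_g[res_filled] <- gval[i]
        res_l[res_filled] <- liab[i]
      } else if (stats::runif(1) < n_controls / n_unaff_seen) {
        j <- sample.int(n_controls, 1)
        res_X[j, ] <- Xc[i, ]; res_g[j] <- gval[i]; res_l[j] <- liab[i]
      }
    }
    if (nrow(cases_X) >= n_cases && res_filled >= n_controls) break
  }
  if (nrow(cases_X) < n_cases || res_filled < n_controls)
    stop_snpher("snpher_resource_error",
                "case quota unreachable in %d chunks; ~%d individuals required",
                max_chunks, ceiling(n_cases / K))

  n <- n_cases + n_controls
  set.seed(stream_seed(seed, "genotypes"))
  calls <- matrix(stats::rbinom(n * n_snps(g), 2L, rep(p, each = n)), nrow = n)
  calls[, causal$idx] <- rbind(cases_X, res_X)
  samples <- sample_ids(n, id_prefix)
  out_g <- genotype_matrix(calls, samples, g$snps, annotations = g$annotations)
  attr(out_g, "p_gen") <- p
  attr(out_g, "sim_config") <- cfg

  structure(list(
    genotypes = out_g,
    phenotype = c(rep(1L, n_cases), rep(0L, n_controls)),
    genetic_value = c(cases_g, res_g),
    liability = c(cases_l, res_l),
    prevalence_realized = n_aff / n_pop,
    truth = data.frame(snp = g$snps$id[causal$idx], partition = causal$partition,
                       beta = causal$beta, stringsAsFactors = FALSE),
    arch = arch), class = "phenotype_set")
}

#' Simulate two genetically correlated case-control traits
#'
#' Per-SNP effect pairs for a shared causal set are drawn from a bivariate
#' normal with correlation \code{arch$rg} and trait-specific variances;
#' each trait is then ascertained on its own disjoint sample via
#' \code{\link{simulate_liability_phenotype}}.
#'
#' @param g1,g2 genotype panels sharing the same SNP set (their sample ids
#'   must be disjoint).
#' @param arch a bivariate \code{\link{architecture}} (with \code{rg}).
#' @return list with elements \code{trait1} and \code{trait2}, each a
#'   \code{phenotype_set}, plus \code{effects} (the drawn effect pairs).
#' @inheritParams simulate_liability_phenotype
#' @export
simulate_bivariate <- function(g1, g2, arch, seed,
                               chunk_size = 10000, max_chunks = 100) {
  if (is.null(arch$rg))
    stop_snpher("snpher_precondition_error", "architecture has no rg")
  if (!identical(g1$snps$id, g2$snps$id))
    stop_snpher("snpher_precondition_error", "panels must share the same SNP set")
  k1 <- paste(g1$samples$fid, g1$samples$iid)
  k2 <- paste(g2$samples$fid, g2$samples$iid)
  if (length(intersect(k1, k2)))
    stop_snpher("snpher_precondition_error", "overlapping sample ids: %s",
                paste(utils::head(intersect(k1, k2), 5), collapse = ", "))

  h2a <- arch$h2_liability; h2b <- arch$h2_liability2
  set.seed(stream_seed(seed, "effects"))
  base <- draw_causal_effects(g1, arch, h2 = 1, exact = FALSE)
  nc <- length(base$idx)
  # effect pairs from a bivariate normal at correlation rg; the two raw
  # draws are orthonormalized first so the realized effect-vector
  # correlation and per-trait effect variances equal the preset exactly
  z1 <- stats::rnorm(nc)
  z2 <- stats::rnorm(nc)
  z1 <- z1 - mean(z1); z1 <- z1 / sqrt(sum(z1^2) / nc)
  z2r <- stats::residuals(stats::lm(z2 ~ z1))
  z2r <- z2r / sqrt(sum(z2r^2) / nc)
  rg <- arch$rg
  z2 <- rg * z1 + sqrt(1 - rg^2) * z2r
  w <- base$sd / sqrt(sum(base$sd^2))  # per-SNP scale, unit total
  beta1 <- z1 * w * sqrt(h2a)
  beta2 <- z2 * w * sqrt(h2b)
  c1 <- list(idx = base$idx, partition = base$partition, beta = beta1, sd = base$sd)
  c2 <- list(idx = base$idx, partition = base$partition, beta = beta2, sd = base$sd)

  arch1 <- arch; arch2 <- arch
  arch2$h2_liability <- h2b; arch2$prevalence_K <- arch$prevalence_K2
  t1 <- simulate_liability_phenotype(g1, arch1, seed = seed + 1000L,
                                     chunk_size = chunk_size,
                                     max_chunks = max_chunks,
                                     causal = c1, id_prefix = "T1x")
  t2 <- simulate_liability_phenotype(g2, arch2, seed = seed + 2000L,
                                     chunk_size = chunk_size,
                                     max_chunks = max_chunks,
                                     causal = c2, id_prefix = "T2x")
  list(trait1 = t1, trait2 = t2,
       effects = data.frame(snp = g1$snps$id[base$idx],
                            beta1 = beta1, beta2 = beta2))
}

#' Clone a genotype panel for a second, disjoint sample
#'
#' Keeps the SNP metadata, generating allele frequencies and annotations of
#' an existing panel but draws genotypes for a fresh set of individuals
#' with new ids, so two traits can share one SNP panel on disjoint samples.
#'
#' @param g a panel from \code{\link{simulate_genotypes}}.
#' @param n_cases,n_controls target composition of the new sample.
#' @param seed integer seed.
#' @param id_prefix prefix for the new sample ids (must differ from the
#'   source panel's).
#' @return a \code{\link{genotype_matrix}} on the same SNP panel.
#' @export
clone_panel <- function(g, n_cases, n_controls, seed, id_prefix = "C") {
  cfg <- attr(g, "sim_config")
  if (is.null(cfg))
    stop_snpher("snpher_precondition_error", "panel carries no sim_config")
  cfg$n_cases <- as.integer(n_cases)
  cfg$n_controls <- as.integer(n_controls)
  cfg$seed <- as.integer(seed)
  n <- n_cases + n_controls
  p <- attr(g, "p_gen") %||% g$freq
  set.seed(stream_seed(seed, "genotypes"))
  calls <- matrix(stats::rbinom(n * n_snps(g), 2L, rep(p, each = n)), nrow = n)
  out <- genotype_matrix(calls, sample_ids(n, id_prefix), g$snps,
                         annotations = g$annotations)
  attr(out, "p_gen") <- p
  attr(out, "sim_config") <- cfg
  out
}

#' Inject a platform/batch allele-frequency artifact
#'
#' For a random fraction of SNPs, genotypes of one platform group are
#' resampled at a frequency shifted by \code{shift} (clamped to (0, 1) with
#' a warning), emulating the cross-platform batch effects the QC screens
#' must catch. Affected SNP ids are recorded in
#' \code{attr(, "artifact_snps")}.
#'
#' @param g a \code{genotype_matrix}.
#' @param platform_labels character/factor of length \code{n_samples(g)}
#'   with exactly two levels.
#' @param affected_fraction fraction of SNPs perturbed.
#' @param shift allele-frequency shift applied in the second platform group.
#' @param seed integer seed.
#' @return the perturbed \code{genotype_matrix}.
#' @export
inject_platform_artifact <- function(g, platform_labels, affected_fraction,
                                     shift, seed) {
  lev <- unique(platform_labels)
  if (length(lev) != 2)
    stop_snpher("snpher_precondition_error", "need exactly two platform labels")
  if (affected_fraction < 0 || affected_fraction > 1)
    stop_snpher("snpher_config_error", "affected_fraction must lie in [0, 1]")
  if (affected_fraction == 0) return(g)
  set.seed(stream_seed(seed, "artifact"))
  m <- n_snps(g)
  hit <- sample.int(m, round(affected_fraction * m))
  grp <- which(platform_labels == lev[2])
  p_new <- g$freq[hit] + shift
  if (any(p_new <= 0 | p_new >= 1)) {
    warning("shift clamps some frequencies to (0, 1)")
    p_new <- pmin(pmax(p_new, 1e-4), 1 - 1e-4)
  }
  for (j in seq_along(hit)) {
    g$calls[grp, hit[j]] <- stats::rbinom(length(grp), 2L, p_new[j])
  }
  g <- recompute_freq(g)
  attr(g, "artifact_snps") <- g$snps$id[sort(hit)]
  g
}
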