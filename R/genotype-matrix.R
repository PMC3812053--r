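#' In-memory genotype matrix
#'
#' The central genotype container: an individuals-by-SNPs matrix of counted
#' allele dosages in \{0, 1, 2\} (NA for missing), together with sample ids,
#' per-SNP map information, counted-allele (A1) frequencies computed on the
#' stored sample, and named boolean annotation masks over SNPs.
#'
#' @param calls integer matrix, individuals in rows, SNPs in columns,
#'   entries in \{0, 1, 2, NA\}; counts copies of the A1 allele.
#' @param samples data.frame with columns \code{fid} and \code{iid}.
#' @param snps data.frame with columns \code{id}, \code{chr} (1-22),
#'   \code{pos}, \code{a1}, \code{a2}.
#' @param annotations named list of logical vectors, one entry per SNP mask
#'   (e.g. genic membership, eQTL membership).
#'
#' @return An object of class \code{genotype_matrix} with elements
#'   \code{calls}, \code{samples}, \code{snps}, \code{freq} (A1 frequency),
#'   \code{maf}, and \code{annotations}.
#' @export
genotype_matrix <- function(calls, samples, snps, annotations = list()) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(samples) != nrow(calls))
    stop_snpher("snpher_format_error", "sample table has %d rows but calls has %d",
                nrow(samples), nrow(calls))
  if (nrow(snps) != ncol(calls))
    stop_snpher("snpher_format_error", "snp table has %d rows but calls has %d columns",
                nrow(snps), ncol(calls))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop_snpher("snpher_format_error", "genotype calls must be 0, 1, 2 or NA")
  for (nm in names(annotations)) {
    if (length(annotations[[nm]]) != nrow(snps))
      stop_snpher("snpher_format_error", "annotation '%s' length != number of SNPs", nm)
    annotations[[nm]] <- as.logical(annotations[[nm]])
  }
  g <- structure(list(calls = calls,
                      samples = as.data.frame(samples),
                      snps = as.data.frame(snps),
                      annotations = annotations),
                 class = "genotype_matrix")
  g <- recompute_freq(g)
  g
}

#' Recompute allele frequencies from the stored calls
#'
#' Counted-allele (A1) frequency per SNP from non-missing calls; minor
#' allele frequency is \code{min(p, 1 - p)}.
#'
#' @param g a \code{genotype_matrix}.
#' @return \code{g} with \code{freq} and \code{maf} refreshed.
#' @export
recompute_freq <- function(g) {
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  g$freq <- unname(p)
  g$maf <- pmin(g$freq, 1 - g$freq)
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  chromosomes: %s\n",
              paste(sort(unique(x$snps$chr)), collapse = " ")))
  if (length(x$annotations))
    cat(sprintf("  annotations: %s\n", paste(names(x$annotations), collapse = ", ")))
  invisible(x)
}

#' Number of samples / SNPs
#' @param g a \code{genotype_matrix}.
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname n_samples
#' @export
n_snps <- function(g) ncol(g$calls)

#' Subset a genotype matrix
#'
#' @param g a \code{genotype_matrix}.
#' @param samples logical/integer index over individuals (NULL keeps all).
#' @param snps logical/integer index over SNPs (NULL keeps all).
#' @return the subsetted \code{genotype_matrix}, frequencies recomputed on
#'   the retained sample.
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  si <- samples %||% seq_len(n_samples(g))
  vi <- snps %||% seq_len(n_snps(g))
  ann <- lapply(g$annotations, function(a) a[vi])
  out <- genotype_matrix(g$calls[si, vi, drop = FALSE],
                         g$samples[si, , drop = FALSE],
                         g$snps[vi, , drop = FALSE],
                         annotations = ann)
  if (!is.null(attr(g, "p_gen"))) attr(out, "p_gen") <- attr(g, "p_gen")[vi]
  if (!is.null(attr(g, "sim_config"))) attr(out, "sim_config") <- attr(g, "sim_config")
  out
}

#' Stack two genotype matrices over a shared SNP panel
#'
#' Used to assemble the combined sample for bivariate analyses. SNP panels
#' must be identical (same ids in the same order); sample ids must be
#' disjoint.
#'
#' @param g1,g2 \code{genotype_matrix} objects on the same SNP panel.
#' @return a \code{genotype_matrix} holding both samples.
#' @export
combine_genotypes <- function(g1, g2) {
  if (!identical(g1$snps$id, g2$snps$id))
    stop_snpher("snpher_precondition_error", "SNP panels differ; cannot combine")
  k1 <- paste(g1$samples$fid, g1$samples$iid)
  k2 <- paste(g2$samples$fid, g2$samples$iid)
  dup <- intersect(k1, k2)
  if (length(dup))
    stop_snpher("snpher_precondition_error",
                "overlapping sample ids: %s", paste(utils::head(dup, 5), collapse = ", "))
  genotype_matrix(rbind(g1$calls, g2$calls),
                  rbind(g1$samples, g2$samples),
                  g1$snps,
                  annotations = g1$annotations)
}
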