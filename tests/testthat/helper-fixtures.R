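# small shared fixtures, built in code at test time

tiny_panel <- function(n = 60, m = 120, seed = 11, ...) {
  cfg <- sim_config(n_snps = m, n_cases = ceiling(n / 2),
                    n_controls = floor(n / 2), seed = seed, ...)
  simulate_genotypes(cfg)
}

# genotype matrix from an explicit call matrix, ids auto-generated
gm_from_calls <- function(calls, chr = NULL, maf_ann = list()) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  snps <- data.frame(id = sprintf("s%03d", seq_len(m)),
                     chr = chr %||% rep(1L, m),
                     pos = seq_len(m) * 100L, a1 = "A", a2 = "B",
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, snpher:::sample_ids(nrow(calls)), snps,
                  annotations = maf_ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quantitative-trait simulation on a given panel: y = W beta + e
quant_trait <- function(g, h2, n_causal, seed) {
  set.seed(seed)
  p <- attr(g, "p_gen") %||% g$freq
  idx <- sample(ncol(g$calls), n_causal)
  beta <- rnorm(n_causal, 0, sqrt(h2 / n_causal))
  W <- sweep(sweep(g$calls[, idx, drop = FALSE], 2, 2 * p[idx]),
             2, sqrt(2 * p[idx] * (1 - p[idx])), "/")
  gval <- as.numeric(W %*% beta)
  list(y = gval + rnorm(nrow(g$calls), 0, sqrt(1 - h2)), gval = gval)
}
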