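# enumeration oracle for the HWE exact test: full conditional distribution
# of heterozygote counts given allele counts
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  rare <- min(na, 2 * n - na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # direct enumeration over heterozygote counts with fixed allele counts
  pr <- vapply(hets, function(h) {
    nAA <- (2 * n - na - h) / 2; naa <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(h) - lfactorial(nAA) - lfactorial(naa) +
          h * log(2))
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

test_that("HWE exact test matches full enumeration and handles degenerate tables", {
  expect_identical(hwe_exact_test(50, 0, 0), 1.0)   # monomorphic
  expect_identical(hwe_exact_test(25, 50, 25), 1.0) # observed table is the mode
  # all-heterozygote extreme: 100 minor alleles in 100 diploids
  expect_equal(hwe_exact_test(0, 100, 0), hwe_oracle(0, 100, 0), tolerance = 1e-12)
  # a spread of random tables against the oracle
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    p <- runif(1, 0.05, 0.5)
    x <- stats::rmultinom(1, n, c((1 - p)^2, 2 * p * (1 - p), p^2))
    expect_equal(hwe_exact_test(x[1], x[2], x[3]),
                 hwe_oracle(x[1], x[2], x[3]), tolerance = 1e-9)
  }
})

# brute-force two-sided Fisher p over all tables with fixed margins
fisher_oracle <- function(a, n1, b, n2) {
  k <- a + b
  xs <- max(0, k - n2):min(k, n1)
  pr <- stats::dhyper(xs, n1, n2, k)
  obs <- stats::dhyper(a, n1, n2, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

test_that("differential missingness test equals the hypergeometric enumeration oracle", {
  expect_equal(differential_missingness_test(5, 100, 5, 100), 1.0)
  expect_equal(differential_missingness_test(0, 100, 0, 100), 1.0)
  expect_equal(differential_missingness_test(20, 100, 2, 100),
               fisher_oracle(20, 100, 2, 100), tolerance = 1e-9)
  set.seed(11)
  for (i in 1:10) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    expect_equal(differential_missingness_test(a, 60, b, 80),
                 fisher_oracle(a, 60, b, 80), tolerance = 1e-9)
  }
  expect_error(differential_missingness_test(5, 3, 0, 10),
               class = "snpher_precondition_error")
})

test_that("sample call-rate filter drops exactly the low-call-rate samples", {
  g <- tiny_panel(n = 20, m = 1000, seed = 13)
  expect_identical(sample_call_rate_filter(g, 0.999), g$samples$iid)
  g$calls[3, 1:10] <- NA_integer_  # 1% missing
  g$calls[7, 1] <- NA_integer_    # 0.1% missing, on the threshold
  kept <- sample_call_rate_filter(g, 0.999)
  expect_false(g$samples$iid[3] %in% kept)
  expect_true(g$samples$iid[7] %in% kept)
  # direct counting oracle
  oracle <- g$samples$iid[rowMeans(!is.na(g$calls)) >= 0.999]
  expect_identical(kept, oracle)
})

test_that("relatedness pruning removes duplicates and resolves chains greedily", {
  ids <- data.frame(fid = paste0("F", 1:4), iid = c("A", "B", "C", "D"))
  A <- diag(4)
  # duplicated pair (A, B)
  A[1, 2] <- A[2, 1] <- 0.98
  grm <- snpher:::new_grm(A, ids)
  kept <- prune_related(grm, 0.05)
  expect_identical(sort(c(setdiff(1:4, kept), kept)), 1:4)
  expect_length(intersect(kept, 1:2), 1)

  # chain A-B, B-C: removing B alone clears all violations
  A2 <- diag(4)
  A2[1, 2] <- A2[2, 1] <- 0.2
  A2[2, 3] <- A2[3, 2] <- 0.2
  kept2 <- prune_related(snpher:::new_grm(A2, ids), 0.05)
  expect_identical(kept2, c(1L, 3L, 4L))

  # all pairs below threshold: identity
  expect_identical(prune_related(snpher:::new_grm(diag(4), ids), 0.05), 1:4)

  # kept set has no violating pair
  set.seed(5)
  A3 <- diag(8)
  for (i in 1:6) {
    p <- sample(8, 2)
    A3[p[1], p[2]] <- A3[p[2], p[1]] <- runif(1, 0.06, 0.5)
  }
  k3 <- prune_related(snpher:::new_grm(A3, data.frame(fid = paste0("F", 1:8),
                                                      iid = letters[1:8])), 0.05)
  off <- A3[k3, k3]; diag(off) <- 0
  expect_lte(max(off), 0.05)
})

test_that("priority keeps cases when resolving duplicate pairs", {
  ids <- data.frame(fid = paste0("F", 1:2), iid = c("A", "B"))
  A <- diag(2); A[1, 2] <- A[2, 1] <- 0.9
  kept_case_first <- prune_related(snpher:::new_grm(A, ids), 0.05,
                                   priority = c(FALSE, TRUE))
  expect_identical(kept_case_first, 2L)
})

test_that("platform scan flags constant genotypes and detects injected artifacts", {
  set.seed(17)
  cfg <- sim_config(n_snps = 150, maf_spectrum = maf_uniform(0.1, 0.5),
                    n_cases = 200, n_controls = 200, seed = 19)
  g <- simulate_genotypes(cfg)
  g$calls[, 1] <- 1L  # constant SNP
  g <- recompute_freq(g)
  platform <- rep(c("chipA", "chipB"), each = 200)
  scan0 <- platform_association_scan(g, platform)
  expect_identical(scan0$flag[1], "constant")
  expect_identical(scan0$p[1], 1)

  gart <- inject_platform_artifact(g, platform, affected_fraction = 0.2,
                                   shift = 0.25, seed = 23)
  hit <- match(attr(gart, "artifact_snps"), gart$snps$id)
  scan <- platform_association_scan(gart, platform)
  # power: far more than the nominal 0.1% of perturbed SNPs flagged
  expect_gt(mean(scan$p[hit] < 0.001), 0.5)
  # null calibration on untouched SNPs at a liberal level
  clean <- setdiff(seq_len(n_snps(g))[-1], hit)
  expect_lt(mean(scan$p[clean] < 0.001), 0.05)
})

test_that("artifact injection with zero affected fraction is the identity", {
  g <- tiny_panel(n = 30, m = 50, seed = 29)
  platform <- rep(c("a", "b"), 15)
  expect_identical(inject_platform_artifact(g, platform, 0, 0.2, 1)$calls,
                   g$calls)
})

test_that("SNP tests are calibrated (at most nominal) on artifact-free data", {
  # clean HWE genotypes with some random missingness: the exact HWE test is
  # conservative, so drop fractions must not exceed alpha by more than
  # binomial noise, and the missingness test sees no case/control signal
  cfg <- sim_config(n_snps = 5000, maf_spectrum = maf_uniform(0.05, 0.5),
                    n_cases = 150, n_controls = 350, seed = 401)
  g <- simulate_genotypes(cfg)
  set.seed(402)
  miss <- sample(length(g$calls), round(0.0005 * length(g$calls)))
  g$calls[miss] <- NA_integer_
  g <- recompute_freq(g)
  y <- c(rep(1L, 150), rep(0L, 350))
  rep <- run_qc(g, y)
  # per-test calibration: first-pass p-values reject at most the nominal
  # alpha (the exact tests are conservative); binomial 3-sigma slack
  p_hwe <- rep$snp_table$p_hwe
  expect_lt(mean(p_hwe < 0.05, na.rm = TRUE), 0.05 + 0.009)
  p_miss <- rep$snp_table$p_missingness
  expect_lt(mean(p_miss < 0.05, na.rm = TRUE), 0.05 + 0.009)
  # total drops accumulate over the fixed-point passes but stay modest
  expect_lt(mean(rep$snp_table$dropped_reason != ""), 0.10)
  expect_gt(sum(rep$snp_table$dropped_reason != ""), 0)
})

test_that("run_qc is idempotent and records one primary drop reason per SNP", {
  set.seed(31)
  cfg <- sim_config(n_snps = 300, maf_spectrum = maf_uniform(0.05, 0.5),
                    n_cases = 120, n_controls = 180, seed = 37)
  g <- simulate_genotypes(cfg)
  y <- c(rep(1L, 120), rep(0L, 180))
  # plant a differential-missingness SNP and a duplicate individual
  g$calls[y == 1, 2][1:30] <- NA_integer_
  g$calls[300, ] <- g$calls[1, ]
  g <- recompute_freq(g)
  rep1 <- run_qc(g, y, snp_call_rate = 0.8)
  expect_s3_class(rep1, "qc_report")
  expect_identical(rep1$snp_table$dropped_reason[2], "diff_missingness")
  expect_true("relatedness" %in% rep1$sample_table$dropped_reason)
  # exactly one reason per dropped SNP by construction of the column
  expect_true(all(rep1$snp_table$dropped_reason %in%
                    c("", "snp_call_rate", "monomorphic", "diff_missingness",
                      "hwe", "platform")))
  # idempotence: a second pass drops nothing
  rep2 <- run_qc(rep1$genotypes, rep1$phenotype, snp_call_rate = 0.8)
  expect_identical(rep2$n_snps_kept, n_snps(rep1$genotypes))
  expect_identical(rep2$n_samples_kept, n_samples(rep1$genotypes))
})
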