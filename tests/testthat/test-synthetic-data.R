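test_that("genotypes are HWE draws from the configured spectrum, deterministic by seed", {
  cfg <- sim_config(n_snps = 3, maf_spectrum = maf_point(0.5),
                    n_cases = 2000, n_controls = 2000, seed = 41)
  g <- simulate_genotypes(cfg)
  freqs <- apply(g$calls, 2, function(x) tabulate(x + 1L, 3) / length(x))
  expect_true(all(abs(freqs[1, ] - 0.25) < 0.04))
  expect_true(all(abs(freqs[2, ] - 0.50) < 0.04))

  g2 <- simulate_genotypes(cfg)
  expect_identical(g$calls, g2$calls)

  cfg3 <- sim_config(n_snps = 5000, maf_spectrum = maf_uniform(0.01, 0.5),
                     n_cases = 50, n_controls = 50, seed = 43)
  g3 <- simulate_genotypes(cfg3)
  expect_true(all(g3$maf >= 0 & g3$maf <= 0.5))
  expect_true(all(g3$calls %in% 0:2))

  expect_error(maf_uniform(0, 0.5), class = "snpher_config_error")
  expect_error(maf_point(0.7), class = "snpher_config_error")
})

test_that("liability phenotype respects the threshold model and ascertainment", {
  cfg <- sim_config(n_snps = 800, n_cases = 150, n_controls = 850, seed = 47)
  g <- simulate_genotypes(cfg)
  arch <- architecture("t", 0.5, 0.05, c(all = 1), c(all = 200L))
  ps <- simulate_liability_phenotype(g, arch, seed = 48)
  # exact sample composition
  expect_identical(sum(ps$phenotype), 150L)
  expect_identical(length(ps$phenotype), 1000L)
  # realized population prevalence near K
  expect_lt(abs(ps$prevalence_realized - 0.05), 0.01)
  # liability variance ~1 in the population implies the control liabilities
  # sit below the threshold and cases above it
  Tthr <- qnorm(1 - 0.05)
  expect_true(all(ps$liability[ps$phenotype == 1] > Tthr))
  expect_true(all(ps$liability[ps$phenotype == 0] <= Tthr))
  # per-replicate genetic variance pinned at the architecture truth
  expect_equal(sum(ps$truth$beta^2), 0.5, tolerance = 1e-12)
  # reproducible end to end
  ps2 <- simulate_liability_phenotype(g, arch, seed = 48)
  expect_identical(ps2$genotypes$calls, ps$genotypes$calls)
  expect_identical(ps2$phenotype, ps$phenotype)
})

test_that("population liability has unit variance and null architectures carry no signal", {
  cfg <- sim_config(n_snps = 500, n_cases = 100, n_controls = 100, seed = 53)
  g <- simulate_genotypes(cfg)
  arch <- architecture("v", 0.4, 0.5, c(all = 1), c(all = 100L))
  # K = 0.5 with equal case/control counts: the retained sample is close to
  # a population sample, so its liability variance estimates Var(L) = 1
  ps <- simulate_liability_phenotype(g, arch, seed = 54,
                                     n_cases = 5000, n_controls = 5000)
  expect_lt(abs(var(ps$liability) - 1), 0.05)

  arch0 <- architecture("null", 0, 0.1, c(all = 1), c(all = 10L))
  ps0 <- simulate_liability_phenotype(g, arch0, seed = 55)
  expect_true(all(ps0$genetic_value == 0))
  # phenotype independent of genotypes: correlation with any SNP tiny
  r <- abs(cor(ps0$phenotype, ps0$genotypes$calls[, 1:50]))
  expect_lt(max(r), 0.25)
})

test_that("partition variance shares match the architecture for shipped presets", {
  cfg <- sim_config(n_snps = 6000, maf_spectrum = maf_binned(),
                    n_cases = 100, n_controls = 100, seed = 59)
  g <- simulate_genotypes(cfg)
  arch <- architecture_preset("TS_MAF")
  ps <- simulate_liability_phenotype(g, arch, seed = 60)
  by_part <- tapply(ps$truth$beta^2, ps$truth$partition, sum)
  shares <- by_part[names(arch$partition_shares)] / sum(by_part)
  expect_equal(as.numeric(shares), unname(arch$partition_shares),
               tolerance = 1e-9)

  genic_cfg <- sim_config(n_snps = 2000, annotation_probs = c(genic = 0.5),
                          n_cases = 100, n_controls = 100, seed = 61)
  gg <- simulate_genotypes(genic_cfg)
  arch_g <- architecture_preset("TS_GENIC")
  psg <- simulate_liability_phenotype(gg, arch_g, seed = 62)
  sh <- tapply(psg$truth$beta^2, psg$truth$partition, sum) / 0.58
  expect_equal(unname(sh["genic"]), 0.53, tolerance = 1e-9)
})

test_that("bivariate generator realizes the preset genetic correlation on disjoint samples", {
  arch <- architecture_preset("TSOCD_BIVAR")
  cfg <- sim_config(n_snps = 1500, n_cases = 60, n_controls = 240, seed = 63)
  g1 <- simulate_genotypes(cfg, id_prefix = "A")
  g2 <- clone_panel(g1, 60, 240, seed = 64, id_prefix = "B")
  bv <- simulate_bivariate(g1, g2, arch, seed = 65)
  expect_equal(cor(bv$effects$beta1, bv$effects$beta2), 0.41, tolerance = 1e-9)
  expect_equal(sum(bv$effects$beta1^2), 0.58, tolerance = 1e-9)
  expect_equal(sum(bv$effects$beta2^2), 0.37, tolerance = 1e-9)
  ids1 <- paste(bv$trait1$genotypes$samples$fid, bv$trait1$genotypes$samples$iid)
  ids2 <- paste(bv$trait2$genotypes$samples$fid, bv$trait2$genotypes$samples$iid)
  expect_length(intersect(ids1, ids2), 0)

  # rg = 1 with equal h2: identical effect vectors up to scale
  arch1 <- architecture("b1", 0.5, 0.05, c(all = 1), c(all = 100L),
                        rg = 1, h2_liability2 = 0.5, prevalence_K2 = 0.05)
  bv1 <- simulate_bivariate(g1, g2, arch1, seed = 66)
  expect_equal(cor(bv1$effects$beta1, bv1$effects$beta2), 1, tolerance = 1e-9)

  # overlapping samples are rejected
  expect_error(simulate_bivariate(g1, g1, arch, seed = 67),
               class = "snpher_precondition_error")
})

test_that("unreachable case quotas raise a resource error naming the population size", {
  cfg <- sim_config(n_snps = 100, n_cases = 500, n_controls = 100, seed = 69)
  g <- simulate_genotypes(cfg)
  arch <- architecture("rare", 0.3, 0.001, c(all = 1), c(all = 20L))
  expect_error(
    simulate_liability_phenotype(g, arch, seed = 70,
                                 chunk_size = 1000, max_chunks = 3),
    class = "snpher_resource_error")
})

test_that("architecture presets encode the study estimates and YAML round-trips", {
  ts <- architecture_preset("TS_GLOBAL")
  expect_equal(ts$h2_liability, 0.58)
  expect_equal(ts$prevalence_K, 0.008)
  ocd <- architecture_preset("OCD_GLOBAL")
  expect_equal(ocd$h2_liability, 0.37)
  expect_equal(ocd$prevalence_K, 0.025)
  expect_equal(architecture_preset("TS_MAF")$partition_shares[["maf_bin1"]], 0.21)
  expect_equal(architecture_preset("OCD_MAF")$partition_shares[["maf_bin1"]], 0)
  expect_equal(architecture_preset("TS_GENIC")$partition_shares[["genic"]], 0.53)
  expect_equal(architecture_preset("TSOCD_BIVAR")$rg, 0.41)
  expect_equal(architecture_preset("OCD_EARLY")$h2_liability, 0.43)
  expect_equal(sum(architecture_preset("OCD_MAF")$partition_shares), 1, tolerance = 1e-12)

  path <- file.path(withr::local_tempdir(), "arch.yaml")
  write_architecture_yaml(ts, path)
  back <- read_architecture_yaml(path)
  expect_equal(back$h2_liability, ts$h2_liability)
  expect_equal(back$partition_shares, ts$partition_shares)

  expect_error(architecture("bad", 0.5, 0.1, c(a = 0.6, b = 0.5)),
               class = "snpher_config_error")
})
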