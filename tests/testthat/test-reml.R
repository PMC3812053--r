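test_that("restricted log-likelihood matches a direct matrix-formula evaluation", {
  set.seed(91)
  n <- 6
  A <- crossprod(matrix(rnorm(n * 12), 12, n)) / 12
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  s <- c(0.4, 0.8)
  # independent direct evaluation
  V <- s[1] * A + s[2] * diag(n)
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
  direct <- -0.5 * (log(det(V)) + log(det(t(X) %*% Vi %*% X)) +
                      drop(t(y) %*% P %*% y))
  expect_equal(reml_loglik(s, list(A), y, X), direct, tolerance = 1e-10)
})

test_that("identity GRM collapses the likelihood to the total variance", {
  set.seed(97)
  n <- 40; y <- rnorm(n)
  A <- diag(n)
  l1 <- reml_loglik(c(0.3, 0.7), list(A), y)
  l2 <- reml_loglik(c(0.7, 0.3), list(A), y)
  l3 <- reml_loglik(c(0.5, 0.5), list(A), y)
  expect_equal(l1, l2, tolerance = 1e-10)
  expect_equal(l1, l3, tolerance = 1e-10)
})

test_that("AI-REML matches a grid-search oracle on a small problem", {
  g <- tiny_panel(n = 50, m = 500, seed = 101)
  tr <- quant_trait(g, 0.5, 100, seed = 102)
  grm <- compute_grm(g)
  fit <- reml_fit(grm, tr$y)
  # grid maximization of the pure likelihood surface
  grid <- expand.grid(sg = seq(0.01, 1.2, length.out = 50),
                      se = seq(0.01, 1.2, length.out = 50))
  ll <- mapply(function(a, b) reml_loglik(c(a, b), grm, tr$y),
               grid$sg, grid$se)
  best <- grid[which.max(ll), ]
  res <- diff(seq(0.01, 1.2, length.out = 50))[1]
  expect_lt(abs(fit$sigma2[["V(G)"]] - best$sg), res)
  expect_lt(abs(fit$sigma2[["V(e)"]] - best$se), res)
  expect_gte(fit$loglik, max(ll) - 1e-6)
  # first-order conditions at an interior optimum
  eps <- 1e-5
  for (j in 1:2) {
    sp <- sm <- unname(fit$sigma2)
    sp[j] <- sp[j] + eps; sm[j] <- sm[j] - eps
    ngrad <- (reml_loglik(sp, grm, tr$y) - reml_loglik(sm, grm, tr$y)) / (2 * eps)
    expect_lt(abs(ngrad), 1e-4 * abs(fit$loglik) + 1e-3)
  }
})

test_that("eigen and dense engines maximize the same likelihood", {
  g <- tiny_panel(n = 80, m = 400, seed = 103)
  tr <- quant_trait(g, 0.4, 80, seed = 104)
  grm <- compute_grm(g)
  X <- matrix(rnorm(80 * 3), 80, 3)
  f1 <- reml_fit(grm, tr$y, X, options = list(method = "eigen"))
  f2 <- reml_fit(grm, tr$y, X, options = list(method = "dense"))
  expect_equal(unname(f1$sigma2), unname(f2$sigma2), tolerance = 1e-5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(unname(f1$se_sigma2), unname(f2$se_sigma2), tolerance = 1e-4)
})

test_that("quantitative-trait heritability is recovered without bias", {
  est <- vapply(131:136, function(seed) {
    g <- tiny_panel(n = 500, m = 1500, seed = seed,
                    maf_spectrum = maf_uniform(0.05, 0.5))
    tr <- quant_trait(g, 0.5, 300, seed = seed + 1)
    fit <- reml_fit(compute_grm(g), tr$y)
    fit$h2_observed$total
  }, 0)
  # se per replicate ~ sqrt(2M)/n ~ 0.11; mean of 6 ~ 0.045
  expect_lt(abs(mean(est) - 0.5), 0.14)
})

test_that("joint two-GRM fit recovers both variance shares", {
  set.seed(107)
  g <- tiny_panel(n = 600, m = 2000, seed = 109,
                  maf_spectrum = maf_uniform(0.05, 0.5))
  p <- attr(g, "p_gen")
  W <- sweep(sweep(g$calls, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  i1 <- 1:1000; i2 <- 1001:2000
  b1 <- rnorm(300, 0, sqrt(0.3 / 300)); b2 <- rnorm(300, 0, sqrt(0.2 / 300))
  b1 <- b1 * sqrt(0.3 / sum(b1^2)); b2 <- b2 * sqrt(0.2 / sum(b2^2))
  y <- W[, 1:300] %*% b1 + W[, 1001:1300] %*% b2 + rnorm(600, 0, sqrt(0.5))
  fit <- reml_fit(list(compute_grm(g, i1), compute_grm(g, i2)), as.numeric(y))
  expect_lt(abs(fit$sigma2[["V(G1)"]] - 0.3), 0.17)
  expect_lt(abs(fit$sigma2[["V(G2)"]] - 0.2), 0.15)
  expect_equal(fit$h2_observed$total,
               unname((fit$sigma2[1] + fit$sigma2[2]) / sum(fit$sigma2)),
               tolerance = 1e-10)
})

test_that("permuted phenotypes drive the genetic component to the boundary", {
  g <- tiny_panel(n = 300, m = 1000, seed = 113)
  tr <- quant_trait(g, 0.6, 200, seed = 114)
  set.seed(115)
  yperm <- sample(tr$y)
  fit <- reml_fit(compute_grm(g), yperm)
  expect_lt(fit$h2_observed$total, 0.35)
})

test_that("rescaling the phenotype rescales variances but not h2 or the fit ranking", {
  g <- tiny_panel(n = 120, m = 500, seed = 117)
  tr <- quant_trait(g, 0.5, 100, seed = 118)
  grm <- compute_grm(g)
  f1 <- reml_fit(grm, tr$y)
  f2 <- reml_fit(grm, 3 * tr$y)
  expect_equal(unname(f2$sigma2), unname(9 * f1$sigma2), tolerance = 1e-3)
  expect_equal(f2$h2_observed$total, f1$h2_observed$total, tolerance = 1e-4)
})

test_that("LRT uses the boundary mixture and closed forms", {
  g <- tiny_panel(n = 60, m = 200, seed = 119)
  tr <- quant_trait(g, 0.5, 50, seed = 120)
  fit <- reml_fit(compute_grm(g), tr$y)
  same <- reml_lrt(fit, fit_reduced = structure(
    list(loglik = fit$loglik, n = fit$n, n_components = 0), class = "vc_fit"),
    boundary = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 0.5)
  # closed form: stat 3.84 under the 50:50 mixture
  mock_full <- structure(list(loglik = 1.92, n = 60, n_components = 1), class = "vc_fit")
  mock_red <- structure(list(loglik = 0, n = 60, n_components = 0), class = "vc_fit")
  out <- reml_lrt(mock_full, mock_red, boundary = TRUE)
  expect_equal(out$p, 0.5 * pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(out$p, 0.025, tolerance = 1e-3)
  non <- reml_lrt(mock_full, mock_red, boundary = FALSE)
  expect_equal(non$p, pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_error(reml_lrt(mock_red, mock_full), class = "snpher_precondition_error")
})

test_that("LRT type-I error is calibrated under the null", {
  # null: no genetic effect; small n, shared GRM, many replicates
  g <- tiny_panel(n = 100, m = 400, seed = 121)
  grm <- compute_grm(g)
  Xf <- matrix(1, 100, 1)
  set.seed(122)
  pvals <- replicate(200, {
    y <- rnorm(100)
    fit <- reml_fit(grm, y)
    null_ll <- snpher:::reml_null_loglik(y, Xf)
    stat <- max(0, 2 * (fit$loglik - null_ll))
    0.5 * pchisq(stat, 1, lower.tail = FALSE)
  })
  rate <- mean(pvals < 0.05)
  # binomial 99% CI half-width at p=0.05, n=200 is ~0.04
  expect_lt(abs(rate - 0.05), 0.045)
})

test_that("degenerate inputs raise typed errors", {
  g <- tiny_panel(n = 30, m = 100, seed = 123,
                  maf_spectrum = maf_uniform(0.1, 0.5))
  grm <- compute_grm(g)
  expect_error(reml_fit(grm, rep(1, 30)), class = "snpher_precondition_error")
  expect_error(reml_fit(grm, rnorm(30), X = cbind(1, 1:30, 2 * (1:30))),
               class = "snpher_precondition_error")
  expect_error(reml_loglik(c(0.5), grm, rnorm(30)),
               class = "snpher_precondition_error")
})
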