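#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates, as a pure function,
#' \deqn{\ell_R(\sigma^2) = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| +
#'   y'Py\right]}
#' (no additive constant) with \eqn{V = \sum_j \sigma^2_j A_j +
#' \sigma^2_e I} and \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}}.
#' The last element of \code{sigma2} is the residual variance.
#'
#' @param sigma2 numeric vector: one variance per GRM, then the residual.
#' @param grms a \code{grm}, a list of \code{grm}s, or a list of n x n
#'   relationship matrices.
#' @param y numeric response.
#' @param X fixed-effect design matrix (default: intercept only).
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(sigma2, grms, y, X = NULL) {
  designs <- c(as_design_list(grms, length(y)), list(diag(length(y))))
  if (length(sigma2) != length(designs))
    stop_snpher("snpher_precondition_error",
                "need %d variance components (got %d)",
                length(designs), length(sigma2))
  X <- X %||% matrix(1, length(y), 1)
  V <- Reduce(`+`, Map(`*`, designs, sigma2))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    stop_snpher("snpher_numeric_error",
                "V is not positive definite at sigma2 = (%s)",
                paste(signif(sigma2, 4), collapse = ", "))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  W <- solve(XtViX)
  Py <- Vi %*% y - ViX %*% (W %*% crossprod(ViX, y))
  as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                     determinant(XtViX, logarithm = TRUE)$modulus +
                     sum(y * Py)))
}

as_design_list <- function(grms, n) {
  if (inherits(grms, "grm")) grms <- list(grms)
  lapply(grms, function(a) {
    A <- if (inherits(a, "grm")) a$A else as.matrix(a)
    if (!all(dim(A) == c(n, n)))
      stop_snpher("snpher_precondition_error",
                  "GRM dimension %dx%d does not match n = %d",
                  nrow(A), ncol(A), n)
    A
  })
}

# --- dense AI-REML engine: arbitrary symmetric design matrices ----------

ai_engine_dense <- function(designs, y, X) {
  n <- length(y)
  function(sigma) {
    V <- Reduce(`+`, Map(`*`, designs, sigma))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    W <- tryCatch(solve(XtViX), error = function(e) NULL)
    if (is.null(W)) return(NULL)
    P <- Vi - ViX %*% W %*% t(ViX)
    Py <- P %*% y
    yPy <- sum(y * Py)
    logL <- as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                               determinant(XtViX, logarithm = TRUE)$modulus +
                               yPy))
    m <- length(designs)
    trPD <- vapply(designs, function(D) sum(P * D), 0)
    U <- vapply(designs, function(D) as.numeric(D %*% Py), numeric(n))
    yPDPy <- as.numeric(crossprod(U, Py))
    grad <- -0.5 * (trPD - yPDPy)
    AI <- 0.5 * crossprod(U, P %*% U)
    list(logL = logL, grad = grad, AI = AI, yPDPy = yPDPy, trPD = trPD)
  }
}

# --- eigen-rotated engine for a single GRM plus residual ----------------
# After rotating by the GRM eigenvectors every iteration is O(n p^2),
# which makes replicate studies and permutation nulls cheap.

ai_engine_eigen <- function(A, y, X) {
  ee <- eigen(A, symmetric = TRUE)
  lam <- ee$values
  Xt <- crossprod(ee$vectors, X)
  yt <- as.numeric(crossprod(ee$vectors, y))
  n <- length(y)
  applyP <- function(v_over_d, Xd, W) {
    # P v given v already divided by d
    v_over_d - Xd %*% (W %*% crossprod(Xt, v_over_d))
  }
  function(sigma) {
    d <- sigma[1] * lam + sigma[2]
    if (any(d <= 0)) return(NULL)
    Xd <- Xt / d
    XtViX <- crossprod(Xt, Xd)
    W <- tryCatch(solve(XtViX), error = function(e) NULL)
    if (is.null(W)) return(NULL)
    Pyt <- as.numeric(applyP(yt / d, Xd, W))
    yPy <- sum(yt * Pyt)
    logL <- as.numeric(-0.5 * (sum(log(d)) +
                               determinant(XtViX, logarithm = TRUE)$modulus +
                               yPy))
    B_A <- crossprod(Xt, Xt * (lam / d^2))
    B_I <- crossprod(Xt, Xt / d^2)
    trPA <- sum(lam / d) - sum(W * B_A)
    trPI <- sum(1 / d) - sum(W * B_I)
    U <- cbind(lam * Pyt, Pyt)
    yPDPy <- c(sum(lam * Pyt^2), sum(Pyt^2))
    PU <- apply(U, 2, function(u) as.numeric(applyP(u / d, Xd, W)))
    AI <- 0.5 * crossprod(U, PU)
    list(logL = logL, grad = -0.5 * (c(trPA, trPI) - yPDPy),
         AI = AI, yPDPy = yPDPy, trPD = c(trPA, trPI))
  }
}

# --- shared optimizer ----------------------------------------------------

ai_reml <- function(engine, init, var_p, n,
                    constraint = rep("nonneg", length(init)),
                    options = list()) {
  maxit <- options$maxit %||% 100L
  tol_logl <- options$tol_logl %||% 1e-6
  tol_param <- options$tol_param %||% 1e-8
  floor_val <- (options$floor_frac %||% 1e-6) * var_p
  fixed <- options$fixed %||% rep(FALSE, length(init))

  sigma <- init
  sigma[constraint == "nonneg" & sigma < floor_val & !fixed] <- floor_val
  st <- engine(sigma)
  if (is.null(st))
    stop_snpher("snpher_numeric_error", "V not positive definite at start")
  converged <- FALSE; it <- 0L
  for (it in seq_len(maxit)) {
    # active set: floored components whose gradient points below the floor
    # are held there for this iteration (constrained optimum handling)
    pinned <- constraint == "nonneg" & sigma <= floor_val * (1 + 1e-12) &
      st$grad < 0
    act <- which(!fixed & !pinned)
    if (length(act) == 0) { converged <- TRUE; break }
    delta <- numeric(length(sigma))
    if (it == 1L) {
      # one EM warm-up step: guaranteed uphill, robust far from optimum
      delta[act] <- (sigma^2 / n * (st$yPDPy - st$trPD))[act]
    } else {
      AI <- st$AI[act, act, drop = FALSE]
      g <- st$grad[act]
      delta[act] <- tryCatch(solve(AI, g), error = function(e)
        solve(AI + diag(1e-6 * max(diag(AI)), nrow(AI)), g))
    }
    # step-halving on boundary violation or likelihood decrease
    step <- 1; new_st <- NULL; new_sigma <- sigma
    repeat {
      trial <- sigma + step * delta
      trial[constraint == "nonneg" & trial < floor_val & !fixed] <- floor_val
      ts <- engine(trial)
      if (!is.null(ts) && ts$logL >= st$logL - 1e-10) {
        new_st <- ts; new_sigma <- trial
        break
      }
      step <- step / 2
      if (step < 2^-10) break
    }
    if (is.null(new_st)) {
      # no uphill step: converged if the active gradient is already flat
      converged <- max(abs(st$grad[act])) < 1e-3 * max(1, abs(st$logL) * 1e-4)
      break
    }
    dlogl <- new_st$logL - st$logL
    at_floor <- constraint == "nonneg" & new_sigma <= floor_val * (1 + 1e-12)
    relpar <- abs(new_sigma - sigma) / pmax(abs(sigma), 1e-12)
    relpar[at_floor | fixed] <- 0
    sigma <- new_sigma; st <- new_st
    if (it > 1 && abs(dlogl) < tol_logl && max(relpar) < tol_param) {
      converged <- TRUE
      break
    }
  }
  free_idx <- which(!fixed)
  AIfree <- st$AI[free_idx, free_idx, drop = FALSE]
  covmat <- matrix(NA_real_, length(sigma), length(sigma))
  cf <- tryCatch(solve(AIfree), error = function(e)
    solve(AIfree + diag(1e-8 * max(diag(AIfree)), nrow(AIfree))))
  covmat[free_idx, free_idx] <- cf
  list(sigma = sigma, se = sqrt(pmax(diag(covmat), 0)), cov = covmat,
       logL = st$logL, n_iter = it, converged = converged,
       boundary = constraint == "nonneg" &
         sigma <= floor_val * (1 + 1e-12),
       floor = floor_val, grad = st$grad)
}

#' Fit a variance-component model by AI-REML
#'
#' Average-information REML for one or more GRMs plus an independent
#' residual, with fixed-effect covariates. Components are initialized at
#' \eqn{\sigma^2_p / (m + 1)} each, one EM warm-up step is taken, then AI
#' (Newton-type) updates with step-halving whenever a step would decrease
#' the restricted likelihood or leave the positive-definite cone.
#' Components are constrained to at least \code{1e-6} of the phenotypic
#' variance (boundary hits are flagged). Convergence requires the
#' log-likelihood change below \code{1e-6} and the maximum relative
#' parameter change below \code{1e-8} (at most 100 iterations). Standard
#' errors come from the inverse average-information matrix; observed-scale
#' heritabilities use the delta method.
#'
#' A single-GRM model is fitted in the eigenbasis of the GRM (every
#' iteration is then linear in n); multi-GRM models use the dense path.
#' Both paths maximize the same restricted likelihood.
#'
#' @param grms a \code{grm}, list of \code{grm}s, or list of matrices.
#' @param y numeric response (0/1 for case-control).
#' @param X covariate matrix; an intercept column is prepended unless one
#'   is present (constant column).
#' @param options list: \code{maxit}, \code{tol_logl}, \code{tol_param},
#'   \code{floor_frac}, \code{method} ("auto", "eigen", "dense"),
#'   \code{init}.
#' @return an object of class \code{vc_fit}: \code{sigma2} (named, genetic
#'   components then residual), \code{se_sigma2}, \code{h2_observed}
#'   (per-component, with \code{total} and delta-method SEs),
#'   \code{loglik}, \code{n_iter}, \code{converged},
#'   \code{boundary_flags}, \code{n}, \code{cov_sigma2}.
#' @export
reml_fit <- function(grms, y, X = NULL, options = list()) {
  n <- length(y)
  designs <- as_design_list(grms, n)
  m <- length(designs)
  X <- prep_X(X, n)
  if (qr(X)$rank < ncol(X))
    stop_snpher("snpher_precondition_error", "X is rank deficient")
  var_p <- stats::var(y)
  if (var_p == 0)
    stop_snpher("snpher_precondition_error", "phenotype has zero variance")
  init <- options$init %||% rep(var_p / (m + 1), m + 1)
  method <- options$method %||% "auto"
  use_eigen <- (method == "eigen") || (method == "auto" && m == 1)
  engine <- if (use_eigen) ai_engine_eigen(designs[[1]], y, X)
            else ai_engine_dense(c(designs, list(diag(n))), y, X)
  res <- ai_reml(engine, init, var_p, n,
                 constraint = rep("nonneg", m + 1), options = options)
  labels <- c(if (m == 1) "V(G)" else paste0("V(G", seq_len(m), ")"), "V(e)")
  sigma2 <- stats::setNames(res$sigma, labels)
  h2 <- h2_from_sigma(res$sigma, res$cov, genetic = seq_len(m))
  structure(list(sigma2 = sigma2, se_sigma2 = stats::setNames(res$se, labels),
                 cov_sigma2 = res$cov,
                 h2_observed = h2, loglik = res$logL, n_iter = res$n_iter,
                 converged = res$converged, boundary_flags = res$boundary,
                 n = n, n_components = m, grad = res$grad),
            class = "vc_fit")
}

prep_X <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1))
  X <- as.matrix(X)
  if (nrow(X) != n)
    stop_snpher("snpher_precondition_error", "X has %d rows, y has %d", nrow(X), n)
  if (!any(apply(X, 2, function(c) stats::sd(c) == 0))) X <- cbind(1, X)
  X
}

# delta-method h2 per component and total; cov is the AI-inverse
h2_from_sigma <- function(sigma, cov, genetic) {
  s <- sum(sigma)
  k <- length(sigma)
  per <- sigma[genetic] / s
  se_per <- vapply(genetic, function(j) {
    gr <- -sigma[j] / s^2 * rep(1, k)
    gr[j] <- gr[j] + 1 / s
    sqrt(max(0, crossprod(gr, cov %*% gr)))
  }, 0)
  gtot <- sum(sigma[genetic])
  gr <- rep(-gtot / s^2, k)
  gr[genetic] <- gr[genetic] + 1 / s
  se_tot <- sqrt(max(0, crossprod(gr, cov %*% gr)))
  list(per_component = per, se_per_component = se_per,
       total = gtot / s, se_total = as.numeric(se_tot))
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("AI-REML variance-component fit\n")
  for (i in seq_along(x$sigma2))
    cat(sprintf("  %-7s %10.6f (se %.6f)%s\n", names(x$sigma2)[i],
                x$sigma2[i], x$se_sigma2[i],
                if (x$boundary_flags[i]) " [boundary]" else ""))
  cat(sprintf("  h2 (observed scale) %.4f (se %.4f)\n",
              x$h2_observed$total, x$h2_observed$se_total))
  cat(sprintf("  logL %.4f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Likelihood-ratio test between nested REML fits
#'
#' Statistic \eqn{2(\ell_{full} - \ell_{reduced})}, floored at zero. When
#' the tested variance component sits on its zero boundary under the null,
#' the reference distribution is the 50:50 mixture of a point mass at zero
#' and \eqn{\chi^2_1}, giving \eqn{p = \tfrac12 P(\chi^2_1 > LRT)};
#' otherwise a plain \eqn{\chi^2} with df equal to the parameter
#' difference.
#'
#' @param fit_full,fit_reduced \code{vc_fit} objects on the same data, the
#'   reduced model nested in the full one.
#' @param boundary is the tested component on the boundary under the null?
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
reml_lrt <- function(fit_full, fit_reduced, boundary = TRUE) {
  if (fit_full$n != fit_reduced$n)
    stop_snpher("snpher_precondition_error", "fits are on different n")
  df <- fit_full$n_components - fit_reduced$n_components
  if (df < 1)
    stop_snpher("snpher_precondition_error", "reduced model is not nested in full")
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- if (boundary && df == 1) 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
       else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Write a fit as a GCTA-style .hsq table
#'
#' @param fit a \code{vc_fit}.
#' @param path output TSV.
#' @param lrt optional result of \code{\link{reml_lrt}}.
#' @return \code{path}, invisibly.
#' @export
write_hsq <- function(fit, path, lrt = NULL) {
  vp <- sum(fit$sigma2)
  rows <- data.frame(Source = c(names(fit$sigma2), "Vp",
                                paste0(names(fit$sigma2)[seq_len(fit$n_components)], "/Vp")),
                     Variance = c(unname(fit$sigma2), vp,
                                  unname(fit$h2_observed$per_component)),
                     SE = c(unname(fit$se_sigma2), NA,
                            unname(fit$h2_observed$se_per_component)))
  con <- file(path, "w")
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("logL\t%.6f", fit$loglik), con)
  if (!is.null(lrt)) {
    writeLines(sprintf("LRT\t%.6f", lrt$statistic), con)
    writeLines(sprintf("df\t%d", lrt$df), con)
    writeLines(sprintf("Pval\t%.6g", lrt$p), con)
  }
  writeLines(sprintf("n\t%d", fit$n), con)
  close(con)
  invisible(path)
}
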