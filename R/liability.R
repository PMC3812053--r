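#' Liability-threshold parameters
#'
#' @param K population prevalence in (0, 1).
#' @param P sample case fraction in (0, 1).
#' @return list with \code{K}, \code{P}, the liability threshold
#'   \code{T} = \eqn{\Phi^{-1}(1-K)} and the normal density at the
#'   threshold \code{z} = \eqn{\phi(T)}.
#' @export
liability_params <- function(K, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop_snpher("snpher_config_error", "K and P must lie in (0, 1)")
  Tthr <- stats::qnorm(1 - K)
  list(K = K, P = P, T = Tthr, z = stats::dnorm(Tthr))
}

#' Convert observed-scale heritability to the liability scale
#'
#' Case-control heritability estimated on the observed 0/1 scale is
#' rescaled to the latent liability scale, correcting for ascertainment:
#' \deqn{h^2_{liab} = h^2_{obs} \cdot
#'   \frac{K^2 (1-K)^2}{z^2 \, P(1-P)}}
#' with K the population prevalence, P the sample case fraction and z the
#' standard-normal density at the liability threshold. The standard error
#' is scaled by the same factor, which does not depend on
#' \eqn{h^2_{obs}}.
#'
#' @param h2_obs observed-scale estimate (>= 0).
#' @param se_obs its standard error.
#' @param params a \code{\link{liability_params}} object.
#' @return list with \code{h2_liab}, \code{se_liab} and \code{factor}.
#' @export
observed_to_liability <- function(h2_obs, se_obs, params) {
  if (any(h2_obs < 0))
    stop_snpher("snpher_precondition_error", "h2_obs must be >= 0")
  K <- params$K; P <- params$P; z <- params$z
  fac <- (K * (1 - K))^2 / (z^2 * P * (1 - P))
  list(h2_liab = h2_obs * fac, se_liab = se_obs * fac, factor = fac)
}

#' Liability heritability across a grid of assumed prevalences
#'
#' Recomputes the liability transform of a fixed observed-scale estimate
#' for each prevalence in a grid, mirroring published prevalence
#' sensitivity analyses.
#'
#' @param h2_obs,se_obs observed-scale estimate and SE.
#' @param P sample case fraction.
#' @param K_grid prevalences in (0, 1).
#' @return data.frame with columns \code{K}, \code{factor},
#'   \code{h2_liab}, \code{se_liab}.
#' @export
prevalence_sensitivity <- function(h2_obs, se_obs, P, K_grid) {
  rows <- lapply(K_grid, function(K) {
    r <- observed_to_liability(h2_obs, se_obs, liability_params(K, P))
    data.frame(K = K, factor = r$factor, h2_liab = r$h2_liab,
               se_liab = r$se_liab)
  })
  do.call(rbind, rows)
}

# upper-orthant probability P(L1 > T, L2 > T) of a standard bivariate
# normal with correlation rho, by adaptive quadrature over one margin
bvn_orthant_upper <- function(Tthr, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    if (rho > 0) return(stats::pnorm(Tthr, lower.tail = FALSE))
    return(max(0, 1 - 2 * stats::pnorm(Tthr)))
  }
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((Tthr - rho * x) / s, lower.tail = FALSE),
    Tthr, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Sibling (relative) recurrence risk implied by liability heritability
#'
#' Under the liability-threshold model, relatives sharing a fraction
#' \code{a} of additive genetic variance have liability correlation
#' \eqn{\rho = a h^2_{liab}}. The recurrence risk in relatives of a case
#' is \eqn{K_R = P(L_2 > T \mid L_1 > T)}, computed from the
#' bivariate-normal upper-orthant probability at correlation \eqn{\rho},
#' and \eqn{\lambda = K_R / K}.
#'
#' @param h2_liab liability-scale heritability in [0, 1].
#' @param K population prevalence.
#' @param relative_coefficient additive-sharing coefficient a in (0, 1]
#'   (0.5 for first-degree relatives).
#' @return list with \code{lambda}, \code{K_R}, \code{rho}.
#' @export
sibling_recurrence_risk <- function(h2_liab, K, relative_coefficient = 0.5) {
  if (h2_liab < 0 || h2_liab > 1)
    stop_snpher("snpher_precondition_error", "h2_liab must lie in [0, 1]")
  if (relative_coefficient <= 0 || relative_coefficient > 1)
    stop_snpher("snpher_precondition_error", "relative_coefficient must lie in (0, 1]")
  rho <- relative_coefficient * h2_liab
  Tthr <- stats::qnorm(1 - K)
  both <- bvn_orthant_upper(Tthr, rho)
  K_R <- both / K
  list(lambda = K_R / K, K_R = K_R, rho = rho)
}
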