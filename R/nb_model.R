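#' Mean-dependent negative-binomial dispersion
#'
#' Evaluates the dispersion trend \eqn{\alpha(\mu) = a + b/\mu}. `a` is the
#' asymptotic dispersion (the floor approached by highly expressed genes) and
#' `b` the extra-Poisson noise term that dominates at low expression.
#'
#' @param mu positive mean expression (vectorized).
#' @param a nonnegative asymptotic dispersion.
#' @param b nonnegative extra-Poisson noise.
#' @return Dispersion value(s) `a + b/mu`, always `>= a`.
#' @examples
#' dispersion_at(100, a = 0.01, b = 1) # 0.02
#' @export
dispersion_at <- function(mu, a, b) {
  stop_if(any(!is.finite(mu)) || any(mu <= 0), "`mu` must be positive")
  stop_if(a < 0 || b < 0, "hyperparameters `a` and `b` must be nonnegative")
  a + b / mu
}

#' Negative-binomial shape parameters from mean and dispersion
#'
#' Converts the (mean, dispersion) parameterization used throughout the
#' package into the classical `NB(n, p)` parameterization:
#' \eqn{\sigma^2 = \mu + \alpha \mu^2}, \eqn{p = \mu/\sigma^2},
#' \eqn{n = \mu^2 / (\sigma^2 - \mu)}, which simplifies to \eqn{n = 1/\alpha}.
#' At `alpha = 0` the variance collapses to the mean and the distribution
#' degenerates to Poisson; `n = Inf`, `p = 1` is returned and samplers treat
#' it as exact Poisson.
#'
#' @param mu positive mean (vectorized).
#' @param alpha nonnegative dispersion (vectorized).
#' @return A list with components `n` (size), `p` (success probability),
#'   and `sigma2` (the implied variance).
#' @examples
#' nb_shape(100, 0.02) # n = 50, p = 1/3, variance 300
#' @export
nb_shape <- function(mu, alpha) {
  stop_if(any(!is.finite(mu)) || any(mu <= 0), "`mu` must be positive")
  stop_if(any(alpha < 0), "`alpha` must be nonnegative")
  sigma2 <- mu + alpha * mu^2
  list(n = ifelse(alpha == 0, Inf, 1 / alpha),
       p = mu / sigma2,
       sigma2 = sigma2)
}

# Draw NB(mu, alpha) variates; exact Poisson when alpha == 0, exact zero
# when mu == 0. Vectorized over mu/alpha.
nb_sample <- function(mu, alpha) {
  n <- max(length(mu), length(alpha))
  mu <- rep_len(mu, n)
  alpha <- rep_len(alpha, n)
  out <- integer(n)
  zero <- mu == 0
  pois <- !zero & alpha == 0
  nb <- !zero & !pois
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), lambda = mu[pois])
  if (any(nb)) out[nb] <- stats::rnbinom(sum(nb), size = 1 / alpha[nb], mu = mu[nb])
  out
}
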