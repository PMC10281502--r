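#' Beta density in mean-precision parameterization
#'
#' Shape parameters are `a = mu * phi`, `b = (1 - mu) * phi`, giving mean
#' `mu` and variance `mu (1 - mu) / (1 + phi)`.
#'
#' @param x Values in (0, 1).
#' @param mu Mean in (0, 1).
#' @param phi Precision (> 0).
#' @param log Return log density?
#' @return (Log) density values.
#' @export
dbeta_mu_phi <- function(x, mu, phi, log = FALSE) {
  stats::dbeta(x, shape1 = mu * phi, shape2 = (1 - mu) * phi, log = log)
}

#' Random draws from the mean-precision beta
#'
#' @param n Number of draws.
#' @param mu Mean in (0, 1).
#' @param phi Precision (> 0).
#' @return Draws in (0, 1).
#' @export
rbeta_mu_phi <- function(n, mu, phi) {
  stats::rbeta(n, shape1 = mu * phi, shape2 = (1 - mu) * phi)
}

#' Log likelihood of the combined latent-muscle model
#'
#' The combined fitting process evaluates, for each dissected bear, (i) the
#' lognormal regression of total muscle on length and adipose mass and (ii)
#' the beta law for the storage-muscle proportion derived from the latent
#' structural muscle prediction. The beta term is evaluated only where the
#' derived proportion lies inside (0, 1); outside that support the log
#' likelihood is `-Inf` (the sampler treats such parameter values as
#' rejected).
#'
#' @param theta Named list or vector with `alpha_lU0`, `beta_lU1`,
#'   `beta_lU2`, `sd_lU`, `alpha_POu`, `beta_POu`, `phi1`.
#' @param U Observed total muscle mass, kg.
#' @param A Observed adipose mass, kg.
#' @param L Straight-line body length, m.
#' @param smi Scaled mass index per bear, kg.
#' @return Scalar log likelihood.
#' @export
loglik_combined <- function(theta, U, A, L, smi) {
  th <- as.list(theta)
  if (th$sd_lU <= 0 || th$phi1 <= 0) return(-Inf)
  mu_logU <- th$alpha_lU0 + th$beta_lU1 * log(L) + th$beta_lU2 * log(A)
  ll <- sum(stats::dnorm(log(U), mu_logU, th$sd_lU, log = TRUE))
  K_U <- exp(th$alpha_lU0 + th$beta_lU1 * log(L))
  O_U <- U - K_U
  if (any(O_U <= 0)) return(-Inf)
  P_OU <- O_U / (A + O_U)
  mu <- stats::plogis(th$alpha_POu + th$beta_POu * smi)
  ll + sum(dbeta_mu_phi(P_OU, mu, th$phi1, log = TRUE))
}

#' Log likelihood of a lognormal allometric regression
#'
#' `log(y) ~ Normal(alpha + beta * log(x), sd)`; used for the structure
#' non-muscle fit.
#'
#' @param theta Named list/vector with `alpha`, `beta`, `sd`.
#' @param y Response (positive), kg.
#' @param x Predictor (positive), m.
#' @return Scalar log likelihood.
#' @export
loglik_lognormal_reg <- function(theta, y, x) {
  th <- as.list(theta)
  if (th$sd <= 0) return(-Inf)
  sum(stats::dnorm(log(y), th$alpha + th$beta * log(x), th$sd, log = TRUE))
}

#' Log likelihood of a logit-link beta regression
#'
#' `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `mu = plogis(intercept + slope * x)`. Intercepts may vary by group (e.g.
#' sex) via `group`.
#'
#' @param theta Named list/vector: `alpha` (scalar or per-group vector named
#'   by group level), `beta`, `phi`.
#' @param y Proportions strictly inside (0, 1).
#' @param x Covariate.
#' @param group Optional character vector selecting the intercept per
#'   observation.
#' @return Scalar log likelihood.
#' @export
loglik_beta_reg <- function(theta, y, x, group = NULL) {
  th <- as.list(theta)
  if (th$phi <= 0) return(-Inf)
  alpha <- if (is.null(group)) th$alpha else unlist(th$alpha)[group]
  mu <- stats::plogis(alpha + th$beta * x)
  sum(dbeta_mu_phi(y, mu, th$phi, log = TRUE))
}
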