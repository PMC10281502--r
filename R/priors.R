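#' Prior sets for the Bayesian fitting processes
#'
#' Two named prior sets are available for every fitted parameter:
#'
#' * `"unrestricted"`: flat uniforms over ranges far wider than any plausible
#'   posterior (location and slope parameters over (-100, 100), residual SDs
#'   over (0, 100), beta precisions over (0, 1000)). These stand in for
#'   unbounded flat priors; propriety of the resulting posterior is assessed
#'   by comparison against the proper weakly-informative fit (see
#'   [prior_sensitivity()]).
#' * `"weakly_informative"`: Normal(0, sd 2) on location/slope parameters,
#'   Uniform(0, 1) on the log-scale residual SDs, half-Normal(0, sd 2) on the
#'   storage-allocation precision `phi1`, and Uniform(0, 100) on the adipose
#'   precisions `phi2`/`phi3`.
#'
#' @param name `"unrestricted"` or `"weakly_informative"`.
#' @return An object of class `prior_set`.
#' @export
prior_set <- function(name = c("weakly_informative", "unrestricted")) {
  name <- match.arg(name)
  if (name == "weakly_informative") {
    p <- list(
      loc = "%s ~ dnorm(0, 0.25)",
      # centered intercept given slope term: alpha = a_c - <mean predictor>,
      # so a_c | slopes ~ Normal(<mean predictor>, sd 2) keeps the Table
      # prior on alpha while sampling in the well-mixing centered coordinate
      loc_centered = "%s ~ dnorm(%s, 0.25)",
      sd = "%s ~ dunif(0, 1)",
      phi1 = "%s ~ dnorm(0, 0.25) T(0,)",
      phi23 = "%s ~ dunif(0, 100)"
    )
  } else {
    p <- list(
      loc = "%s ~ dunif(-100, 100)",
      loc_centered = "%s ~ dunif(%s - 100, %s + 100)",
      sd = "%s ~ dunif(0, 100)",
      phi1 = "%s ~ dunif(0, 1000)",
      phi23 = "%s ~ dunif(0, 1000)"
    )
  }
  structure(c(list(name = name), p), class = "prior_set")
}

# Render one prior statement.  kind selects the template; `par` is the JAGS
# variable; `mean_expr` is the conditional mean expression for centered
# intercepts.
prior_line <- function(priors, kind, par, mean_expr = NULL) {
  tpl <- priors[[kind]]
  if (kind == "loc_centered") {
    if (priors$name == "weakly_informative") {
      sprintf(tpl, par, mean_expr)
    } else {
      sprintf(tpl, par, mean_expr, mean_expr)
    }
  } else {
    sprintf(tpl, par)
  }
}
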