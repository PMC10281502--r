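#' Split-R-hat for one parameter
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so within-chain trends register as apparent non-convergence.
#'
#' @param chains List of numeric vectors, one per chain (equal lengths).
#' @return Split-R-hat (>= 1; values near 1 indicate convergence).
#' @export
split_rhat <- function(chains) {
  if (length(chains) < 2L) {
    stop("R-hat requires at least 2 chains", call. = FALSE)
  }
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x)
    h <- floor(n / 2)
    list(x[seq_len(h)], x[(n - h + 1):n])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Convergence report for a posterior fit
#'
#' Checks per-parameter split-R-hat and effective sample size, and the
#' invalid-latent iteration count (reported in the `divergences` slot),
#' against thresholds.
#'
#' @param fit A `posterior_fit`.
#' @param rhat_threshold Maximum acceptable split-R-hat (default 1.01).
#' @param ess_threshold Minimum acceptable effective sample size
#'   (default 100).
#' @param max_divergences Maximum acceptable invalid-latent iterations
#'   (default 0).
#' @return An object of class `diagnostic_report`: per-parameter table plus
#'   overall `pass`.
#' @export
diagnose <- function(fit, rhat_threshold = 1.01, ess_threshold = 100,
                     max_divergences = 0) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (fit$diagnostics$chains < 2) {
    stop("R-hat unavailable: fit used a single chain", call. = FALSE)
  }
  tab <- data.frame(
    parameter = names(fit$diagnostics$rhat),
    rhat = unname(fit$diagnostics$rhat),
    ess = unname(fit$diagnostics$ess)
  )
  tab$rhat_ok <- tab$rhat <= rhat_threshold
  tab$ess_ok <- tab$ess >= ess_threshold
  div_ok <- fit$diagnostics$divergences <= max_divergences
  structure(list(
    model_name = fit$model_name,
    table = tab,
    divergences = fit$diagnostics$divergences,
    divergences_ok = div_ok,
    energy_fraction_flag = fit$diagnostics$energy_fraction_flag,
    thresholds = list(rhat = rhat_threshold, ess = ess_threshold,
                      divergences = max_divergences),
    pass = all(tab$rhat_ok) && all(tab$ess_ok) && div_ok
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Diagnostics for %s: %s\n", x$model_name,
              if (x$pass) "PASS" else "FAIL"))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("invalid-latent iterations: %d (max allowed %d)\n",
              x$divergences, x$thresholds$divergences))
  invisible(x)
}

#' Prior-sensitivity comparison of two fits
#'
#' Compares posterior means of the same model fitted to the same data under
#' two prior sets. Differences are reported in absolute terms and scaled by
#' the pooled posterior SD; parameters whose scaled difference exceeds the
#' tolerance are flagged.
#'
#' @param fit_a,fit_b `posterior_fit` objects for the same model/data.
#' @param tolerance Maximum acceptable SD-scaled difference (default 0.2).
#' @return An object of class `prior_sensitivity_report`.
#' @export
prior_sensitivity <- function(fit_a, fit_b, tolerance = 0.2) {
  stopifnot(inherits(fit_a, "posterior_fit"),
            inherits(fit_b, "posterior_fit"))
  pa <- fit_a$summary$parameter
  pb <- fit_b$summary$parameter
  if (!setequal(pa, pb)) {
    stop("fits have mismatched parameter sets", call. = FALSE)
  }
  sb <- fit_b$summary[match(pa, pb), ]
  abs_diff <- abs(fit_a$summary$mean - sb$mean)
  pooled_sd <- sqrt((fit_a$summary$sd^2 + sb$sd^2) / 2)
  scaled <- ifelse(pooled_sd > 0, abs_diff / pooled_sd,
                   ifelse(abs_diff > 0, Inf, 0))
  tab <- data.frame(parameter = pa,
                    mean_a = fit_a$summary$mean, mean_b = sb$mean,
                    abs_diff = abs_diff, pooled_sd = pooled_sd,
                    scaled_diff = scaled,
                    flagged = scaled > tolerance)
  structure(list(model_name = fit_a$model_name,
                 prior_sets = c(fit_a$prior_set, fit_b$prior_set),
                 table = tab, tolerance = tolerance,
                 pass = !any(tab$flagged)),
            class = "prior_sensitivity_report")
}

#' @export
print.prior_sensitivity_report <- function(x, ...) {
  cat(sprintf("Prior sensitivity (%s vs %s) for %s: %s\n",
              x$prior_sets[1], x$prior_sets[2], x$model_name,
              if (x$pass) "insensitive" else "sensitive"))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
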