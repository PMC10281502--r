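#' MCMC sampler configuration
#'
#' @param chains Number of chains (>= 2 so that R-hat is defined).
#' @param warmup_iterations Iterations discarded per chain (half used for
#'   JAGS adaptation, half for burn-in).
#' @param sampling_iterations Retained iterations per chain.
#' @param seed Integer seed; all chain RNGs are derived from it, so identical
#'   configs reproduce identical draws.
#' @param target_acceptance Retained for configuration compatibility with
#'   gradient-based samplers; the JAGS backend does not use it.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4, warmup_iterations = 1000,
                           sampling_iterations = 1000, seed = 1,
                           target_acceptance = 0.95) {
  if (chains < 2) stop("at least 2 chains are required", call. = FALSE)
  if (warmup_iterations <= 0 || sampling_iterations <= 0) {
    stop("iteration counts must be positive", call. = FALSE)
  }
  structure(list(chains = as.integer(chains),
                 warmup_iterations = as.integer(warmup_iterations),
                 sampling_iterations = as.integer(sampling_iterations),
                 seed = as.integer(seed),
                 target_acceptance = target_acceptance),
            class = "sampler_config")
}

chain_inits <- function(cfg, init_fun) {
  lapply(seq_len(cfg$chains), function(ch) {
    ini <- init_fun(ch)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- (cfg$seed * 97L + ch) %% .Machine$integer.max
    ini
  })
}

run_jags <- function(model_string, data, monitors, cfg, init_fun) {
  n_adapt <- max(100L, ceiling(cfg$warmup_iterations / 2))
  n_burn <- cfg$warmup_iterations - n_adapt
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = chain_inits(cfg, init_fun),
                          n.chains = cfg$chains, n.adapt = n_adapt,
                          quiet = TRUE)
  if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
  rjags::coda.samples(jm, variable.names = monitors,
                      n.iter = cfg$sampling_iterations,
                      progress.bar = "none")
}

# Assemble a posterior_fit from a coda::mcmc.list.  `params` names the
# model parameters (the remaining monitored columns, e.g. the invalid-latent
# counter, go to diagnostics).
make_posterior_fit <- function(model_name, samples, params, cfg, priors,
                               n_data, notes = list()) {
  mat_list <- lapply(samples, function(ch) as.matrix(ch))
  full <- do.call(rbind, mat_list)
  n_iter <- nrow(mat_list[[1]])
  draws <- data.frame(
    chain = rep(seq_along(mat_list), each = n_iter),
    iteration = rep(seq_len(n_iter), times = length(mat_list))
  )
  draws <- cbind(draws, as.data.frame(full[, params, drop = FALSE]))

  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  summ <- do.call(rbind, lapply(params, function(p) {
    x <- full[, p]
    q <- qs(x)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               q2.5 = q[1], median = q[2], q97.5 = q[3])
  }))

  rhat <- vapply(params, function(p) {
    split_rhat(lapply(mat_list, function(m) m[, p]))
  }, numeric(1))
  ess <- vapply(params, function(p) {
    as.numeric(coda::effectiveSize(coda::as.mcmc.list(
      lapply(mat_list, function(m) coda::mcmc(m[, p])))))
  }, numeric(1))

  invalid_iters <- 0L
  if ("invalid" %in% colnames(full)) {
    invalid_iters <- sum(full[, "invalid"] > 0)
  }

  structure(list(
    model_name = model_name,
    draws = draws,
    summary = summ,
    diagnostics = list(
      rhat = rhat,
      ess = ess,
      divergences = invalid_iters,
      energy_fraction_flag = NA,
      sampler = "JAGS (adaptive slice/Metropolis)",
      chains = cfg$chains,
      sampling_iterations = cfg$sampling_iterations
    ),
    prior_set = priors$name,
    n_data = n_data,
    config = cfg,
    notes = notes
  ), class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("Posterior fit: %s (n = %d, priors = %s)\n", x$model_name,
              x$n_data, x$prior_set))
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("max R-hat %.4f | min ESS %.0f | invalid-latent iterations %d\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess),
              x$diagnostics$divergences))
  invisible(x)
}

validate_dissection <- function(records, tolerance = 0.01) {
  req <- c("sex", "length", "mass", "U", "A", "hide", "viscera", "bones")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("dissection records missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tis <- records[c("U", "A", "hide", "viscera", "bones")]
  bad <- which(apply(tis, 1, function(r) any(r <= 0)))
  if (length(bad)) {
    stop("non-positive tissue mass in dissection record(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tot <- rowSums(tis)
  off <- abs(tot - records$mass) / records$mass
  if (any(off > tolerance)) {
    stop("tissue masses do not sum to total mass (beyond ",
         tolerance * 100, "% tolerance) in record(s) ",
         paste(which(off > tolerance), collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Combined latent-muscle fitting process
#'
#' Joint fit of the total-muscle allometry and the storage-allocation beta
#' regression on dissection records. Within each posterior draw, structural
#' muscle is `K_U = exp(alpha_lU0 + beta_lU1 log L)`, storage muscle is
#' `O_U = U - K_U`, and the derived proportion `P_OU = O_U / (A + O_U)`
#' enters a beta likelihood with mean `plogis(alpha_POu + beta_POu SMI)` and
#' precision `phi1`. Parameter values that push any derived proportion
#' outside (0, 1) receive an effectively infinite log-density penalty; the
#' number of sampled iterations in that region is reported as the
#' `divergences` diagnostic.
#'
#' @param records Data frame of dissection records (columns `sex`, `length`
#'   in m, `mass` in kg, tissue masses `U`, `A`, `hide`, `viscera`, `bones`
#'   in kg).
#' @param smi An [smi_params()] object used to compute each bear's SMI.
#' @param priors A [prior_set()].
#' @param cfg A [sampler_config()].
#' @param method `"joint"` (canonical) or `"two_stage"` (fit the muscle
#'   allometry first, then the beta regression on plug-in proportions; for
#'   testing/debugging).
#' @return A `posterior_fit` over `alpha_lU0`, `beta_lU1`, `beta_lU2`,
#'   `sd_lU`, `alpha_POu`, `beta_POu`, `phi1`.
#' @export
fit_combined <- function(records, smi, priors = prior_set(),
                         cfg = sampler_config(),
                         method = c("joint", "two_stage")) {
  method <- match.arg(method)
  validate_dissection(records)
  if (nrow(records) < 3L) {
    stop("identifiability error: at least 3 dissection records are required",
         call. = FALSE)
  }
  if (stats::sd(log(records$length)) == 0) {
    stop("identifiability error: no variance in log(length)", call. = FALSE)
  }
  if (stats::sd(log(records$A)) == 0) {
    stop("identifiability error: no variance in log(adipose)", call. = FALSE)
  }
  smi_v <- scaled_mass_index(records$mass, records$length, smi)
  if (method == "two_stage") {
    return(fit_combined_two_stage(records, smi_v, priors, cfg))
  }

  logL <- log(records$length); logA <- log(records$A)
  mlogL <- mean(logL); mlogA <- mean(logA); mSMI <- mean(smi_v)
  # orthogonalize the adipose covariate against log-length: the two are
  # strongly correlated, and sampling (length slope + residual-adipose
  # slope) removes the posterior ridge that stalls one-at-a-time updates;
  # priors are mapped through the reparameterization so the posterior on
  # the reported parameters is unchanged
  gA <- stats::cov(logA, logL) / stats::var(logL)

  model <- paste0("
model {
  for (i in 1:N) {
    logU[i] ~ dnorm(a1c + b1o * (logL[i] - mlogL)
                    + beta_lU2 * zA[i], tau_lU)
    KU[i] <- exp(alpha_lU0 + beta_lU1 * logL[i])
    OU[i] <- U[i] - KU[i]
    POUr[i] <- OU[i] / (A[i] + OU[i])
    ok[i] <- step(OU[i] - 1.0E-9)
    pc[i] <- max(min(POUr[i], 1 - 1.0E-9), 1.0E-9)
    muP[i] <- ilogit(a2c + beta_POu * (SMI[i] - mSMI))
    ll[i] <- ok[i] * logdensity.beta(pc[i], muP[i] * phi1,
                                     (1 - muP[i]) * phi1)
             - (1 - ok[i]) * 1.0E6
    zeros[i] ~ dpois(Cz - ll[i])
  }
  beta_lU1 <- b1o - gA * beta_lU2
  alpha_lU0 <- a1c - beta_lU1 * mlogL - beta_lU2 * mlogA
  alpha_POu <- a2c - beta_POu * mSMI
  invalid <- N - sum(ok[])
  tau_lU <- pow(sd_lU, -2)
  ", prior_line(priors, "loc", "beta_lU2"), "
  ", prior_line(priors, "loc_centered", "b1o", "gA * beta_lU2"), "
  ", prior_line(priors, "loc_centered", "a1c",
                "beta_lU1 * mlogL + beta_lU2 * mlogA"), "
  ", prior_line(priors, "sd", "sd_lU"), "
  ", prior_line(priors, "loc", "beta_POu"), "
  ", prior_line(priors, "loc_centered", "a2c", "beta_POu * mSMI"), "
  ", prior_line(priors, "phi1", "phi1"), "
}")

  data <- list(N = nrow(records), logU = log(records$U), logL = logL,
               zA = (logA - mlogA) - gA * (logL - mlogL),
               U = records$U, A = records$A, SMI = smi_v,
               mlogL = mlogL, mlogA = mlogA, mSMI = mSMI, gA = gA,
               zeros = rep(0, nrow(records)), Cz = 10)

  base_ini <- combined_inits(records, smi_v, cfg)
  ini <- function(chain) {
    b <- base_ini(chain)
    list(a1c = b$a1c, b1o = b$beta_lU1 + gA * b$beta_lU2,
         beta_lU2 = b$beta_lU2, sd_lU = b$sd_lU, a2c = b$a2c,
         beta_POu = b$beta_POu, phi1 = b$phi1)
  }
  samples <- run_jags(model, data,
                      c("alpha_lU0", "beta_lU1", "beta_lU2", "sd_lU",
                        "alpha_POu", "beta_POu", "phi1", "invalid"),
                      cfg, ini)
  fit <- make_posterior_fit(
    "combined", samples,
    c("alpha_lU0", "beta_lU1", "beta_lU2", "sd_lU", "alpha_POu",
      "beta_POu", "phi1"),
    cfg, priors, nrow(records))
  if (fit$diagnostics$divergences > 0.5 * cfg$chains *
      cfg$sampling_iterations) {
    warning("persistent invalid latent storage-muscle proportions: ",
            fit$diagnostics$divergences, " of ",
            cfg$chains * cfg$sampling_iterations,
            " iterations had O_U <= 0 for at least one bear",
            call. = FALSE)
  }
  fit
}

# Data-driven initial values for the combined fit: start the structural
# muscle curve strictly below every observed total muscle mass so the latent
# proportions begin inside the beta support.
combined_inits <- function(records, smi_v, cfg) {
  logL <- log(records$length); logA <- log(records$A)
  m0 <- stats::lm(log(records$U) ~ logL + logA)
  b1 <- unname(stats::coef(m0)[2])
  a0 <- min(log(records$U) - b1 * logL) - 0.2
  sd0 <- max(0.02, min(0.9, stats::sd(stats::resid(m0))))
  KU0 <- exp(a0 + b1 * logL)
  POU0 <- pmin(pmax((records$U - KU0) / (records$A + records$U - KU0),
                    0.02), 0.98)
  m1 <- stats::lm(stats::qlogis(POU0) ~ smi_v)
  mlogL <- mean(logL); mlogA <- mean(logA); mSMI <- mean(smi_v)
  function(chain) {
    set.seed(cfg$seed * 131L + chain)
    j <- function(s) stats::rnorm(1, 0, s)
    b1i <- b1 + j(0.02)
    b2i <- 0.05 + abs(j(0.02))
    a2i <- unname(stats::coef(m1)[1]) + j(0.05)
    bPi <- unname(stats::coef(m1)[2]) + j(0.001)
    list(a1c = a0 + j(0.02) + b1i * mlogL + b2i * mlogA,
         beta_lU1 = b1i, beta_lU2 = b2i,
         sd_lU = sd0 * exp(j(0.1)),
         a2c = a2i + bPi * mSMI, beta_POu = bPi,
         phi1 = max(0.5, 5 * exp(j(0.2))))
  }
}

fit_combined_two_stage <- function(records, smi_v, priors, cfg) {
  logL <- log(records$length); logA <- log(records$A)
  mlogL <- mean(logL); mlogA <- mean(logA)
  model1 <- paste0("
model {
  for (i in 1:N) {
    logU[i] ~ dnorm(a1c + beta_lU1 * (logL[i] - mlogL)
                    + beta_lU2 * (logA[i] - mlogA), tau_lU)
  }
  alpha_lU0 <- a1c - beta_lU1 * mlogL - beta_lU2 * mlogA
  tau_lU <- pow(sd_lU, -2)
  ", prior_line(priors, "loc", "beta_lU1"), "
  ", prior_line(priors, "loc", "beta_lU2"), "
  ", prior_line(priors, "loc_centered", "a1c",
                "beta_lU1 * mlogL + beta_lU2 * mlogA"), "
  ", prior_line(priors, "sd", "sd_lU"), "
}")
  data1 <- list(N = nrow(records), logU = log(records$U), logL = logL,
                logA = logA, mlogL = mlogL, mlogA = mlogA)
  m0 <- stats::lm(log(records$U) ~ logL + logA)
  ini1 <- function(chain) {
    set.seed(cfg$seed * 151L + chain)
    cf <- stats::coef(m0) + stats::rnorm(3, 0, 0.02)
    list(a1c = unname(cf[1] + cf[2] * mlogL + cf[3] * mlogA),
         beta_lU1 = unname(cf[2]), beta_lU2 = unname(cf[3]),
         sd_lU = max(0.02, min(0.9, stats::sd(stats::resid(m0)))))
  }
  s1 <- run_jags(model1, data1,
                 c("alpha_lU0", "beta_lU1", "beta_lU2", "sd_lU"), cfg, ini1)
  f1 <- make_posterior_fit("combined_stage1", s1,
                           c("alpha_lU0", "beta_lU1", "beta_lU2", "sd_lU"),
                           cfg, priors, nrow(records))

  a0 <- mean(f1$draws$alpha_lU0); b1 <- mean(f1$draws$beta_lU1)
  KU <- exp(a0 + b1 * logL)
  OU <- records$U - KU
  keep <- OU > 0
  if (sum(keep) < 3L) {
    stop("fit-failure: plug-in structural muscle leaves fewer than 3 valid ",
         "latent proportions (", sum(!keep), " invalid)", call. = FALSE)
  }
  POU <- OU[keep] / (records$A[keep] + OU[keep])
  f2 <- fit_beta_regression("combined_stage2", y = POU, x = smi_v[keep],
                            group = NULL, priors = priors, cfg = cfg,
                            par_names = c(alpha = "alpha_POu",
                                          beta = "beta_POu", phi = "phi1"),
                            phi_kind = "phi1")
  draws <- cbind(f1$draws,
                 f2$draws[c("alpha_POu", "beta_POu", "phi1")])
  fit <- make_posterior_fit_from_draws("combined_two_stage", draws, cfg,
                                       priors, nrow(records))
  fit$notes$invalid_plugin_records <- sum(!keep)
  fit
}

# Rebuild a posterior_fit from an existing draws data.frame (chain,
# iteration, parameters).
make_posterior_fit_from_draws <- function(model_name, draws, cfg, priors,
                                          n_data, notes = list()) {
  params <- setdiff(names(draws), c("chain", "iteration"))
  chains <- split(draws[params], draws$chain)
  samples <- lapply(chains, function(d) coda::mcmc(as.matrix(d)))
  make_posterior_fit(model_name, samples, params, cfg, priors, n_data,
                     notes = notes)
}

# Shared machinery for logit-link beta regressions (optionally with grouped
# intercepts).  par_names maps generic names to reported parameter names.
fit_beta_regression <- function(model_name, y, x, group, priors, cfg,
                                par_names, phi_kind) {
  if (any(y <= 0) || any(y >= 1)) {
    stop("proportions must lie strictly inside (0, 1)", call. = FALSE)
  }
  mx <- mean(x)
  n <- length(y)
  if (is.null(group)) {
    model <- paste0("
model {
  for (i in 1:N) {
    y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
    logit(mu[i]) <- ac + beta * (x[i] - mx)
  }
  alpha <- ac - beta * mx
  ", prior_line(priors, "loc", "beta"), "
  ", prior_line(priors, "loc_centered", "ac", "beta * mx"), "
  ", prior_line(priors, phi_kind, "phi"), "
}")
    data <- list(N = n, y = y, x = x, mx = mx)
    monitors <- c("alpha", "beta", "phi")
  } else {
    levels_g <- sort(unique(group))
    gi <- match(group, levels_g)
    model <- paste0("
model {
  for (i in 1:N) {
    y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
    logit(mu[i]) <- ac[g[i]] + beta * (x[i] - mx)
  }
  for (s in 1:G) {
    alpha[s] <- ac[s] - beta * mx
    ", prior_line(priors, "loc_centered", "ac[s]", "beta * mx"), "
  }
  ", prior_line(priors, "loc", "beta"), "
  ", prior_line(priors, phi_kind, "phi"), "
}")
    data <- list(N = n, y = y, x = x, mx = mx, g = gi, G = length(levels_g))
    monitors <- c("alpha", "beta", "phi")
  }
  m0 <- stats::lm(stats::qlogis(y) ~ x)
  ini <- function(chain) {
    set.seed(cfg$seed * 173L + chain)
    a <- unname(stats::coef(m0)[1]) + stats::rnorm(1, 0, 0.05)
    b <- unname(stats::coef(m0)[2]) + stats::rnorm(1, 0, 0.01)
    out <- list(beta = b, phi = max(1, 10 * exp(stats::rnorm(1, 0, 0.2))))
    if (is.null(group)) {
      out$ac <- a + b * mx
    } else {
      out$ac <- rep(a + b * mx, length(unique(group)))
    }
    out
  }
  samples <- run_jags(model, data, monitors, cfg, ini)

  if (is.null(group)) {
    fit <- make_posterior_fit(model_name, samples, monitors, cfg, priors, n)
    rn <- par_names[c("alpha", "beta", "phi")]
  } else {
    levels_g <- sort(unique(group))
    cols <- c(paste0("alpha[", seq_along(levels_g), "]"), "beta", "phi")
    fit <- make_posterior_fit(model_name, samples, cols, cfg, priors, n)
    rn <- c(par_names[paste0("alpha_", levels_g)],
            par_names[c("beta", "phi")])
  }
  old <- setdiff(names(fit$draws), c("chain", "iteration"))
  names(fit$draws)[match(old, names(fit$draws))] <- unname(rn)
  fit$summary$parameter <- unname(rn)
  names(fit$diagnostics$rhat) <- unname(rn)
  names(fit$diagnostics$ess) <- unname(rn)
  fit
}

#' Structure non-muscle fitting process
#'
#' Lognormal allometric regression of structure non-muscle (hide + viscera +
#' bones) on straight-line body length.
#'
#' @inheritParams fit_combined
#' @return A `posterior_fit` over `alpha_lKnU0`, `beta_lKnU1`, `sd_lKnU`.
#' @export
fit_structure_nonmuscle <- function(records, priors = prior_set(),
                                    cfg = sampler_config()) {
  validate_dissection(records)
  if (nrow(records) < 3L) {
    stop("identifiability error: at least 3 dissection records are required",
         call. = FALSE)
  }
  if (stats::sd(log(records$length)) == 0) {
    stop("identifiability error: no variance in log(length)", call. = FALSE)
  }
  KnU <- records$hide + records$viscera + records$bones
  logL <- log(records$length); mlogL <- mean(logL)
  model <- paste0("
model {
  for (i in 1:N) {
    logKnU[i] ~ dnorm(ac + beta_lKnU1 * (logL[i] - mlogL), tau)
  }
  alpha_lKnU0 <- ac - beta_lKnU1 * mlogL
  tau <- pow(sd_lKnU, -2)
  ", prior_line(priors, "loc", "beta_lKnU1"), "
  ", prior_line(priors, "loc_centered", "ac", "beta_lKnU1 * mlogL"), "
  ", prior_line(priors, "sd", "sd_lKnU"), "
}")
  data <- list(N = nrow(records), logKnU = log(KnU), logL = logL,
               mlogL = mlogL)
  m0 <- stats::lm(log(KnU) ~ logL)
  ini <- function(chain) {
    set.seed(cfg$seed * 191L + chain)
    cf <- stats::coef(m0) + stats::rnorm(2, 0, 0.02)
    list(ac = unname(cf[1] + cf[2] * mlogL), beta_lKnU1 = unname(cf[2]),
         sd_lKnU = max(0.02, min(0.9, stats::sd(stats::resid(m0)))))
  }
  samples <- run_jags(model, data,
                      c("alpha_lKnU0", "beta_lKnU1", "sd_lKnU"), cfg, ini)
  make_posterior_fit("structure_nonmuscle", samples,
                     c("alpha_lKnU0", "beta_lKnU1", "sd_lKnU"), cfg, priors,
                     nrow(records))
}

#' Adipose-lipid fitting process
#'
#' Beta regression of the lipid proportion of adipose biopsies on SMI with
#' sex-specific intercepts. If only one sex is present the missing sex's
#' intercept is informed by its prior alone and the fit is flagged.
#'
#' @param records Data frame of biopsy records (columns `sex`, `length`,
#'   `mass`, `P_AL` strictly inside (0, 1)).
#' @inheritParams fit_combined
#' @return A `posterior_fit` over `alpha_F`, `alpha_M`, `beta`, `phi2`.
#' @export
fit_adipose_lipid <- function(records, smi, priors = prior_set(),
                              cfg = sampler_config()) {
  req <- c("sex", "length", "mass", "P_AL")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("biopsy records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(records$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  if (any(records$P_AL <= 0) || any(records$P_AL >= 1)) {
    stop("P_AL must lie strictly inside (0, 1)", call. = FALSE)
  }
  smi_v <- scaled_mass_index(records$mass, records$length, smi)
  missing_sex <- setdiff(c("F", "M"), unique(records$sex))

  # both intercepts are always in the model; an absent sex contributes no
  # likelihood, so its intercept is informed by the prior alone
  fit <- fit_beta_regression_both_sexes(records, smi_v, priors, cfg)
  if (length(missing_sex)) fit$notes$missing_sex <- missing_sex
  fit
}

fit_beta_regression_both_sexes <- function(records, smi_v, priors, cfg) {
  mx <- mean(smi_v)
  gi <- ifelse(records$sex == "F", 1L, 2L)
  model <- paste0("
model {
  for (i in 1:N) {
    y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
    logit(mu[i]) <- ac[g[i]] + beta * (x[i] - mx)
  }
  for (s in 1:2) {
    alpha[s] <- ac[s] - beta * mx
    ", prior_line(priors, "loc_centered", "ac[s]", "beta * mx"), "
  }
  ", prior_line(priors, "loc", "beta"), "
  ", prior_line(priors, "phi23", "phi"), "
}")
  data <- list(N = nrow(records), y = records$P_AL, x = smi_v, mx = mx,
               g = gi)
  m0 <- stats::lm(stats::qlogis(records$P_AL) ~ smi_v)
  ini <- function(chain) {
    set.seed(cfg$seed * 173L + chain)
    a <- unname(stats::coef(m0)[1]) + stats::rnorm(1, 0, 0.05)
    b <- unname(stats::coef(m0)[2]) + stats::rnorm(1, 0, 0.01)
    list(ac = rep(a + b * mx, 2), beta = b,
         phi = max(1, 10 * exp(stats::rnorm(1, 0, 0.2))))
  }
  samples <- run_jags(model, data, c("alpha", "beta", "phi"), cfg, ini)
  fit <- make_posterior_fit("adipose_lipid", samples,
                            c("alpha[1]", "alpha[2]", "beta", "phi"), cfg,
                            priors, nrow(records))
  rn <- c("alpha_F", "alpha_M", "beta", "phi2")
  old <- setdiff(names(fit$draws), c("chain", "iteration"))
  names(fit$draws)[match(old, names(fit$draws))] <- rn
  fit$summary$parameter <- rn
  names(fit$diagnostics$rhat) <- rn
  names(fit$diagnostics$ess) <- rn
  fit
}

#' Adipose-protein fitting process
#'
#' Beta regression of the protein proportion of adipose on its lipid
#' proportion.
#'
#' @param records Data frame of adipose chemistry records (columns `P_AL`,
#'   `P_AP`, both strictly inside (0, 1)).
#' @inheritParams fit_combined
#' @return A `posterior_fit` over `alpha`, `beta`, `phi3`.
#' @export
fit_adipose_protein <- function(records, priors = prior_set(),
                                cfg = sampler_config()) {
  req <- c("P_AL", "P_AP")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("adipose chemistry records missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) < 3L) {
    stop("identifiability error: at least 3 records are required",
         call. = FALSE)
  }
  if (any(records$P_AP <= 0) || any(records$P_AP >= 1)) {
    stop("P_AP must lie strictly inside (0, 1)", call. = FALSE)
  }
  fit_beta_regression("adipose_protein", y = records$P_AP,
                      x = records$P_AL, group = NULL, priors = priors,
                      cfg = cfg,
                      par_names = c(alpha = "alpha", beta = "beta",
                                    phi = "phi3"),
                      phi_kind = "phi23")
}

#' Sex-varying variant of the combined fitting process
#'
#' As [fit_combined()] but with sex-indexed intercept and slope in the
#' storage-allocation regression, to probe sex differences in muscle
#' retention. Diagnostics are reported so that the degradation expected at
#' dissection-scale sample sizes is visible rather than hidden.
#'
#' @inheritParams fit_combined
#' @return A `posterior_fit` over `alpha_lU0`, `beta_lU1`, `beta_lU2`,
#'   `sd_lU`, `alpha_POu_F`, `alpha_POu_M`, `beta_POu_F`, `beta_POu_M`,
#'   `phi1`.
#' @export
fit_combined_sex_varying <- function(records, smi, priors = prior_set(),
                                     cfg = sampler_config()) {
  validate_dissection(records)
  if (!all(c("F", "M") %in% records$sex)) {
    stop("both sexes must be present for the sex-varying variant",
         call. = FALSE)
  }
  smi_v <- scaled_mass_index(records$mass, records$length, smi)
  logL <- log(records$length); logA <- log(records$A)
  mlogL <- mean(logL); mlogA <- mean(logA); mSMI <- mean(smi_v)
  gi <- ifelse(records$sex == "F", 1L, 2L)

  model <- paste0("
model {
  for (i in 1:N) {
    logU[i] ~ dnorm(a1c + beta_lU1 * (logL[i] - mlogL)
                    + beta_lU2 * (logA[i] - mlogA), tau_lU)
    KU[i] <- exp(alpha_lU0 + beta_lU1 * logL[i])
    OU[i] <- U[i] - KU[i]
    POUr[i] <- OU[i] / (A[i] + OU[i])
    ok[i] <- step(OU[i] - 1.0E-9)
    pc[i] <- max(min(POUr[i], 1 - 1.0E-9), 1.0E-9)
    muP[i] <- ilogit(a2c[g[i]] + bP[g[i]] * (SMI[i] - mSMI))
    ll[i] <- ok[i] * logdensity.beta(pc[i], muP[i] * phi1,
                                     (1 - muP[i]) * phi1)
             - (1 - ok[i]) * 1.0E6
    zeros[i] ~ dpois(Cz - ll[i])
  }
  alpha_lU0 <- a1c - beta_lU1 * mlogL - beta_lU2 * mlogA
  for (s in 1:2) {
    alpha_POu[s] <- a2c[s] - bP[s] * mSMI
    ", prior_line(priors, "loc", "bP[s]"), "
    ", prior_line(priors, "loc_centered", "a2c[s]", "bP[s] * mSMI"), "
  }
  invalid <- N - sum(ok[])
  tau_lU <- pow(sd_lU, -2)
  ", prior_line(priors, "loc", "beta_lU1"), "
  ", prior_line(priors, "loc", "beta_lU2"), "
  ", prior_line(priors, "loc_centered", "a1c",
                "beta_lU1 * mlogL + beta_lU2 * mlogA"), "
  ", prior_line(priors, "sd", "sd_lU"), "
  ", prior_line(priors, "phi1", "phi1"), "
}")
  data <- list(N = nrow(records), logU = log(records$U), logL = logL,
               logA = logA, U = records$U, A = records$A, SMI = smi_v,
               g = gi, mlogL = mlogL, mlogA = mlogA, mSMI = mSMI,
               zeros = rep(0, nrow(records)), Cz = 10)
  base_ini <- combined_inits(records, smi_v, cfg)
  ini <- function(chain) {
    b <- base_ini(chain)
    list(a1c = b$a1c, beta_lU1 = b$beta_lU1, beta_lU2 = b$beta_lU2,
         sd_lU = b$sd_lU, a2c = rep(b$a2c, 2), bP = rep(b$beta_POu, 2),
         phi1 = b$phi1)
  }
  samples <- run_jags(model, data,
                      c("alpha_lU0", "beta_lU1", "beta_lU2", "sd_lU",
                        "alpha_POu", "bP", "phi1", "invalid"), cfg, ini)
  fit <- make_posterior_fit(
    "combined_sex_varying", samples,
    c("alpha_lU0", "beta_lU1", "beta_lU2", "sd_lU", "alpha_POu[1]",
      "alpha_POu[2]", "bP[1]", "bP[2]", "phi1"),
    cfg, priors, nrow(records))
  rn <- c("alpha_lU0", "beta_lU1", "beta_lU2", "sd_lU", "alpha_POu_F",
          "alpha_POu_M", "beta_POu_F", "beta_POu_M", "phi1")
  old <- setdiff(names(fit$draws), c("chain", "iteration"))
  names(fit$draws)[match(old, names(fit$draws))] <- rn
  fit$summary$parameter <- rn
  names(fit$diagnostics$rhat) <- rn
  names(fit$diagnostics$ess) <- rn
  fit
}

#' Assemble a composition-parameter bundle from posterior fits
#'
#' Posterior means of the fitting processes become the point parameters used
#' by the deterministic composition chain.
#'
#' @param combined_fit Fit from [fit_combined()].
#' @param nonmuscle_fit Fit from [fit_structure_nonmuscle()].
#' @param lipid_fit Fit from [fit_adipose_lipid()].
#' @param protein_fit Fit from [fit_adipose_protein()].
#' @param smi An [smi_params()] object (typically from [fit_sma()]).
#' @param muscle,energy Constant components; defaults are the published
#'   bounds and energy densities.
#' @return A [composition_params()] object.
#' @export
fitted_composition_params <- function(combined_fit, nonmuscle_fit,
                                      lipid_fit, protein_fit, smi,
                                      muscle = muscle_composition_bounds(),
                                      energy = energy_densities()) {
  pm <- function(fit, par) {
    fit$summary$mean[match(par, fit$summary$parameter)]
  }
  composition_params(
    structural = structural_params(
      alpha_lU0 = pm(combined_fit, "alpha_lU0"),
      beta_lU1 = pm(combined_fit, "beta_lU1"),
      beta_lU2 = pm(combined_fit, "beta_lU2"),
      sd_lU = pm(combined_fit, "sd_lU"),
      alpha_lKnU0 = pm(nonmuscle_fit, "alpha_lKnU0"),
      beta_lKnU1 = pm(nonmuscle_fit, "beta_lKnU1"),
      sd_lKnU = pm(nonmuscle_fit, "sd_lKnU")),
    allocation = storage_allocation_params(
      alpha_POu = pm(combined_fit, "alpha_POu"),
      beta_POu = pm(combined_fit, "beta_POu"),
      phi1 = pm(combined_fit, "phi1")),
    adipose_lipid = adipose_lipid_params(
      alpha_F = pm(lipid_fit, "alpha_F"),
      alpha_M = pm(lipid_fit, "alpha_M"),
      beta = pm(lipid_fit, "beta"),
      phi2 = pm(lipid_fit, "phi2")),
    adipose_protein = adipose_protein_params(
      alpha = pm(protein_fit, "alpha"),
      beta = pm(protein_fit, "beta"),
      phi3 = pm(protein_fit, "phi3")),
    muscle = muscle, energy = energy, smi = smi)
}

#' Central posterior interval for each parameter
#'
#' @param fit A `posterior_fit`.
#' @param prob Central interval probability (default 0.95).
#' @return Data frame with `parameter`, `lower`, `upper`.
#' @export
posterior_interval <- function(fit, prob = 0.95) {
  a <- (1 - prob) / 2
  params <- setdiff(names(fit$draws), c("chain", "iteration"))
  do.call(rbind, lapply(params, function(p) {
    q <- stats::quantile(fit$draws[[p]], c(a, 1 - a), names = FALSE)
    data.frame(parameter = p, lower = q[1], upper = q[2])
  }))
}

#' Serialize a posterior fit
#'
#' Writes the summary and diagnostics as JSON and all draws as CSV (one
#' column per parameter plus `chain` and `iteration`).
#'
#' @param fit A `posterior_fit`.
#' @param json_path Path for the JSON report.
#' @param draws_path Optional path for the draws CSV.
#' @return `json_path`, invisibly.
#' @export
write_posterior_fit <- function(fit, json_path, draws_path = NULL) {
  obj <- list(model_name = fit$model_name, prior_set = fit$prior_set,
              n_data = fit$n_data,
              summary = fit$summary,
              diagnostics = list(
                rhat = as.list(fit$diagnostics$rhat),
                ess = as.list(fit$diagnostics$ess),
                divergences = fit$diagnostics$divergences,
                energy_fraction_flag = fit$diagnostics$energy_fraction_flag,
                sampler = fit$diagnostics$sampler),
              config = unclass(fit$config), notes = fit$notes)
  write_json_atomic(obj, json_path)
  if (!is.null(draws_path)) {
    write_csv_atomic(fit$draws, draws_path)
  }
  invisible(json_path)
}
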