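test_that("underdetermined or degenerate data raises identifiability errors", {
  cfg <- generator_config(seed = 51, n_dissection = 5)
  d <- gen_dissection(cfg)
  expect_error(fit_combined(d[1:2, ], truth_params$smi),
               "identifiability")
  d_flat <- d
  d_flat$length <- 1.8
  expect_error(fit_combined(d_flat, truth_params$smi), "variance")
  expect_error(fit_structure_nonmuscle(d[1:2, ]), "identifiability")
})

test_that("identical seed and config reproduce identical draws", {
  cfg <- generator_config(seed = 52, n_dissection = 20)
  d <- gen_dissection(cfg)
  f1 <- fit_structure_nonmuscle(d, prior_set("weakly_informative"),
                                quick_cfg(52, warmup = 200, sampling = 200))
  f2 <- fit_structure_nonmuscle(d, prior_set("weakly_informative"),
                                quick_cfg(52, warmup = 200, sampling = 200))
  expect_identical(f1$draws, f2$draws)
  # draw count contract: chains x sampling iterations
  expect_equal(nrow(f1$draws), 2 * 200)
})

test_that("noiseless allometry recovers its exponent almost exactly", {
  set.seed(53)
  L <- runif(40, 1.0, 2.5)
  KnU <- exp(2.47 + 3 * log(L))  # exact cubic, no residual noise
  d <- data.frame(id = as.character(1:40), sex = "F", length = L,
                  mass = KnU + 2, U = 1, A = 1,
                  hide = 0.35 * KnU, viscera = 0.30 * KnU,
                  bones = 0.35 * KnU)
  d$mass <- d$U + d$A + d$hide + d$viscera + d$bones
  f <- fit_structure_nonmuscle(d, prior_set("unrestricted"),
                               quick_cfg(53, warmup = 600, sampling = 800))
  est <- f$summary$mean[f$summary$parameter == "beta_lKnU1"]
  expect_lt(abs(est - 3), 0.01)
})

test_that("structure non-muscle exponent fits below 3 on realistic data", {
  cfg <- generator_config(seed = 54, n_dissection = 200)
  d <- gen_dissection(cfg)
  f <- fit_structure_nonmuscle(d, prior_set("weakly_informative"),
                               quick_cfg(54, warmup = 400, sampling = 600))
  expect_lt(f$summary$mean[f$summary$parameter == "beta_lKnU1"], 3)
})

test_that("adipose-lipid fit flags a missing sex instead of failing", {
  cfg <- generator_config(seed = 55, n_biopsy = 60)
  b <- gen_biopsy(cfg)
  b$sex <- "F"
  f <- fit_adipose_lipid(b, truth_params$smi, prior_set("weakly_informative"),
                         quick_cfg(55, warmup = 300, sampling = 400))
  expect_identical(f$notes$missing_sex, "M")
  # the prior-only male intercept carries prior-scale uncertainty
  sd_M <- f$summary$sd[f$summary$parameter == "alpha_M"]
  sd_F <- f$summary$sd[f$summary$parameter == "alpha_F"]
  expect_gt(sd_M, 4 * sd_F)
})

test_that("proportions at the support boundary are rejected as input", {
  cfg <- generator_config(seed = 56, n_biopsy = 20)
  b <- gen_biopsy(cfg)
  b$P_AL[3] <- 1
  expect_error(fit_adipose_lipid(b, truth_params$smi), "strictly inside")
  ch <- gen_adipose_chem(cfg)
  ch$P_AP[2] <- 0
  expect_error(fit_adipose_protein(ch), "strictly inside")
})

test_that("constant-proportion chemistry concentrates the slope near zero", {
  set.seed(57)
  ch <- data.frame(id = as.character(1:40),
                   P_AL = runif(40, 0.45, 0.75),
                   P_AP = rbeta_mu_phi(40, 0.25, 60))
  f <- fit_adipose_protein(ch, prior_set("weakly_informative"),
                           quick_cfg(57, warmup = 400, sampling = 600))
  ci <- posterior_interval(f)
  expect_true(ci$lower[ci$parameter == "beta"] < 0 &&
                ci$upper[ci$parameter == "beta"] > 0)
})

test_that("joint and two-stage combined fits agree on the allometry", {
  cfg <- generator_config(seed = 58, n_dissection = 60)
  d <- gen_dissection(cfg)
  fj <- fit_combined(d, truth_params$smi, prior_set("weakly_informative"),
                     quick_cfg(58, warmup = 500, sampling = 600))
  ft <- fit_combined(d, truth_params$smi, prior_set("weakly_informative"),
                     quick_cfg(58, warmup = 500, sampling = 600),
                     method = "two_stage")
  expect_s3_class(ft, "posterior_fit")
  expect_setequal(ft$summary$parameter, fj$summary$parameter)
  bj <- fj$summary$mean[fj$summary$parameter == "beta_lU1"]
  bt <- ft$summary$mean[ft$summary$parameter == "beta_lU1"]
  expect_lt(abs(bj - bt), 0.5)
  # both recover a negative condition slope for storage allocation
  expect_lt(fj$summary$mean[fj$summary$parameter == "beta_POu"], 0)
  expect_lt(ft$summary$mean[ft$summary$parameter == "beta_POu"], 0)
})

test_that("sex-varying allocation overlaps on sex-homogeneous data", {
  cfg <- generator_config(seed = 59, n_dissection = 60)
  d <- gen_dissection(cfg)  # truth has no sex effect in allocation
  f <- fit_combined_sex_varying(d, truth_params$smi,
                                prior_set("weakly_informative"),
                                quick_cfg(59, warmup = 500, sampling = 600))
  s <- f$summary
  dF <- s[s$parameter == "beta_POu_F", ]
  dM <- s[s$parameter == "beta_POu_M", ]
  # sex-level slopes overlap within 3 pooled SDs
  expect_lt(abs(dF$mean - dM$mean), 3 * sqrt(dF$sd^2 + dM$sd^2))
  expect_s3_class(diagnose(f, rhat_threshold = 1.2, ess_threshold = 10),
                  "diagnostic_report")
})

test_that("fitted parameter bundle assembles into a working chain", {
  cfg <- generator_config(seed = 60, n_dissection = 40, n_biopsy = 60,
                          n_chem = 25)
  d <- gen_dissection(cfg)
  b <- gen_biopsy(cfg)
  ch <- gen_adipose_chem(cfg)
  smi <- fit_sma(d$length, d$mass)
  qc <- quick_cfg(60, warmup = 300, sampling = 400)
  pr <- prior_set("weakly_informative")
  params <- fitted_composition_params(
    fit_combined(d, smi, pr, qc),
    fit_structure_nonmuscle(d, pr, qc),
    fit_adipose_lipid(b, smi, pr, qc),
    fit_adipose_protein(ch, pr, qc),
    smi)
  expect_s3_class(params, "composition_params")
  est <- full_composition(random_bears(20, 61), params)
  expect_true(all(is.finite(est$E_O[est$feasible])))
  # round-trip through JSON serialization
  path <- tempfile(fileext = ".json")
  write_composition_params(params, path)
  back <- read_composition_params(path)
  expect_equal(back$structural$alpha_lU0, params$structural$alpha_lU0)
  expect_equal(back$allocation$beta_POu, params$allocation$beta_POu)
  expect_equal(back$smi$b_sma, params$smi$b_sma)
})

test_that("posterior fits serialize to JSON and CSV", {
  cfg <- generator_config(seed = 62, n_dissection = 20)
  d <- gen_dissection(cfg)
  f <- fit_structure_nonmuscle(d, prior_set("weakly_informative"),
                               quick_cfg(62, warmup = 200, sampling = 200))
  jp <- tempfile(fileext = ".json")
  cp <- tempfile(fileext = ".csv")
  write_posterior_fit(f, jp, cp)
  obj <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(obj$model_name, "structure_nonmuscle")
  expect_equal(obj$summary$parameter,
               c("alpha_lKnU0", "beta_lKnU1", "sd_lKnU"))
  draws <- read.csv(cp)
  expect_equal(nrow(draws), nrow(f$draws))
  expect_true(all(c("chain", "iteration", "beta_lKnU1") %in% names(draws)))
})
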