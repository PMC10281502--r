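test_that("mean length averages the two captures", {
  r <- data.frame(len1 = c(1.80, 1.79), len2 = c(1.80, 1.83))
  expect_equal(mean_length(r), c(1.80, 1.81))
  expect_error(mean_length(data.frame(len1 = 1.8, len2 = NA)), "required")
})

test_that("structural mass cancels under the mean-length substitution", {
  cfg <- generator_config(seed = 81, isotopic_error_fraction = 0)
  rec <- gen_recapture(cfg)
  L <- mean_length(rec)
  e1 <- full_composition(data.frame(length = L, mass = rec$mass1,
                                    sex = rec$sex), truth_params)
  e2 <- full_composition(data.frame(length = L, mass = rec$mass2,
                                    sex = rec$sex), truth_params)
  expect_equal(e2$O - e1$O, rec$mass2 - rec$mass1, tolerance = 1e-9)
})

test_that("identical masses at both captures predict zero lipid change", {
  rec <- data.frame(id = "R1", subpop = "WH", sex = "F", class = "adult",
                    interval_days = 30, len1 = 1.9, mass1 = 250,
                    lipid1 = 60, len2 = 1.9, mass2 = 250, lipid2 = 60)
  pred <- predict_lipid_change(rec, truth_params)
  expect_equal(pred$predicted_dlipid, 0)
})

test_that("zero-noise recaptures round-trip through the prediction", {
  cfg <- generator_config(seed = 82, isotopic_error_fraction = 0)
  rec <- gen_recapture(cfg)
  pred <- predict_lipid_change(rec, truth_params, "avg")
  expect_true(all(pred$feasible))
  obs <- rec$lipid2 - rec$lipid1
  expect_lt(rmse(pred$predicted_dlipid, obs), 1e-6)
  expect_lt(max(abs(pred$predicted_dlipid - rec$true_dlipid)), 1e-6)
})

test_that("muscle-level bounds order with the storage-muscle change", {
  cfg <- generator_config(seed = 83, isotopic_error_fraction = 0)
  rec <- gen_recapture(cfg)
  pmin_ <- predict_lipid_change(rec, truth_params, "min")$predicted_dlipid
  pavg <- predict_lipid_change(rec, truth_params, "avg")$predicted_dlipid
  pmax_ <- predict_lipid_change(rec, truth_params, "max")$predicted_dlipid
  # the predicted lipid change is linear in the muscle lipid proportion
  # with coefficient equal to the change in storage muscle mass, so the
  # min/avg/max levels order with the sign of that change
  L <- mean_length(rec)
  e1 <- full_composition(data.frame(length = L, mass = rec$mass1,
                                    sex = rec$sex), truth_params)
  e2 <- full_composition(data.frame(length = L, mass = rec$mass2,
                                    sex = rec$sex), truth_params)
  up <- (e2$O_U - e1$O_U) > 0
  expect_true(all(pmin_[up] <= pavg[up] & pavg[up] <= pmax_[up]))
  expect_true(all(pmin_[!up] >= pavg[!up] & pavg[!up] >= pmax_[!up]))
  # the spread between bounds is proportional to |storage-muscle change|
  b <- muscle_composition_bounds()
  expect_equal(pmax_ - pmin_, (e2$O_U - e1$O_U) *
                 (b$lipid_max - b$lipid_min), tolerance = 1e-9)
})

test_that("records with an infeasible timepoint are excluded with reason", {
  rec <- data.frame(id = c("ok", "bad"), subpop = "WH", sex = "F",
                    class = "adult", interval_days = 40,
                    len1 = c(1.9, 2.2), mass1 = c(250, 90),
                    lipid1 = c(60, 5), len2 = c(1.9, 2.2),
                    mass2 = c(230, 85), lipid2 = c(50, 4))
  pred <- predict_lipid_change(rec, truth_params)
  expect_true(pred$feasible[1])
  expect_false(pred$feasible[2])
  expect_match(pred$exclusion_reason[2], "infeasible")
})

test_that("rmse matches hand-computed cases and scales linearly", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(2, 0), c(0, 0)), sqrt(2), tolerance = 1e-12)
  expect_equal(round(rmse(c(2, 0), c(0, 0)), 4), 1.4142)
  expect_equal(round(rmse(c(3, 4), c(0, 0)), 4), 3.5355)
  set.seed(84)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(rmse(7 * a, 7 * b), 7 * rmse(a, b))
  expect_equal(rmse(rev(a), rev(b)), rmse(a, b))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("paired length t-test matches the brute-force statistic", {
  set.seed(85)
  n <- 36
  rec <- data.frame(len1 = runif(n, 1.8, 2.3))
  rec$len2 <- rec$len1 + rnorm(n, 0, 0.02)
  tt <- paired_length_ttest(rec)
  d <- rec$len1 - rec$len2
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-12)
  expect_equal(tt$df, 35)
  expect_gte(tt$p, 0)

  # differences placed symmetrically around zero give t = 0, p = 1
  sym <- data.frame(len1 = c(1.9, 2.0, 2.1, 2.2))
  sym$len2 <- sym$len1 + c(-0.02, 0.02, -0.01, 0.01)
  tt0 <- paired_length_ttest(sym)
  expect_equal(tt0$t, 0, tolerance = 1e-12)
  expect_equal(tt0$p, 1, tolerance = 1e-12)

  same <- data.frame(len1 = c(1.9, 2.0), len2 = c(1.9, 2.0))
  expect_error(paired_length_ttest(same), "undefined")
})

test_that("model comparison tabulates subgroup and exclusion RMSEs", {
  cfg <- generator_config(seed = 86)
  rec <- gen_recapture(cfg)
  rep <- compare_models(rec, truth_params, single_storage_params(),
                        exclude_ids = rec$id[1:2])
  tab <- rep$rmse_table
  expect_true("all" %in% tab$group)
  expect_true(any(grepl("minus_excluded", tab$group)))
  # subgroup MSEs recompose to the overall MSE, record-weighted
  sub <- tab[tab$group %in% c("SB_F", "WH_F", "WH_M"), ]
  overall <- tab[tab$group == "all", ]
  expect_equal(sum(sub$n * sub$rmse_multi_iso^2) / sum(sub$n),
               overall$rmse_multi_iso^2, tolerance = 1e-9)
  expect_equal(sum(sub$n), overall$n)
  # per-bear table carries the isotopic error band and model bounds
  expect_true(all(rep$per_bear$iso_lower <= rep$per_bear$iso_upper))
  expect_true(all(rep$per_bear$multi_lower <= rep$per_bear$multi_upper))
  # non-adult records are rejected up front
  rec2 <- rec
  rec2$class[1] <- "subadult"
  expect_error(compare_models(rec2, truth_params, single_storage_params()),
               "adult")
})

test_that("a comparator that mirrors the multi model has zero model RMSE", {
  cfg <- generator_config(seed = 87, isotopic_error_fraction = 0)
  rec <- gen_recapture(cfg)
  rep <- compare_models(rec, truth_params, single_storage_params())
  pb <- rep$per_bear
  expect_equal(rmse(pb$multi_dlipid, pb$multi_dlipid), 0)
  # and against the zero-noise isotopic truth the multi model is exact
  expect_lt(rep$rmse_table$rmse_multi_iso[rep$rmse_table$group == "all"],
            1e-6)
})

test_that("validation reports serialize to CSV and JSON", {
  cfg <- generator_config(seed = 88)
  rec <- gen_recapture(cfg)
  rep <- compare_models(rec, truth_params, single_storage_params())
  csvp <- tempfile(fileext = ".csv")
  jsonp <- tempfile(fileext = ".json")
  write_validation_report(rep, csvp, jsonp)
  tab <- read.csv(csvp)
  expect_named(tab, c("group", "n", "rmse_multi_iso", "rmse_single_iso",
                      "rmse_multi_single"))
  obj <- jsonlite::read_json(jsonp, simplifyVector = TRUE)
  expect_equal(obj$muscle_level, "avg")
})
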