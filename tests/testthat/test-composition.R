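test_that("structural allometries reproduce closed-form values", {
  p <- structural_params(alpha_lU0 = 0, beta_lU1 = 3, alpha_lKnU0 = 0,
                         beta_lKnU1 = 3)
  expect_equal(structural_muscle_mass(1, p), 1)
  expect_equal(structural_muscle_mass(2, p), exp(3 * log(2)))
  expect_equal(structural_muscle_mass(2, p), 8)
  expect_equal(structure_nonmuscle_mass(1, p), 1)

  p2 <- structural_params(alpha_lU0 = 0, beta_lU1 = 3,
                          alpha_lKnU0 = log(2), beta_lKnU1 = 2)
  expect_equal(structure_nonmuscle_mass(0.5, p2), 0.5)

  # strictly increasing in length for positive exponents, positive always
  L <- seq(0.5, 2.6, length.out = 50)
  km <- structural_muscle_mass(L, p)
  expect_true(all(diff(km) > 0))
  expect_true(all(structure_nonmuscle_mass(L, p2) > 0))

  expect_error(structural_muscle_mass(0, p), "positive")
  expect_error(structure_nonmuscle_mass(-1, p), "positive")
})

test_that("structural mass is the sum of its two components", {
  p <- truth_params$structural
  expect_equal(structural_mass(1, structural_params(0, 3, alpha_lKnU0 = 0,
                                                    beta_lKnU1 = 3)), 2)
  set.seed(11)
  L <- runif(100, 0.8, 2.6)
  expect_equal(structural_mass(L, p),
               structural_muscle_mass(L, p) + structure_nonmuscle_mass(L, p))
})

test_that("storage mass flags infeasibility instead of erroring", {
  expect_equal(storage_mass(100, 100)$O, 0)
  expect_true(storage_mass(100, 100)$feasible)
  expect_equal(storage_mass(200, 80)$O, 120)
  r <- storage_mass(70, 80)
  expect_false(r$feasible)
  expect_true(is.na(r$O))
})

test_that("storage allocation follows the inverse-logit with SMI", {
  p0 <- storage_allocation_params(0, 0, 5)
  expect_equal(proportion_storage_muscle(123, p0), 0.5)
  p <- storage_allocation_params(0, -0.01, 5)
  expect_equal(proportion_storage_muscle(100, p), plogis(-1),
               tolerance = 1e-12)
  expect_equal(round(proportion_storage_muscle(100, p), 4), 0.2689)
  # decreasing across an SMI grid when the slope is negative
  grid <- seq(100, 250, by = 10)
  expect_true(all(diff(proportion_storage_muscle(grid,
                       truth_params$allocation)) < 0))
})

test_that("storage partition conserves mass exactly", {
  r <- partition_storage(50, 0.2)
  expect_equal(r$O_U, 10)
  expect_equal(r$A, 40)
  r0 <- partition_storage(0, 0.9)
  expect_equal(c(r0$O_U, r0$A), c(0, 0))
  set.seed(2)
  O <- rexp(1000, 1 / 50)
  P <- runif(1000)
  r <- partition_storage(O, P)
  expect_equal(r$O_U + r$A, O, tolerance = 1e-12)
  expect_error(partition_storage(10, 1.2), "0, 1")
})

test_that("adipose proportions follow their logit-linear laws", {
  pl <- adipose_lipid_params(alpha_F = 0, alpha_M = 0, beta = 0, phi2 = 5)
  expect_equal(adipose_lipid_proportion(170, "F", pl), 0.5)
  pl2 <- adipose_lipid_params(alpha_F = 1, alpha_M = 0, beta = 0, phi2 = 5)
  expect_equal(round(adipose_lipid_proportion(10, "F", pl2), 4), 0.7311)
  expect_equal(adipose_lipid_proportion(10, "M", pl2), 0.5)
  # female exceeds male at equal condition whenever alpha_F > alpha_M
  smi <- seq(120, 240, by = 20)
  expect_true(all(adipose_lipid_proportion(smi, "F",
                                           truth_params$adipose_lipid) >
                  adipose_lipid_proportion(smi, "M",
                                           truth_params$adipose_lipid)))
  expect_error(adipose_lipid_proportion(150, "X", pl), "sex")

  pp <- adipose_protein_params(alpha = 0, beta = 0, phi3 = 5)
  expect_equal(adipose_protein_proportion(0.3, pp), 0.5)
  pp2 <- adipose_protein_params(alpha = 1, beta = -2, phi3 = 5)
  expect_equal(adipose_protein_proportion(0.5, pp2), 0.5)
  # decay-like: decreasing in lipid proportion for negative slope
  x <- seq(0, 1, by = 0.1)
  expect_true(all(diff(adipose_protein_proportion(x,
                       truth_params$adipose_protein)) < 0))
  expect_error(adipose_protein_proportion(1.2, pp), "0, 1")
})

test_that("storage lipid, protein and energy arithmetic is exact", {
  expect_equal(storage_lipid_mass(0.5, 40, 0.0218, 10), 20.218)
  expect_equal(storage_lipid_mass(0.9, 0, 0.5, 0), 0)
  expect_equal(storage_protein_mass(0.1, 40, 0.3738, 10), 7.738)
  # bounded by total compartment masses
  set.seed(3)
  for (i in 1:20) {
    A <- runif(1, 0, 100); OU <- runif(1, 0, 40)
    pA <- runif(1); pU <- runif(1)
    expect_lte(storage_lipid_mass(pA, A, pU, OU), A + OU)
  }
  expect_equal(total_storage_energy(2, 0), 78.6)
  expect_equal(total_storage_energy(0, 0), 0)
  expect_equal(total_storage_energy(25, 0), 982.5)
  expect_error(total_storage_energy(-1, 0), "non-negative")
})

test_that("muscle energy density reproduces the printed sensitivity suite", {
  b <- muscle_composition_bounds()
  e_minmin <- muscle_energy_density(b$lipid_min, b$protein_min)
  e_maxmax <- muscle_energy_density(b$lipid_max, b$protein_max)
  expect_equal(e_minmin, 3.8899)
  expect_equal(e_maxmax, 14.0804)
  pct <- function(a, b) round(100 * (b - a) / a)
  expect_equal(pct(e_minmin, e_maxmax), 262)
  expect_equal(pct(e_minmin,
                   muscle_energy_density(b$lipid_min, b$protein_max)), 196)
  expect_equal(pct(muscle_energy_density(b$lipid_max, b$protein_min),
                   muscle_energy_density(b$lipid_max, b$protein_max)), 118)
  expect_equal(pct(e_minmin,
                   muscle_energy_density(b$lipid_max, b$protein_min)), 66)
  expect_equal(pct(muscle_energy_density(b$lipid_min, b$protein_max),
                   e_maxmax), 22)
})

test_that("age classification follows the sex-specific adult thresholds", {
  expect_equal(classify_age_class("F", 4), "adult")
  expect_equal(classify_age_class("M", 5), "subadult")
  expect_equal(classify_age_class("F", 0.75), "coy")
  expect_equal(classify_age_class(c("F", "M", "M", "F"),
                                  c(1.5, 6, 2, 3.9)),
               c("yearling", "adult", "subadult", "subadult"))
  expect_error(classify_age_class("X", 3), "sex")
})

test_that("identity-parameter bear chains to the hand-computed partition", {
  p <- identity_params()
  est <- full_composition(data.frame(length = 1, mass = 2.5, sex = "F"), p)
  expect_equal(est$K, 2)
  expect_equal(est$O, 0.5)
  expect_equal(est$P_OU, 0.5)
  expect_equal(est$O_U, 0.25)
  expect_equal(est$A, 0.25)
  expect_true(est$feasible)
})

test_that("full composition equals the composed unit operations", {
  bears <- random_bears(100, seed = 21)
  est <- full_composition(bears, truth_params, "avg")
  p <- truth_params
  smi <- scaled_mass_index(bears$mass, bears$length, p$smi)
  K_U <- structural_muscle_mass(bears$length, p$structural)
  K_nU <- structure_nonmuscle_mass(bears$length, p$structural)
  st <- storage_mass(bears$mass, K_U + K_nU)
  P_OU <- proportion_storage_muscle(smi, p$allocation)
  part <- partition_storage(st$O, P_OU)
  P_AL <- adipose_lipid_proportion(smi, bears$sex, p$adipose_lipid)
  P_AP <- adipose_protein_proportion(P_AL, p$adipose_protein)
  ml <- muscle_level(p$muscle, "avg")
  O_L <- storage_lipid_mass(P_AL, part$A, ml$lipid, part$O_U)
  O_P <- storage_protein_mass(P_AP, part$A, ml$protein, part$O_U)
  E_O <- total_storage_energy(O_L, O_P, p$energy)
  expect_equal(est$smi, smi, tolerance = 1e-9)
  expect_equal(est$O_U, part$O_U, tolerance = 1e-9)
  expect_equal(est$A, part$A, tolerance = 1e-9)
  expect_equal(est$O_L, O_L, tolerance = 1e-9)
  expect_equal(est$E_O, E_O, tolerance = 1e-9)
})

test_that("feasible estimates conserve mass to numerical precision", {
  bears <- random_bears(10000, seed = 31)
  est <- full_composition(bears, truth_params)
  expect_true(all(est$feasible))
  err <- abs(est$K_U + est$K_nU + est$O_U + est$A - bears$mass)
  expect_lt(max(err), 1e-9)
  # proportion closure
  pos <- est$O > 0
  expect_equal(est$O_U[pos] / est$O[pos] + est$A[pos] / est$O[pos],
               rep(1, sum(pos)), tolerance = 1e-12)
  # all masses non-negative, proportions inside [0, 1]
  expect_true(all(est$O_U >= 0 & est$A >= 0 & est$O_L >= 0 &
                    est$O_P >= 0 & est$E_O >= 0))
  expect_true(all(est$P_OU > 0 & est$P_OU < 1))
})

test_that("storage energy is non-decreasing in mass at fixed length", {
  for (sex in c("F", "M")) {
    masses <- seq(130, 500, by = 5)
    bears <- data.frame(length = 1.9, mass = masses, sex = sex)
    est <- full_composition(bears, truth_params)
    expect_true(all(diff(est$E_O[est$feasible]) > 0))
  }
})

test_that("infeasible bears are flagged with null storage fields", {
  bears <- data.frame(length = 2.2, mass = 50, sex = "F")
  est <- full_composition(bears, truth_params)
  expect_false(est$feasible)
  expect_true(is.na(est$O))
  expect_true(is.na(est$E_O))
  expect_gt(est$K, 50)  # structural prediction still reported
})
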