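test_that("single-storage energy follows its closed form", {
  p <- single_storage_params(structural_coefficient = 100 / 1.8^3,
                             structural_exponent = 3,
                             storage_lipid_fraction = 0.5,
                             storage_protein_fraction = 0.1)
  # at the structural boundary energy is exactly zero
  expect_equal(single_storage_energy(1.8, 100, p)$energy, 0)
  expect_equal(single_storage_energy(1.8, 150, p)$energy,
               50 * (0.5 * 39.3 + 0.1 * 18.4))
  expect_equal(single_storage_energy(1.8, 150, p)$energy, 1074.5)
  # affine in mass above the boundary
  m <- seq(110, 300, by = 10)
  e <- single_storage_energy(rep(1.8, length(m)), m, p)$energy
  expect_equal(diff(e), rep(diff(e)[1], length(m) - 1), tolerance = 1e-9)
  # below the boundary: flagged, not an error
  r <- single_storage_energy(1.8, 90, p)
  expect_false(r$feasible)
  expect_true(is.na(r$energy))
})

test_that("multi-storage surface cells equal the composition chain", {
  Lg <- seq(1.6, 2.4, length.out = 9)
  Mg <- seq(100, 450, length.out = 11)
  s <- multi_storage_surface(Lg, Mg, "F", truth_params)
  expect_equal(dim(s$energy), c(9, 11))
  idx <- expand.grid(i = c(1, 5, 9), j = c(1, 6, 11))
  for (k in seq_len(nrow(idx))) {
    i <- idx$i[k]; j <- idx$j[k]
    est <- full_composition(data.frame(length = Lg[i], mass = Mg[j],
                                       sex = "F"), truth_params)
    if (est$feasible) {
      expect_equal(s$energy[i, j], est$E_O)
      expect_true(s$feasible[i, j])
    } else {
      expect_false(s$feasible[i, j])
      expect_true(is.na(s$energy[i, j]))
    }
  }
  # energy along any fixed-length column is non-decreasing in mass
  for (i in seq_along(Lg)) {
    col <- s$energy[i, s$feasible[i, ]]
    if (length(col) > 1) expect_true(all(diff(col) > 0))
  }
  # energy is null exactly where infeasible
  expect_identical(is.na(s$energy), !s$feasible)
})

test_that("multi-storage energy is convex in mass under fitted-sign slopes", {
  # within the condition span the model was fit for; far beyond it the
  # logistic composition laws saturate and curvature flattens out
  m <- seq(140, 500, by = 2)
  est <- full_composition(data.frame(length = 1.9, mass = m, sex = "F"),
                          truth_params)
  span <- est$smi >= 130 & est$smi <= 230
  d2 <- diff(diff(est$E_O[span]))
  expect_true(all(d2 > -1e-9))
  expect_gt(mean(diff(est$E_O)[(length(m) - 20):(length(m) - 1)]),
            mean(diff(est$E_O)[1:20]))  # contour spacing narrows
})

test_that("with condition-invariant composition the chain is affine in mass", {
  p <- truth_params
  p$allocation <- storage_allocation_params(qlogis(0.2), 0, 10)
  p$adipose_lipid <- adipose_lipid_params(qlogis(0.6), qlogis(0.6), 0, 10)
  m <- seq(150, 400, by = 10)
  est <- full_composition(data.frame(length = 1.9, mass = m, sex = "M"), p)
  expect_equal(diff(est$E_O), rep(diff(est$E_O)[1], length(m) - 1),
               tolerance = 1e-9)
})

test_that("surface difference is cellwise and antisymmetric", {
  Lg <- seq(1.7, 2.3, length.out = 7)
  Mg <- seq(120, 400, length.out = 9)
  multi <- multi_storage_surface(Lg, Mg, "M", truth_params)
  single <- single_storage_surface(Lg, Mg, single_storage_params())
  d <- surface_difference(multi, single)
  both <- d$category == "both"
  expect_equal(d$difference[both],
               (multi$energy - single$energy)[both])
  # identical inputs give all zeros
  d0 <- surface_difference(multi, multi)
  expect_true(all(d0$difference[d0$category == "both"] == 0))
  # antisymmetry under swapping
  d_swap <- surface_difference(single, multi)
  expect_equal(d$difference[both], -d_swap$difference[both])
  # grid mismatch errors
  multi2 <- multi_storage_surface(Lg + 0.01, Mg, "M", truth_params)
  expect_error(surface_difference(multi2, single), "grids")
})

test_that("lower multi-storage structure opens a multi-only region", {
  # single-storage structural mass above the multi-storage curve
  single <- single_storage_params(structural_coefficient = 25)
  Lg <- seq(1.7, 2.3, length.out = 7)
  Mg <- seq(100, 400, length.out = 25)
  expect_true(all(single_storage_structural_mass(Lg, single) >
                    structural_mass(Lg, truth_params$structural)))
  d <- surface_difference(
    multi_storage_surface(Lg, Mg, "F", truth_params),
    single_storage_surface(Lg, Mg, single))
  expect_gt(sum(d$category == "multi_only"), 0)
})

test_that("shape density is constant under isomorphy, decreasing below it", {
  iso <- structural_params(alpha_lU0 = 1, beta_lU1 = 3, alpha_lKnU0 = 1.2,
                           beta_lKnU1 = 3)
  L <- seq(0.5, 2.6, length.out = 40)
  sd_iso <- shape_density(L, iso)
  expect_equal(max(sd_iso) - min(sd_iso), 0, tolerance = 1e-9)
  sd_fit <- shape_density(L, truth_params$structural)
  expect_true(all(is.finite(sd_fit)))
  expect_true(all(diff(sd_fit) < 0))
})

test_that("surfaces export as long-format CSV with unit-tagged columns", {
  Lg <- seq(1.8, 2.0, length.out = 3)
  Mg <- seq(150, 250, length.out = 4)
  s <- multi_storage_surface(Lg, Mg, "F", truth_params,
                             single = single_storage_params())
  expect_equal(length(s$bounds$max_mass), 3)
  expect_true(all(s$bounds$min_mass < s$bounds$max_mass))
  path <- tempfile(fileext = ".csv")
  write_surface_csv(s, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 3 * 4)
  expect_named(df, c("length_m", "mass_kg", "energy_MJ", "feasible"))
})
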