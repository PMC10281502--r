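#' Storage energy under the single-storage comparator
#'
#' Structural mass is `coefficient * L^exponent`; storage is the excess
#' total mass, carrying fixed lipid and protein fractions. Energy is affine
#' in mass above the structural boundary and exactly zero on it.
#'
#' @param length Straight-line body length, m (vectorized).
#' @param mass Total body mass, kg.
#' @param p A [single_storage_params()] object.
#' @return List with `energy` (MJ, NA where infeasible), `O` (storage mass)
#'   and `feasible`.
#' @export
single_storage_energy <- function(length, mass, p) {
  stopifnot(inherits(p, "single_storage_params"))
  if (any(length <= 0) || any(mass <= 0)) {
    stop("length and mass must be positive", call. = FALSE)
  }
  K <- p$structural_coefficient * length^p$structural_exponent
  O <- mass - K
  feasible <- O >= 0
  O[!feasible] <- NA_real_
  dens <- p$storage_lipid_fraction * p$energy$lipid +
    p$storage_protein_fraction * p$energy$protein
  list(energy = O * dens, O = O, feasible = feasible)
}

#' Single-storage structural mass
#'
#' @param length Straight-line body length, m.
#' @param p A [single_storage_params()] object.
#' @return Structural mass, kg.
#' @export
single_storage_structural_mass <- function(length, p) {
  stopifnot(inherits(p, "single_storage_params"))
  p$structural_coefficient * length^p$structural_exponent
}

new_energy_surface <- function(length_grid, mass_grid, energy, feasible,
                               model, min_mass, max_mass) {
  structure(list(length_grid = length_grid, mass_grid = mass_grid,
                 energy = energy, feasible = feasible, model = model,
                 bounds = list(min_mass = min_mass, max_mass = max_mass)),
            class = "energy_surface")
}

#' Storage-energy surface from the multi-storage model
#'
#' Evaluates [full_composition()] on every (length, mass) grid cell for one
#' sex. Cells whose mass falls below the predicted structural mass are
#' masked as infeasible. The attached bounds are the model's own structural
#' mass curve (minimum feasible mass) and, when `single` is supplied, four
#' times the single-storage structural mass (the conventional maximum-mass
#' overlay).
#'
#' @param length_grid Ascending lengths, m.
#' @param mass_grid Ascending masses, kg.
#' @param sex `"F"` or `"M"`.
#' @param params A [composition_params()] object.
#' @param muscle_level Storage-muscle composition level (`"avg"`, `"min"`,
#'   `"max"`).
#' @param single Optional [single_storage_params()] for the maximum-mass
#'   overlay.
#' @return An `energy_surface`: energy matrix (lengths in rows, masses in
#'   columns), feasibility mask, and bound curves.
#' @export
multi_storage_surface <- function(length_grid, mass_grid, sex, params,
                                  muscle_level = c("avg", "min", "max"),
                                  single = NULL) {
  muscle_level <- match.arg(muscle_level)
  check_grids(length_grid, mass_grid)
  cells <- expand.grid(length = length_grid, mass = mass_grid)
  cells$sex <- sex
  est <- full_composition(cells, params, muscle_level)
  energy <- matrix(est$E_O, nrow = length(length_grid))
  feasible <- matrix(est$feasible, nrow = length(length_grid))
  max_mass <- if (is.null(single)) NULL else
    4 * single_storage_structural_mass(length_grid, single)
  new_energy_surface(length_grid, mass_grid, energy, feasible,
                     "multi_storage",
                     structural_mass(length_grid, params$structural),
                     max_mass)
}

#' Storage-energy surface from the single-storage comparator
#'
#' @inheritParams multi_storage_surface
#' @param p A [single_storage_params()] object.
#' @return An `energy_surface`.
#' @export
single_storage_surface <- function(length_grid, mass_grid, p) {
  check_grids(length_grid, mass_grid)
  cells <- expand.grid(length = length_grid, mass = mass_grid)
  res <- single_storage_energy(cells$length, cells$mass, p)
  new_energy_surface(length_grid, mass_grid,
                     matrix(res$energy, nrow = length(length_grid)),
                     matrix(res$feasible, nrow = length(length_grid)),
                     "single_storage",
                     single_storage_structural_mass(length_grid, p),
                     4 * single_storage_structural_mass(length_grid, p))
}

check_grids <- function(length_grid, mass_grid) {
  if (is.unsorted(length_grid, strictly = TRUE) ||
      is.unsorted(mass_grid, strictly = TRUE)) {
    stop("grids must be strictly ascending", call. = FALSE)
  }
  invisible(NULL)
}

#' Cell-wise difference of two energy surfaces
#'
#' Multi-storage minus single-storage energy on a shared grid. Cells
#' feasible under the multi-storage model but not the single-storage model
#' (the region opened up by the lower multi-storage structural mass) are
#' reported as a distinct category rather than a numeric difference.
#'
#' @param multi,single `energy_surface` objects on identical grids.
#' @return An object of class `surface_difference`: `difference` matrix and
#'   `category` matrix (`"both"`, `"multi_only"`, `"single_only"`,
#'   `"neither"`).
#' @export
surface_difference <- function(multi, single) {
  stopifnot(inherits(multi, "energy_surface"),
            inherits(single, "energy_surface"))
  if (!isTRUE(all.equal(multi$length_grid, single$length_grid)) ||
      !isTRUE(all.equal(multi$mass_grid, single$mass_grid))) {
    stop("surfaces are on different grids", call. = FALSE)
  }
  diff <- multi$energy - single$energy
  cat_m <- matrix("neither", nrow = nrow(diff), ncol = ncol(diff))
  cat_m[multi$feasible & single$feasible] <- "both"
  cat_m[multi$feasible & !single$feasible] <- "multi_only"
  cat_m[!multi$feasible & single$feasible] <- "single_only"
  diff[cat_m != "both"] <- NA_real_
  structure(list(length_grid = multi$length_grid,
                 mass_grid = multi$mass_grid,
                 difference = diff, category = cat_m),
            class = "surface_difference")
}

#' Shape-density parameter over length
#'
#' Structural mass divided by length cubed (kg/m^3). Constant under
#' isomorphy (both structural exponents equal to 3); decreasing in length
#' when the exponents fall below 3, as fitted for polar bears.
#'
#' @param length Straight-line body length, m (vectorized).
#' @param p A [structural_params()] object.
#' @return Shape density, kg/m^3.
#' @export
shape_density <- function(length, p) {
  structural_mass(length, p) / length^3
}

#' Long-format data frame from an energy surface
#'
#' @param x An `energy_surface`.
#' @param ... Unused.
#' @return Data frame with columns `length_m`, `mass_kg`, `energy_MJ`,
#'   `feasible`.
#' @export
as.data.frame.energy_surface <- function(x, ...) {
  data.frame(length_m = rep(x$length_grid, times = length(x$mass_grid)),
             mass_kg = rep(x$mass_grid, each = length(x$length_grid)),
             energy_MJ = as.vector(x$energy),
             feasible = as.vector(x$feasible))
}

#' Write an energy surface as long-format CSV
#'
#' Columns `length_m,mass_kg,energy_MJ,feasible`, suitable for external
#' contour plotting.
#'
#' @param surface An `energy_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  write_csv_atomic(as.data.frame(surface), path)
}
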