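#' Metabolizable energy densities of lipid and protein
#'
#' Energy released per kilogram of metabolized tissue component. Defaults are
#' the standard mammalian values: lipid 39.3 MJ/kg, protein 18.4 MJ/kg.
#'
#' @param lipid Energy density of lipid, MJ/kg.
#' @param protein Energy density of protein, MJ/kg.
#' @return An object of class `energy_densities`.
#' @export
energy_densities <- function(lipid = 39.3, protein = 18.4) {
  stopifnot(is.numeric(lipid), is.numeric(protein))
  if (lipid <= 0 || protein <= 0) {
    stop("energy densities must be positive", call. = FALSE)
  }
  structure(list(lipid = lipid, protein = protein),
            class = "energy_densities")
}

#' Lipid and protein composition bounds for storage muscle
#'
#' Observed minimum / average / maximum proportions of lipid and protein in
#' polar bear skeletal muscle (biceps femoris chemistry). Storage-muscle
#' lipid and protein content is not modelled as a function of condition;
#' instead one of these levels is selected when converting storage muscle
#' mass to lipid and protein masses.
#'
#' @param lipid_min,lipid_avg,lipid_max Proportions of muscle that is lipid.
#' @param protein_min,protein_avg,protein_max Proportions of muscle that is
#'   protein.
#' @return An object of class `muscle_composition_bounds`.
#' @export
muscle_composition_bounds <- function(lipid_min = 0.0030,
                                      lipid_avg = 0.0218,
                                      lipid_max = 0.0680,
                                      protein_min = 0.2050,
                                      protein_avg = 0.3738,
                                      protein_max = 0.6200) {
  lip <- c(lipid_min, lipid_avg, lipid_max)
  pro <- c(protein_min, protein_avg, protein_max)
  if (any(lip < 0) || any(pro < 0) || any(lip > 1) || any(pro > 1)) {
    stop("muscle composition proportions must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(lip) || is.unsorted(pro)) {
    stop("muscle composition bounds must satisfy min <= avg <= max",
         call. = FALSE)
  }
  if (lipid_max + protein_max > 1) {
    stop("lipid_max + protein_max must not exceed 1", call. = FALSE)
  }
  structure(list(lipid_min = lipid_min, lipid_avg = lipid_avg,
                 lipid_max = lipid_max, protein_min = protein_min,
                 protein_avg = protein_avg, protein_max = protein_max),
            class = "muscle_composition_bounds")
}

#' Select a muscle-composition level
#'
#' @param bounds A [muscle_composition_bounds()] object.
#' @param level One of `"min"`, `"avg"`, `"max"`.
#' @return List with elements `lipid` (P_UL) and `protein` (P_UP).
#' @export
muscle_level <- function(bounds, level = c("avg", "min", "max")) {
  level <- match.arg(level)
  list(lipid = bounds[[paste0("lipid_", level)]],
       protein = bounds[[paste0("protein_", level)]])
}

#' Structural allometry parameters
#'
#' Coefficients of the two log-log regressions that predict structural
#' tissue from straight-line body length (meters): structural muscle
#' `exp(alpha_lU0 + beta_lU1 * log(L))` and structure non-muscle (hide +
#' viscera + bones) `exp(alpha_lKnU0 + beta_lKnU1 * log(L))`. `beta_lU2` is
#' the adipose slope of the total-muscle regression; it carries no role in
#' point prediction of structure (the adipose term is set to zero there) but
#' is part of the fitted model. Residual SDs are on the log scale. Lengths
#' are in meters throughout; the unit is recorded so serialized bundles can
#' be checked at load.
#'
#' @param alpha_lU0,beta_lU1,beta_lU2,sd_lU Total/structural muscle
#'   regression: intercept (log-kg), length exponent, adipose exponent,
#'   residual sd (log scale).
#' @param alpha_lKnU0,beta_lKnU1,sd_lKnU Structure non-muscle regression:
#'   intercept (log-kg), length exponent, residual sd (log scale).
#' @return An object of class `structural_params`.
#' @export
structural_params <- function(alpha_lU0, beta_lU1, beta_lU2 = NA_real_,
                              sd_lU = NA_real_, alpha_lKnU0, beta_lKnU1,
                              sd_lKnU = NA_real_) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L
  stopifnot(num1(alpha_lU0), num1(beta_lU1), num1(alpha_lKnU0),
            num1(beta_lKnU1))
  if (!is.na(sd_lU) && sd_lU <= 0) stop("sd_lU must be > 0", call. = FALSE)
  if (!is.na(sd_lKnU) && sd_lKnU <= 0) {
    stop("sd_lKnU must be > 0", call. = FALSE)
  }
  structure(list(alpha_lU0 = alpha_lU0, beta_lU1 = beta_lU1,
                 beta_lU2 = beta_lU2, sd_lU = sd_lU,
                 alpha_lKnU0 = alpha_lKnU0, beta_lKnU1 = beta_lKnU1,
                 sd_lKnU = sd_lKnU, length_unit = "m"),
            class = "structural_params")
}

#' Storage-allocation (proportion of storage that is muscle) parameters
#'
#' Beta regression with logit link: the mean proportion of storage mass that
#' is muscle is `plogis(alpha_POu + beta_POu * SMI)` with precision `phi1`.
#' SMI is the scaled mass index in kg, so `beta_POu` is per kg of SMI.
#'
#' @param alpha_POu Logit-scale intercept.
#' @param beta_POu Logit-scale slope per unit SMI (kg).
#' @param phi1 Beta precision (> 0).
#' @return An object of class `storage_allocation_params`.
#' @export
storage_allocation_params <- function(alpha_POu, beta_POu, phi1) {
  if (phi1 <= 0) stop("phi1 must be > 0", call. = FALSE)
  structure(list(alpha_POu = alpha_POu, beta_POu = beta_POu, phi1 = phi1),
            class = "storage_allocation_params")
}

#' Adipose lipid-proportion parameters
#'
#' Beta regression with logit link and sex-specific intercepts: the mean
#' proportion of adipose tissue that is lipid is
#' `plogis(alpha_sex + beta * SMI)`.
#'
#' @param alpha_F,alpha_M Female and male logit-scale intercepts.
#' @param beta Logit-scale slope per unit SMI (kg).
#' @param phi2 Beta precision (> 0).
#' @return An object of class `adipose_lipid_params`.
#' @export
adipose_lipid_params <- function(alpha_F, alpha_M, beta, phi2) {
  if (phi2 <= 0) stop("phi2 must be > 0", call. = FALSE)
  structure(list(alpha_F = alpha_F, alpha_M = alpha_M, beta = beta,
                 phi2 = phi2),
            class = "adipose_lipid_params")
}

#' Adipose protein-proportion parameters
#'
#' Beta regression with logit link: the mean proportion of adipose that is
#' protein is `plogis(alpha + beta * P_AL)` where `P_AL` is the lipid
#' proportion of the same tissue. A negative `beta` gives the observed
#' decay-like decline of protein content with increasing lipid content.
#'
#' @param alpha Logit-scale intercept.
#' @param beta Logit-scale slope per unit lipid proportion.
#' @param phi3 Beta precision (> 0).
#' @return An object of class `adipose_protein_params`.
#' @export
adipose_protein_params <- function(alpha, beta, phi3) {
  if (phi3 <= 0) stop("phi3 must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, phi3 = phi3),
            class = "adipose_protein_params")
}

#' Scaled mass index parameters
#'
#' @param b_sma Allometric scaling exponent (standardized major axis slope of
#'   log mass on log length).
#' @param L0 Reference straight-line body length, meters. SMI equals mass for
#'   a bear of exactly this length.
#' @return An object of class `smi_params`.
#' @export
smi_params <- function(b_sma, L0) {
  if (!is.finite(b_sma)) stop("b_sma must be finite", call. = FALSE)
  if (!is.finite(L0) || L0 <= 0) stop("L0 must be > 0", call. = FALSE)
  structure(list(b_sma = b_sma, L0 = L0), class = "smi_params")
}

#' Full multi-storage model parameter bundle
#'
#' Bundles everything needed to run the composition chain for a bear:
#' structural allometry, storage allocation, adipose lipid and protein
#' regressions, muscle composition bounds, energy densities and the SMI
#' definition.
#'
#' @param structural A [structural_params()] object.
#' @param allocation A [storage_allocation_params()] object.
#' @param adipose_lipid An [adipose_lipid_params()] object.
#' @param adipose_protein An [adipose_protein_params()] object.
#' @param muscle A [muscle_composition_bounds()] object.
#' @param energy An [energy_densities()] object.
#' @param smi An [smi_params()] object.
#' @return An object of class `composition_params`.
#' @export
composition_params <- function(structural, allocation, adipose_lipid,
                               adipose_protein,
                               muscle = muscle_composition_bounds(),
                               energy = energy_densities(),
                               smi) {
  stopifnot(inherits(structural, "structural_params"),
            inherits(allocation, "storage_allocation_params"),
            inherits(adipose_lipid, "adipose_lipid_params"),
            inherits(adipose_protein, "adipose_protein_params"),
            inherits(muscle, "muscle_composition_bounds"),
            inherits(energy, "energy_densities"),
            inherits(smi, "smi_params"))
  structure(list(structural = structural, allocation = allocation,
                 adipose_lipid = adipose_lipid,
                 adipose_protein = adipose_protein, muscle = muscle,
                 energy = energy, smi = smi),
            class = "composition_params")
}

#' @export
print.composition_params <- function(x, ...) {
  cat("Multi-storage body composition parameters\n")
  cat(sprintf("  structural muscle:    ln K_U  = %.4f + %.4f ln L\n",
              x$structural$alpha_lU0, x$structural$beta_lU1))
  cat(sprintf("  structure non-muscle: ln K_nU = %.4f + %.4f ln L\n",
              x$structural$alpha_lKnU0, x$structural$beta_lKnU1))
  cat(sprintf("  storage muscle prop.: logit mu = %.4f + %.5f SMI (phi = %.2f)\n",
              x$allocation$alpha_POu, x$allocation$beta_POu,
              x$allocation$phi1))
  cat(sprintf("  adipose lipid prop.:  logit mu = [F %.4f | M %.4f] + %.5f SMI (phi = %.2f)\n",
              x$adipose_lipid$alpha_F, x$adipose_lipid$alpha_M,
              x$adipose_lipid$beta, x$adipose_lipid$phi2))
  cat(sprintf("  adipose protein prop.: logit mu = %.4f + %.4f P_AL (phi = %.2f)\n",
              x$adipose_protein$alpha, x$adipose_protein$beta,
              x$adipose_protein$phi3))
  cat(sprintf("  SMI: b_sma = %.4f, L0 = %.3f m\n", x$smi$b_sma, x$smi$L0))
  invisible(x)
}

#' Single-storage comparator parameters
#'
#' Parameters of the classical single-storage body composition model:
#' structural mass is `coefficient * L^exponent` and storage mass carries a
#' fixed lipid and protein fraction (strong homeostasis). Values are
#' user-supplied; the defaults here are illustrative, not fitted.
#'
#' @param structural_coefficient kg per meter^exponent.
#' @param structural_exponent Unitless length exponent (default 3,
#'   isomorphy).
#' @param storage_lipid_fraction Fixed lipid fraction of storage mass.
#' @param storage_protein_fraction Fixed protein fraction of storage mass.
#' @param energy An [energy_densities()] object.
#' @return An object of class `single_storage_params`.
#' @export
single_storage_params <- function(structural_coefficient = 20,
                                  structural_exponent = 3,
                                  storage_lipid_fraction = 0.59,
                                  storage_protein_fraction = 0.09,
                                  energy = energy_densities()) {
  if (structural_coefficient <= 0) {
    stop("structural_coefficient must be > 0", call. = FALSE)
  }
  fr <- c(storage_lipid_fraction, storage_protein_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("storage fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  structure(list(structural_coefficient = structural_coefficient,
                 structural_exponent = structural_exponent,
                 storage_lipid_fraction = storage_lipid_fraction,
                 storage_protein_fraction = storage_protein_fraction,
                 energy = energy),
            class = "single_storage_params")
}

#' Write a composition-parameter bundle to JSON
#'
#' Flat keys per component with unit tags, so bundles can be audited and
#' reloaded without the package.
#'
#' @param params A [composition_params()] object.
#' @param path File path for the JSON output.
#' @return `path`, invisibly.
#' @export
write_composition_params <- function(params, path) {
  stopifnot(inherits(params, "composition_params"))
  obj <- list(
    units = list(length = "m", mass = "kg", energy = "MJ", smi = "kg"),
    structural = unclass(params$structural),
    allocation = unclass(params$allocation),
    adipose_lipid = unclass(params$adipose_lipid),
    adipose_protein = unclass(params$adipose_protein),
    muscle = unclass(params$muscle),
    energy = unclass(params$energy),
    smi = unclass(params$smi)
  )
  write_json_atomic(obj, path)
  invisible(path)
}

#' Read a composition-parameter bundle from JSON
#'
#' @param path File written by [write_composition_params()].
#' @return A [composition_params()] object.
#' @export
read_composition_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$units$length) && !identical(obj$units$length, "m")) {
    stop("parameter bundle does not use meters for length; refusing to load",
         call. = FALSE)
  }
  s <- obj$structural
  composition_params(
    structural = structural_params(s$alpha_lU0, s$beta_lU1, s$beta_lU2,
                                   s$sd_lU, s$alpha_lKnU0, s$beta_lKnU1,
                                   s$sd_lKnU),
    allocation = storage_allocation_params(obj$allocation$alpha_POu,
                                           obj$allocation$beta_POu,
                                           obj$allocation$phi1),
    adipose_lipid = adipose_lipid_params(obj$adipose_lipid$alpha_F,
                                         obj$adipose_lipid$alpha_M,
                                         obj$adipose_lipid$beta,
                                         obj$adipose_lipid$phi2),
    adipose_protein = adipose_protein_params(obj$adipose_protein$alpha,
                                             obj$adipose_protein$beta,
                                             obj$adipose_protein$phi3),
    muscle = do.call(muscle_composition_bounds,
                     obj$muscle[c("lipid_min", "lipid_avg", "lipid_max",
                                  "protein_min", "protein_avg",
                                  "protein_max")]),
    energy = energy_densities(obj$energy$lipid, obj$energy$protein),
    smi = smi_params(obj$smi$b_sma, obj$smi$L0)
  )
}
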