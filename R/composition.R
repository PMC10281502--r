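#' Structural muscle mass from length
#'
#' Point prediction of structural muscle (kg) from straight-line body length:
#' `exp(alpha_lU0 + beta_lU1 * log(L))`, i.e. the total-muscle allometry with
#' its adipose term set to zero.
#'
#' @param length Straight-line body length, meters (vectorized).
#' @param p A [structural_params()] object.
#' @return Structural muscle mass, kg.
#' @export
structural_muscle_mass <- function(length, p) {
  stopifnot(inherits(p, "structural_params"))
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("length must be positive and finite", call. = FALSE)
  }
  exp(p$alpha_lU0 + p$beta_lU1 * log(length))
}

#' Structure non-muscle mass from length
#'
#' Point prediction of structure non-muscle (hide + viscera + bones), kg:
#' `exp(alpha_lKnU0 + beta_lKnU1 * log(L))`.
#'
#' @inheritParams structural_muscle_mass
#' @return Structure non-muscle mass, kg.
#' @export
structure_nonmuscle_mass <- function(length, p) {
  stopifnot(inherits(p, "structural_params"))
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("length must be positive and finite", call. = FALSE)
  }
  exp(p$alpha_lKnU0 + p$beta_lKnU1 * log(length))
}

#' Total structural mass from length
#'
#' @inheritParams structural_muscle_mass
#' @return Structural mass K = K_U + K_nU, kg.
#' @export
structural_mass <- function(length, p) {
  structural_muscle_mass(length, p) + structure_nonmuscle_mass(length, p)
}

#' Storage mass from total and structural mass
#'
#' Storage is the excess of total body mass over structural mass. A bear
#' whose recorded mass does not exceed its predicted structural mass is
#' infeasible under the model; this is data (the masked region of energy
#' surfaces), not an error, so the result carries a feasibility flag.
#'
#' @param mass Total body mass, kg (vectorized).
#' @param structural Structural mass, kg.
#' @return List with `O` (storage mass, kg; NA where infeasible) and
#'   `feasible` (logical).
#' @export
storage_mass <- function(mass, structural) {
  if (any(mass <= 0) || any(structural <= 0)) {
    stop("mass and structural mass must be positive", call. = FALSE)
  }
  O <- mass - structural
  feasible <- O >= 0
  O[!feasible] <- NA_real_
  list(O = O, feasible = feasible)
}

#' Proportion of storage that is muscle
#'
#' Inverse-logit of the storage-allocation linear predictor at a given
#' scaled mass index. Strictly within (0, 1); decreasing in SMI when the
#' slope is negative (fatter bears hold proportionally less muscle in
#' storage).
#'
#' @param smi_value Scaled mass index, kg (vectorized).
#' @param p A [storage_allocation_params()] object.
#' @return Proportion of storage mass that is muscle.
#' @export
proportion_storage_muscle <- function(smi_value, p) {
  stopifnot(inherits(p, "storage_allocation_params"))
  if (any(!is.finite(smi_value))) {
    stop("smi_value must be finite", call. = FALSE)
  }
  stats::plogis(p$alpha_POu + p$beta_POu * smi_value)
}

#' Partition storage mass into muscle and adipose
#'
#' @param O Storage mass, kg (vectorized).
#' @param P_OU Proportion of storage that is muscle, in \[0, 1\].
#' @return List with `O_U` (storage muscle, kg) and `A` (storage adipose,
#'   kg); `O_U + A == O` exactly.
#' @export
partition_storage <- function(O, P_OU) {
  if (any(O < 0)) stop("storage mass must be non-negative", call. = FALSE)
  if (any(P_OU < 0) || any(P_OU > 1)) {
    stop("P_OU must lie in [0, 1]", call. = FALSE)
  }
  O_U <- O * P_OU
  list(O_U = O_U, A = O - O_U)
}

#' Lipid proportion of adipose tissue
#'
#' Inverse-logit of the sex-specific adipose-lipid linear predictor at a
#' given scaled mass index.
#'
#' @param smi_value Scaled mass index, kg.
#' @param sex `"F"` or `"M"` (vectorized, recycled against `smi_value`).
#' @param p An [adipose_lipid_params()] object.
#' @return Proportion of adipose that is lipid.
#' @export
adipose_lipid_proportion <- function(smi_value, sex, p) {
  stopifnot(inherits(p, "adipose_lipid_params"))
  if (any(!is.finite(smi_value))) {
    stop("smi_value must be finite", call. = FALSE)
  }
  if (!all(sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  alpha <- ifelse(sex == "F", p$alpha_F, p$alpha_M)
  stats::plogis(alpha + p$beta * smi_value)
}

#' Protein proportion of adipose tissue
#'
#' Inverse-logit of the adipose-protein linear predictor given the lipid
#' proportion of the same tissue.
#'
#' @param P_AL Lipid proportion of adipose, in \[0, 1\].
#' @param p An [adipose_protein_params()] object.
#' @return Proportion of adipose that is protein.
#' @export
adipose_protein_proportion <- function(P_AL, p) {
  stopifnot(inherits(p, "adipose_protein_params"))
  if (any(P_AL < 0) || any(P_AL > 1)) {
    stop("P_AL must lie in [0, 1]", call. = FALSE)
  }
  stats::plogis(p$alpha + p$beta * P_AL)
}

#' Total storage lipid mass
#'
#' Lipid held in storage adipose plus lipid held in storage muscle:
#' `P_AL * A + P_UL * O_U`.
#'
#' @param P_AL Lipid proportion of adipose.
#' @param A Storage adipose mass, kg.
#' @param P_UL Lipid proportion of storage muscle.
#' @param O_U Storage muscle mass, kg.
#' @return Storage lipid mass O_L, kg.
#' @export
storage_lipid_mass <- function(P_AL, A, P_UL, O_U) {
  check_prop_mass(P_AL, A, P_UL, O_U)
  P_AL * A + P_UL * O_U
}

#' Total storage protein mass
#'
#' `P_AP * A + P_UP * O_U`.
#'
#' @param P_AP Protein proportion of adipose.
#' @param A Storage adipose mass, kg.
#' @param P_UP Protein proportion of storage muscle.
#' @param O_U Storage muscle mass, kg.
#' @return Storage protein mass O_P, kg.
#' @export
storage_protein_mass <- function(P_AP, A, P_UP, O_U) {
  check_prop_mass(P_AP, A, P_UP, O_U)
  P_AP * A + P_UP * O_U
}

check_prop_mass <- function(p1, m1, p2, m2) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(m1, m2) < 0)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  invisible(NULL)
}

#' Total storage energy
#'
#' Converts storage lipid and protein masses to metabolizable energy:
#' `e_L * O_L + e_P * O_P` (MJ).
#'
#' @param O_L Storage lipid mass, kg.
#' @param O_P Storage protein mass, kg.
#' @param e An [energy_densities()] object.
#' @return Storage energy E_O, MJ.
#' @export
total_storage_energy <- function(O_L, O_P, e = energy_densities()) {
  stopifnot(inherits(e, "energy_densities"))
  if (any(c(O_L, O_P) < 0)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  e$lipid * O_L + e$protein * O_P
}

#' Energy density of storage muscle
#'
#' Per-kg metabolizable energy of storage muscle at a given lipid/protein
#' composition: `e_L * P_UL + e_P * P_UP` (MJ/kg). Used to quantify how
#' sensitive storage-muscle energy is to the observed composition range.
#'
#' @param P_UL Lipid proportion of muscle.
#' @param P_UP Protein proportion of muscle.
#' @param e An [energy_densities()] object.
#' @return Energy density, MJ/kg.
#' @export
muscle_energy_density <- function(P_UL, P_UP, e = energy_densities()) {
  stopifnot(inherits(e, "energy_densities"))
  if (any(c(P_UL, P_UP) < 0) || any(c(P_UL, P_UP) > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  e$lipid * P_UL + e$protein * P_UP
}

#' Classify a bear's age class
#'
#' Cub-of-the-year below 1 year, yearling from 1 to under 2, then adult at
#' 4 years (females) or 6 years (males); otherwise subadult.
#'
#' @param sex `"F"` or `"M"` (vectorized).
#' @param age_years Age in years, non-negative.
#' @return Character vector: `"coy"`, `"yearling"`, `"subadult"`, `"adult"`.
#' @export
classify_age_class <- function(sex, age_years) {
  if (!all(sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  if (any(age_years < 0)) stop("age_years must be >= 0", call. = FALSE)
  adult_age <- ifelse(sex == "F", 4, 6)
  out <- rep("subadult", length(age_years))
  out[age_years < 2] <- "yearling"
  out[age_years < 1] <- "coy"
  out[age_years >= 2 & age_years >= adult_age] <- "adult"
  out
}

#' Full body-composition chain for one or more bears
#'
#' Runs the complete multi-storage chain from morphometrics: SMI, structural
#' muscle and non-muscle, structural mass, storage mass, storage allocation,
#' adipose lipid/protein proportions, storage lipid/protein masses and total
#' storage energy. Bears whose mass falls below predicted structural mass
#' are flagged infeasible with NA storage fields.
#'
#' @param bears Data frame with columns `length` (m), `mass` (kg), `sex`
#'   (`"F"`/`"M"`); an `id` column is carried through if present.
#' @param params A [composition_params()] object.
#' @param muscle_level Which storage-muscle composition level to use for
#'   lipid/protein content: `"avg"` (default), `"min"` or `"max"`.
#' @return Data frame, one row per bear, with columns `smi`, `K_U`, `K_nU`,
#'   `K`, `O`, `P_OU`, `O_U`, `A`, `P_AL`, `P_AP`, `O_L`, `O_P`, `E_O`,
#'   `feasible`.
#' @export
full_composition <- function(bears, params,
                             muscle_level = c("avg", "min", "max")) {
  stopifnot(inherits(params, "composition_params"))
  muscle_level <- match.arg(muscle_level)
  req <- c("length", "mass", "sex")
  miss <- setdiff(req, names(bears))
  if (length(miss)) {
    stop("bears is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(bears$length <= 0) || any(bears$mass <= 0)) {
    stop("length and mass must be positive", call. = FALSE)
  }
  if (!all(bears$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }

  ml <- muscle_level(params$muscle, muscle_level)
  smi <- scaled_mass_index(bears$mass, bears$length, params$smi)
  K_U <- structural_muscle_mass(bears$length, params$structural)
  K_nU <- structure_nonmuscle_mass(bears$length, params$structural)
  K <- K_U + K_nU
  st <- storage_mass(bears$mass, K)
  P_OU <- proportion_storage_muscle(smi, params$allocation)
  O_U <- st$O * P_OU
  A <- st$O - O_U
  P_AL <- adipose_lipid_proportion(smi, bears$sex, params$adipose_lipid)
  P_AP <- adipose_protein_proportion(P_AL, params$adipose_protein)
  O_L <- P_AL * A + ml$lipid * O_U
  O_P <- P_AP * A + ml$protein * O_U
  E_O <- total_storage_energy_raw(O_L, O_P, params$energy)

  out <- data.frame(
    smi = smi, K_U = K_U, K_nU = K_nU, K = K, O = st$O,
    P_OU = ifelse(st$feasible, P_OU, NA_real_),
    O_U = O_U, A = A,
    P_AL = ifelse(st$feasible, P_AL, NA_real_),
    P_AP = ifelse(st$feasible, P_AP, NA_real_),
    O_L = O_L, O_P = O_P, E_O = E_O,
    feasible = st$feasible
  )
  if (!is.null(bears$id)) out <- cbind(id = bears$id, out)
  out
}

# energy without the non-negativity check (NA-safe for infeasible bears)
total_storage_energy_raw <- function(O_L, O_P, e) {
  e$lipid * O_L + e$protein * O_P
}
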