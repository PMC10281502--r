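#' Mean straight-line length of a recapture pair
#'
#' Adult bears have stopped structural growth, so a length difference
#' between two captures is measurement error; the mean length is used for
#' both timepoints. With a common length, structural mass cancels exactly in
#' the between-capture difference.
#'
#' @param records Recapture data frame with columns `len1`, `len2`.
#' @return Mean lengths, m (vectorized).
#' @export
mean_length <- function(records) {
  if (is.null(records$len1) || is.null(records$len2) ||
      anyNA(records$len1) || anyNA(records$len2)) {
    stop("both capture lengths are required", call. = FALSE)
  }
  (records$len1 + records$len2) / 2
}

#' Predicted change in storage lipid mass between captures
#'
#' Runs the full composition chain at each capture's mass (with the shared
#' mean length) and differences the storage lipid masses. The `"min"` and
#' `"max"` muscle-composition levels give the uncertainty bounds used when
#' comparing against isotopic dilution.
#'
#' @param records Recapture records (package layout; see
#'   [read_recapture()]).
#' @param params A [composition_params()] object.
#' @param muscle_level Storage-muscle composition level.
#' @return Data frame with `id`, `predicted_dlipid` (kg), `feasible`, and
#'   `exclusion_reason` (NA when feasible at both timepoints).
#' @export
predict_lipid_change <- function(records, params,
                                 muscle_level = c("avg", "min", "max")) {
  muscle_level <- match.arg(muscle_level)
  L <- mean_length(records)
  b1 <- data.frame(length = L, mass = records$mass1, sex = records$sex)
  b2 <- data.frame(length = L, mass = records$mass2, sex = records$sex)
  e1 <- full_composition(b1, params, muscle_level)
  e2 <- full_composition(b2, params, muscle_level)
  feasible <- e1$feasible & e2$feasible
  reason <- rep(NA_character_, nrow(records))
  reason[!e1$feasible] <- "infeasible at first capture"
  reason[!e2$feasible] <- "infeasible at second capture"
  reason[!e1$feasible & !e2$feasible] <- "infeasible at both captures"
  data.frame(id = records$id,
             predicted_dlipid = ifelse(feasible, e2$O_L - e1$O_L,
                                       NA_real_),
             feasible = feasible, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' Root mean squared error
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0L) {
    stop("at least one prediction is required", call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

#' Paired t-test on capture lengths
#'
#' Two-tailed paired t-test of first- versus second-capture straight-line
#' lengths; a non-significant result justifies the mean-length substitution.
#'
#' @param records Recapture records with `len1`, `len2`.
#' @return List with `t`, `df`, `p`.
#' @export
paired_length_ttest <- function(records) {
  if (nrow(records) < 2L) {
    stop("at least 2 records are required", call. = FALSE)
  }
  d <- records$len1 - records$len2
  if (stats::sd(d) == 0) {
    stop("zero variance of length differences; t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(records$len1, records$len2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Model-validation report against isotopic recaptures
#'
#' Predicts the between-capture change in storage lipid mass with the
#' multi-storage model and the single-storage comparator, compares both to
#' the isotopic dilution measurements, and tabulates RMSE overall, per
#' subgroup, and for caller-specified exclusion subsets (e.g. dropping the
#' best-condition males). Only adult records are accepted: for adults the
#' change in total lipid equals the change in storage lipid. Records with an
#' infeasible timepoint are excluded and listed, not imputed.
#'
#' @param records Recapture records (package layout).
#' @param multi A [composition_params()] object.
#' @param single A [single_storage_params()] object.
#' @param subgroups Named list of logical-index functions or character
#'   labels; default groups by `subpop` x `sex`.
#' @param exclude_ids Character vector of ids for the exclusion-sensitivity
#'   rows.
#' @param muscle_level Storage-muscle composition level for the central
#'   multi-storage prediction.
#' @return An object of class `validation_report` with the RMSE table, the
#'   per-bear prediction table (including min/max muscle-level bounds and
#'   the isotopic error band), and exclusions.
#' @export
compare_models <- function(records, multi, single, subgroups = NULL,
                           exclude_ids = character(),
                           muscle_level = "avg") {
  if (!all(records$class == "adult")) {
    stop("validation accepts adult records only (storage lipid change ",
         "equals total lipid change only for grown bears); non-adult ",
         "record(s): ",
         paste(records$id[records$class != "adult"], collapse = ", "),
         call. = FALSE)
  }
  pred <- predict_lipid_change(records, multi, muscle_level)
  pred_min <- predict_lipid_change(records, multi, "min")
  pred_max <- predict_lipid_change(records, multi, "max")

  L <- mean_length(records)
  s1 <- single_storage_energy(L, records$mass1, single)
  s2 <- single_storage_energy(L, records$mass2, single)
  single_dlipid <- (s2$O - s1$O) * single$storage_lipid_fraction
  single_feasible <- s1$feasible & s2$feasible

  iso_dlipid <- records$lipid2 - records$lipid1
  iso_err <- if (is.null(records$isotopic_error_fraction)) 0.027 else
    records$isotopic_error_fraction

  per_bear <- data.frame(
    id = records$id, subpop = records$subpop, sex = records$sex,
    interval_days = records$interval_days,
    iso_dlipid = iso_dlipid,
    iso_lower = iso_dlipid - iso_err * (records$lipid1 + records$lipid2) / 2,
    iso_upper = iso_dlipid + iso_err * (records$lipid1 + records$lipid2) / 2,
    multi_dlipid = pred$predicted_dlipid,
    multi_lower = pmin(pred_min$predicted_dlipid,
                       pred_max$predicted_dlipid),
    multi_upper = pmax(pred_min$predicted_dlipid,
                       pred_max$predicted_dlipid),
    single_dlipid = ifelse(single_feasible, single_dlipid, NA_real_),
    feasible = pred$feasible & single_feasible,
    stringsAsFactors = FALSE
  )

  excluded <- records$id[!per_bear$feasible]
  keep <- per_bear$feasible

  if (is.null(subgroups)) {
    subgroups <- list()
    for (sp in unique(records$subpop)) {
      for (sx in unique(records$sex[records$subpop == sp])) {
        subgroups[[paste(sp, sx, sep = "_")]] <-
          records$subpop == sp & records$sex == sx
      }
    }
  }

  rmse_rows <- function(sel, label) {
    sel <- sel & keep
    if (!any(sel)) return(NULL)
    data.frame(
      group = label, n = sum(sel),
      rmse_multi_iso = rmse(per_bear$multi_dlipid[sel],
                            per_bear$iso_dlipid[sel]),
      rmse_single_iso = rmse(per_bear$single_dlipid[sel],
                             per_bear$iso_dlipid[sel]),
      rmse_multi_single = rmse(per_bear$multi_dlipid[sel],
                               per_bear$single_dlipid[sel])
    )
  }

  tab <- rmse_rows(rep(TRUE, nrow(per_bear)), "all")
  for (nm in names(subgroups)) {
    tab <- rbind(tab, rmse_rows(subgroups[[nm]], nm))
  }
  if (length(exclude_ids)) {
    not_excl <- !(records$id %in% exclude_ids)
    tab <- rbind(tab, rmse_rows(not_excl, "all_minus_excluded"))
    for (nm in names(subgroups)) {
      tab <- rbind(tab,
                   rmse_rows(subgroups[[nm]] & not_excl,
                             paste0(nm, "_minus_excluded")))
    }
  }
  structure(list(rmse_table = tab, per_bear = per_bear,
                 excluded_ids = excluded, exclude_ids = exclude_ids,
                 muscle_level = muscle_level),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Recapture validation (change in storage lipid mass, kg)\n")
  print(x$rmse_table, row.names = FALSE, digits = 4)
  if (length(x$excluded_ids)) {
    cat("excluded (infeasible timepoint):",
        paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a validation report (CSV + JSON)
#'
#' @param report A `validation_report`.
#' @param csv_path Path for the RMSE table CSV.
#' @param json_path Optional path for the full JSON report.
#' @return `csv_path`, invisibly.
#' @export
write_validation_report <- function(report, csv_path, json_path = NULL) {
  write_csv_atomic(report$rmse_table, csv_path)
  if (!is.null(json_path)) {
    write_json_atomic(list(rmse_table = report$rmse_table,
                           per_bear = report$per_bear,
                           excluded_ids = report$excluded_ids,
                           muscle_level = report$muscle_level), json_path)
  }
  invisible(csv_path)
}
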