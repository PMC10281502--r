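# Atomic writers: write to a temp file in the destination directory, then
# rename, so readers never observe a half-written artifact.
write_json_atomic <- function(obj, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  file.rename(tmp, path)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

read_checked_csv <- function(path, required, kind,
                             numeric_cols = character()) {
  if (!file.exists(path)) {
    stop(kind, " file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(kind, " file ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cl in numeric_cols) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))) &
                     !is.na(df[[cl]]))
      stop(kind, " file ", path, ": non-numeric value in column '", cl,
           "'", if (length(bad)) paste0(" (row ", bad[1], ")"),
           call. = FALSE)
    }
    if (anyNA(df[[cl]])) {
      stop(kind, " file ", path, ": missing value in column '", cl,
           "' (row ", which(is.na(df[[cl]]))[1], ")", call. = FALSE)
    }
  }
  df
}

#' Read a morphometrics CSV
#'
#' Expected header: `id,sex,age_years,length_m,mass_kg` (`age_years` may be
#' empty). Units are encoded in the column names and converted to the
#' package's internal `length`/`mass` columns.
#'
#' @param path CSV file path.
#' @return Data frame with columns `id`, `sex`, `age_years`, `length`,
#'   `mass`.
#' @export
read_morphometrics <- function(path) {
  df <- read_checked_csv(path, c("id", "sex", "length_m", "mass_kg"),
                         "morphometrics", c("length_m", "mass_kg"))
  if (!all(df$sex %in% c("F", "M"))) {
    stop("morphometrics file ", path, ": sex must be 'F' or 'M' (row ",
         which(!df$sex %in% c("F", "M"))[1], ")", call. = FALSE)
  }
  if (any(df$length_m <= 0) || any(df$mass_kg <= 0)) {
    stop("morphometrics file ", path,
         ": lengths and masses must be positive", call. = FALSE)
  }
  out <- data.frame(id = as.character(df$id), sex = df$sex,
                    age_years = if ("age_years" %in% names(df)) {
                      suppressWarnings(as.numeric(df$age_years))
                    } else NA_real_,
                    length = df$length_m, mass = df$mass_kg,
                    stringsAsFactors = FALSE)
  out
}

#' Write a morphometrics CSV
#'
#' @param df Data frame with columns `id`, `sex`, `age_years`, `length`,
#'   `mass`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_morphometrics <- function(df, path) {
  out <- data.frame(id = df$id, sex = df$sex,
                    age_years = if (is.null(df$age_years)) NA else
                      df$age_years,
                    length_m = df$length, mass_kg = df$mass)
  write_csv_atomic(out, path)
}

#' Read a dissection-records CSV
#'
#' Expected header: `id,sex,age_years,length_m,mass_kg,muscle_kg,adipose_kg,
#' hide_kg,viscera_kg,bones_kg`.
#'
#' @param path CSV file path.
#' @return Data frame in the package's dissection-record layout.
#' @export
read_dissection <- function(path) {
  cols <- c("id", "sex", "length_m", "mass_kg", "muscle_kg", "adipose_kg",
            "hide_kg", "viscera_kg", "bones_kg")
  df <- read_checked_csv(path, cols, "dissection", setdiff(cols,
                                                           c("id", "sex")))
  out <- data.frame(id = as.character(df$id), sex = df$sex,
                    age_years = if ("age_years" %in% names(df)) {
                      suppressWarnings(as.numeric(df$age_years))
                    } else NA_real_,
                    length = df$length_m, mass = df$mass_kg,
                    U = df$muscle_kg, A = df$adipose_kg, hide = df$hide_kg,
                    viscera = df$viscera_kg, bones = df$bones_kg,
                    stringsAsFactors = FALSE)
  validate_dissection(out)
  out
}

#' Write a dissection-records CSV
#'
#' @param records Dissection records in the package layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dissection <- function(records, path) {
  out <- data.frame(id = records$id, sex = records$sex,
                    age_years = if (is.null(records$age_years)) NA else
                      records$age_years,
                    length_m = records$length, mass_kg = records$mass,
                    muscle_kg = records$U, adipose_kg = records$A,
                    hide_kg = records$hide, viscera_kg = records$viscera,
                    bones_kg = records$bones)
  write_csv_atomic(out, path)
}

#' Read an adipose-biopsy CSV
#'
#' Expected header: `id,sex,length_m,mass_kg,lipid_proportion`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `id`, `sex`, `length`, `mass`, `P_AL`.
#' @export
read_biopsy <- function(path) {
  cols <- c("id", "sex", "length_m", "mass_kg", "lipid_proportion")
  df <- read_checked_csv(path, cols, "biopsy",
                         c("length_m", "mass_kg", "lipid_proportion"))
  if (any(df$lipid_proportion <= 0) || any(df$lipid_proportion >= 1)) {
    stop("biopsy file ", path,
         ": lipid_proportion must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  data.frame(id = as.character(df$id), sex = df$sex, length = df$length_m,
             mass = df$mass_kg, P_AL = df$lipid_proportion,
             stringsAsFactors = FALSE)
}

#' Write an adipose-biopsy CSV
#'
#' @param records Biopsy records in the package layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biopsy <- function(records, path) {
  out <- data.frame(id = records$id, sex = records$sex,
                    length_m = records$length, mass_kg = records$mass,
                    lipid_proportion = records$P_AL)
  write_csv_atomic(out, path)
}

#' Read an adipose-chemistry CSV
#'
#' Expected header: `id,lipid_proportion,protein_proportion`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `id`, `P_AL`, `P_AP`.
#' @export
read_adipose_chem <- function(path) {
  cols <- c("id", "lipid_proportion", "protein_proportion")
  df <- read_checked_csv(path, cols, "adipose chemistry",
                         c("lipid_proportion", "protein_proportion"))
  pl <- df$lipid_proportion; pp <- df$protein_proportion
  if (any(pl <= 0) || any(pl >= 1) || any(pp <= 0) || any(pp >= 1)) {
    stop("adipose chemistry file ", path,
         ": proportions must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(pl + pp > 1)) {
    stop("adipose chemistry file ", path,
         ": lipid + protein proportions exceed 1 (row ",
         which(pl + pp > 1)[1], ")", call. = FALSE)
  }
  data.frame(id = as.character(df$id), P_AL = pl, P_AP = pp,
             stringsAsFactors = FALSE)
}

#' Write an adipose-chemistry CSV
#'
#' @param records Adipose chemistry records in the package layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adipose_chem <- function(records, path) {
  out <- data.frame(id = records$id, lipid_proportion = records$P_AL,
                    protein_proportion = records$P_AP)
  write_csv_atomic(out, path)
}

#' Read a recapture CSV
#'
#' Expected header: `id,subpop,sex,class,interval_days,len1_m,mass1_kg,
#' lipid1_kg,len2_m,mass2_kg,lipid2_kg`.
#'
#' @param path CSV file path.
#' @return Data frame in the package's recapture layout.
#' @export
read_recapture <- function(path) {
  cols <- c("id", "subpop", "sex", "class", "interval_days", "len1_m",
            "mass1_kg", "lipid1_kg", "len2_m", "mass2_kg", "lipid2_kg")
  num <- setdiff(cols, c("id", "subpop", "sex", "class"))
  df <- read_checked_csv(path, cols, "recapture", num)
  if (any(df$interval_days <= 0)) {
    stop("recapture file ", path, ": interval_days must be positive",
         call. = FALSE)
  }
  if (any(df[c("mass1_kg", "mass2_kg", "lipid1_kg", "lipid2_kg")] <= 0)) {
    stop("recapture file ", path, ": masses and lipid masses must be ",
         "positive", call. = FALSE)
  }
  if (any(df$lipid1_kg >= df$mass1_kg) || any(df$lipid2_kg >= df$mass2_kg)) {
    stop("recapture file ", path, ": lipid mass must be below total mass",
         call. = FALSE)
  }
  data.frame(id = as.character(df$id), subpop = df$subpop, sex = df$sex,
             class = df$class, interval_days = df$interval_days,
             len1 = df$len1_m, mass1 = df$mass1_kg, lipid1 = df$lipid1_kg,
             len2 = df$len2_m, mass2 = df$mass2_kg, lipid2 = df$lipid2_kg,
             stringsAsFactors = FALSE)
}

#' Write a recapture CSV
#'
#' @param records Recapture records in the package layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recapture <- function(records, path) {
  out <- data.frame(id = records$id, subpop = records$subpop,
                    sex = records$sex, class = records$class,
                    interval_days = records$interval_days,
                    len1_m = records$len1, mass1_kg = records$mass1,
                    lipid1_kg = records$lipid1, len2_m = records$len2,
                    mass2_kg = records$mass2, lipid2_kg = records$lipid2)
  write_csv_atomic(out, path)
}
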