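# Reading and validating the three cohort input tables: EAV code records,
# demographics, and eligibility labels. The canonical in-memory cohort is a
# list of three tibbles with presence-only code semantics.

CODE_SYSTEMS <- c("diagnosis", "procedure")

#' Normalize a diagnosis or procedure code string
#'
#' Trims whitespace and upper-cases letters; hyphens and dots are preserved.
#' ICD-10-GM and OPS codes are case-insensitive in practice, and a
#' deterministic canonical form is needed for attribute-column identity.
#'
#' @param code Character vector of raw code strings.
#' @return Character vector of normalized codes.
#' @export
normalize_code <- function(code) {
  toupper(trimws(code))
}

#' Read EAV-format code records
#'
#' Reads a delimited text file (comma or tab, auto-detected) with one row per
#' documented code event: columns `patient_id`, `code`, `system`. Codes are
#' normalized and duplicate (patient, code, system) rows are collapsed to a
#' single record: downstream the data model is presence-only ("was this code
#' ever documented for this patient"), so dates and multiplicities are
#' dropped at ingestion.
#'
#' @param path Path to the delimited file; header row required.
#' @param delim Optional delimiter; auto-detected from the header when `NULL`.
#' @return A tibble with columns `patient_id`, `code`, `system`, one row per
#'   distinct documented (patient, code, system) triple.
#' @export
read_eav <- function(path, delim = NULL) {
  df <- read_delim_table(path, delim)
  require_columns(df, c("patient_id", "code", "system"), path)
  df <- df |>
    transmute(patient_id = trimws(.data$patient_id),
              code = normalize_code(.data$code),
              system = tolower(trimws(.data$system)))
  bad_sys <- which(!df$system %in% CODE_SYSTEMS)
  if (length(bad_sys) > 0) {
    abort(paste0("validation error in ", path, ", row ", bad_sys[1] + 1L,
                 ": unknown code system '", df$system[bad_sys[1]],
                 "' (expected one of: ", paste(CODE_SYSTEMS, collapse = ", "), ")"))
  }
  bad_empty <- which(df$patient_id == "" | df$code == "")
  if (length(bad_empty) > 0) {
    abort(paste0("validation error in ", path, ", row ", bad_empty[1] + 1L,
                 ": empty patient_id or code"))
  }
  distinct(df)
}

#' Default gender synonym table
#'
#' Maps common encodings (including German W/M for weiblich/maennlich) onto
#' the canonical values `female` and `male`. Matching is case-insensitive.
#'
#' @return Named character vector: names are accepted synonyms, values are
#'   canonical genders.
#' @export
default_gender_map <- function() {
  c("F" = "female", "W" = "female", "FEMALE" = "female", "WEIBLICH" = "female",
    "M" = "male", "MALE" = "male", "MAENNLICH" = "male")
}

#' Read patient demographics
#'
#' One row per patient with columns `patient_id`, `age` (non-negative integer
#' years) and `gender` (mapped through a configurable synonym table).
#'
#' @param path Path to the delimited file.
#' @param gender_map Named character vector mapping raw gender strings
#'   (case-insensitive) to `"female"`/`"male"`.
#' @param delim Optional delimiter.
#' @return Tibble with columns `patient_id`, `age` (integer), `gender`.
#' @export
read_demographics <- function(path, gender_map = default_gender_map(), delim = NULL) {
  df <- read_delim_table(path, delim)
  require_columns(df, c("patient_id", "age", "gender"), path)
  df <- df |> mutate(patient_id = trimws(.data$patient_id))
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate patient_id in ", path, ": ", dup[1]))
  }
  age <- suppressWarnings(as.numeric(df$age))
  bad_age <- which(is.na(age) | age < 0 | age != floor(age))
  if (length(bad_age) > 0) {
    abort(paste0("validation error in ", path, ", row ", bad_age[1] + 1L,
                 ": age must be a non-negative integer, got '", df$age[bad_age[1]], "'"))
  }
  g_raw <- toupper(trimws(df$gender))
  gmap <- stats::setNames(gender_map, toupper(names(gender_map)))
  gender <- unname(gmap[g_raw])
  bad_g <- which(is.na(gender))
  if (length(bad_g) > 0) {
    abort(paste0("validation error in ", path, ", row ", bad_g[1] + 1L,
                 ": unmappable gender value '", df$gender[bad_g[1]], "'"))
  }
  tibble(patient_id = df$patient_id, age = as.integer(age), gender = gender)
}

#' Read eligibility labels for screened patients
#'
#' @param path Path to the delimited file with columns `patient_id`,
#'   `eligible`.
#' @param truthy,falsy Character vectors of accepted values (case-insensitive)
#'   mapping to `TRUE`/`FALSE`.
#' @param delim Optional delimiter.
#' @return Tibble with columns `patient_id`, `eligible` (logical).
#' @export
read_labels <- function(path, truthy = c("Y", "YES", "1", "TRUE"),
                        falsy = c("N", "NO", "0", "FALSE"), delim = NULL) {
  df <- read_delim_table(path, delim)
  require_columns(df, c("patient_id", "eligible"), path)
  df <- df |> mutate(patient_id = trimws(.data$patient_id))
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate patient_id in ", path, ": ", dup[1]))
  }
  v <- toupper(trimws(df$eligible))
  eligible <- ifelse(v %in% toupper(truthy), TRUE,
                     ifelse(v %in% toupper(falsy), FALSE, NA))
  bad <- which(is.na(eligible))
  if (length(bad) > 0) {
    abort(paste0("validation error in ", path, ", row ", bad[1] + 1L,
                 ": unmappable eligibility value '", df$eligible[bad[1]], "'"))
  }
  tibble(patient_id = df$patient_id, eligible = as.logical(eligible))
}

#' Assemble and validate a cohort
#'
#' A cohort bundles the three tables. Every labeled patient and every patient
#' with code records must appear in demographics (age and gender are
#' mandatory model inputs); patients present in demographics but absent from
#' the EAV records are kept with zero codes — such patients occur in real
#' hospital data.
#'
#' @param records Tibble of EAV records (see [read_eav()]).
#' @param demographics Tibble of demographics (see [read_demographics()]).
#' @param labels Tibble of eligibility labels (see [read_labels()]).
#' @return An object of class `ctrss_cohort`.
#' @export
cohort <- function(records, demographics, labels) {
  records <- as_tibble(records)
  demographics <- as_tibble(demographics)
  labels <- as_tibble(labels)
  missing_lab <- setdiff(labels$patient_id, demographics$patient_id)
  if (length(missing_lab) > 0) {
    abort(paste0("labeled patient(s) missing from demographics: ",
                 paste(utils::head(missing_lab, 5), collapse = ", ")))
  }
  missing_rec <- setdiff(unique(records$patient_id), demographics$patient_id)
  if (length(missing_rec) > 0) {
    abort(paste0("patient(s) with code records but no demographics: ",
                 paste(utils::head(missing_rec, 5), collapse = ", ")))
  }
  structure(list(records = distinct(records),
                 demographics = demographics,
                 labels = labels),
            class = "ctrss_cohort")
}

#' Read a cohort from its three delimited files
#'
#' @param eav_path,demographics_path,labels_path File paths.
#' @param ... Passed on to the individual readers.
#' @return A `ctrss_cohort`.
#' @export
read_cohort <- function(eav_path, demographics_path, labels_path, ...) {
  cohort(read_eav(eav_path),
         read_demographics(demographics_path),
         read_labels(labels_path))
}

#' Write a cohort to three delimited files
#'
#' Inverse of [read_cohort()]: writing and re-reading yields an identical
#' cohort (set equality on all three tables).
#'
#' @param x A `ctrss_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "ctrss_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(eav = file.path(dir, "eav.csv"),
             demographics = file.path(dir, "demographics.csv"),
             labels = file.path(dir, "labels.csv"))
  readr::write_csv(x$records, paths[["eav"]])
  readr::write_csv(x$demographics, paths[["demographics"]])
  labs <- x$labels |> mutate(eligible = ifelse(.data$eligible, "Y", "N"))
  readr::write_csv(labs, paths[["labels"]])
  invisible(paths)
}

#' @export
print.ctrss_cohort <- function(x, ...) {
  cat("<ctrss_cohort>\n")
  cat("  patients (demographics):", nrow(x$demographics), "\n")
  cat("  code records:", nrow(x$records),
      sprintf("(%d diagnosis, %d procedure)\n",
              sum(x$records$system == "diagnosis"),
              sum(x$records$system == "procedure")))
  cat("  labeled patients:", nrow(x$labels),
      sprintf("(%d eligible)\n", sum(x$labels$eligible)))
  invisible(x)
}
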