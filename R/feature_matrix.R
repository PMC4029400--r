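# Pivot EAV records into the binary patient x attribute table used by all
# model families. A code column is 1 iff the patient has at least one record
# mapping to it at the chosen aggregation level (per-class OR); age and
# gender are always appended. Column order is deterministic: diagnosis codes,
# procedure codes (each sorted), then age, gender.

FM_META_COLS <- c("patient_id", "age", "gender", "eligible")

namespace_attr <- function(code, system) {
  paste0(ifelse(system == "diagnosis", "dx:", "proc:"), code)
}

#' Names of the code attribute columns of a feature matrix
#' @param fm A `ctrss_matrix` (or any data frame using its layout).
#' @return Character vector of `dx:`/`proc:` column names.
#' @export
code_attributes <- function(fm) {
  setdiff(names(fm), FM_META_COLS)
}

#' Names of the model input columns (codes plus age and gender)
#' @param fm A `ctrss_matrix`.
#' @return Character vector of predictor column names.
#' @export
model_attributes <- function(fm) {
  c(code_attributes(fm), "age", "gender")
}

new_feature_matrix <- function(df, level) {
  structure(df, class = c("ctrss_matrix", class(df)), level = level)
}

build_code_columns <- function(records, patient_ids, level, map, strict) {
  if (nrow(records) > 0) {
    recs <- records |>
      group_by(.data$system) |>
      mutate(agg = aggregate_code(.data$code, .data$system[1], level,
                                  map = map, strict = strict)) |>
      ungroup() |>
      transmute(patient_id = .data$patient_id,
                attribute = namespace_attr(.data$agg, .data$system)) |>
      distinct()
    attrs <- sort(unique(recs$attribute))
  } else {
    recs <- tibble(patient_id = character(), attribute = character())
    attrs <- character()
  }
  wide <- matrix(0L, nrow = length(patient_ids), ncol = length(attrs),
                 dimnames = list(NULL, attrs))
  if (nrow(recs) > 0) {
    i <- match(recs$patient_id, patient_ids)
    j <- match(recs$attribute, attrs)
    keep <- !is.na(i)
    wide[cbind(i[keep], j[keep])] <- 1L
  }
  as_tibble(wide, .name_repair = "minimal")
}

#' Pivot a cohort into a feature matrix
#'
#' Builds one row per labeled (screened) patient: binary code attributes at
#' the requested aggregation level, then `age` and `gender` (encoded 0 =
#' female, 1 = male). A patient is deemed affected by an aggregated class if
#' any subordinate code was ever documented. Patients with zero code records
#' get all-zero code columns. The result is independent of the order of the
#' EAV records.
#'
#' @param x A `ctrss_cohort`.
#' @param level Aggregation level: `"none"`, `"category"` or `"block"`.
#' @param map Block map, required iff `level = "block"`.
#' @param strict Error on codes not covered by the block map (default: fall
#'   back to category level with a warning).
#' @return A `ctrss_matrix`: tibble with `patient_id`, `dx:`/`proc:` binary
#'   columns, `age`, `gender`, `eligible`, plus a `level` attribute.
#' @export
pivot_cohort <- function(x, level = "none", map = NULL, strict = FALSE) {
  stopifnot(inherits(x, "ctrss_cohort"))
  level <- match.arg(level, aggregation_levels())
  if (level == "block" && is.null(map)) {
    abort("configuration error: level = 'block' requires a block map")
  }
  ids <- x$labels$patient_id
  records <- x$records[x$records$patient_id %in% ids, ]
  codes <- build_code_columns(records, ids, level, map, strict)
  demo <- x$demographics[match(ids, x$demographics$patient_id), ]
  df <- bind_cols(tibble(patient_id = ids), codes,
                  tibble(age = as.numeric(demo$age),
                         gender = as.integer(demo$gender == "male"),
                         eligible = x$labels$eligible))
  new_feature_matrix(df, level)
}

#' Build a scoring matrix for unscreened patients under a frozen schema
#'
#' Deployment path: pivots new patients' records onto exactly the attribute
#' columns a trained model was fitted with. Codes that aggregate to
#' attributes outside the schema are ignored; schema attributes absent from
#' the new data become all-zero columns.
#'
#' @param schema Character vector of model attribute names (from a
#'   [train_model()] fit), i.e. code attributes plus `age`, `gender`.
#' @param records EAV records tibble for the patients to score.
#' @param demographics Demographics tibble covering those patients.
#' @param level Aggregation level the schema was built at.
#' @param map Block map if `level = "block"`.
#' @return A `ctrss_matrix` without an `eligible` column.
#' @export
build_scoring_matrix <- function(schema, records, demographics,
                                 level = "none", map = NULL) {
  level <- match.arg(level, aggregation_levels())
  ids <- demographics$patient_id
  missing_rec <- setdiff(unique(records$patient_id), ids)
  if (length(missing_rec) > 0) {
    abort(paste0("patient(s) with code records but no demographics: ",
                 paste(utils::head(missing_rec, 5), collapse = ", ")))
  }
  code_cols <- setdiff(schema, c("age", "gender"))
  codes <- build_code_columns(records, ids, level, map, strict = FALSE)
  out <- matrix(0L, nrow = length(ids), ncol = length(code_cols),
                dimnames = list(NULL, code_cols))
  common <- intersect(colnames(codes), code_cols)
  if (length(common) > 0) out[, common] <- as.matrix(codes[, common])
  df <- bind_cols(tibble(patient_id = ids),
                  as_tibble(out, .name_repair = "minimal"),
                  tibble(age = as.numeric(demographics$age),
                         gender = as.integer(demographics$gender == "male")))
  new_feature_matrix(df, level)
}

#' Restrict a feature matrix to a set of model attributes
#'
#' Keeps `patient_id`, the given attributes (in schema order) and, when
#' present, `eligible`. Used to hand a model exactly its frozen schema.
#'
#' @param fm A `ctrss_matrix`.
#' @param attrs Character vector of model attribute names.
#' @return A `ctrss_matrix` with only the requested attribute columns.
#' @export
select_attributes <- function(fm, attrs) {
  missing <- setdiff(attrs, names(fm))
  if (length(missing) > 0) {
    abort(paste0("attributes not present in matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  keep <- c("patient_id", attrs, intersect("eligible", names(fm)))
  level <- attr(fm, "level")
  df <- fm
  class(df) <- setdiff(class(df), "ctrss_matrix")
  new_feature_matrix(df[, keep, drop = FALSE], level)
}

#' Summarize sparsity of a feature matrix
#'
#' Reports the count of patients and code attributes, the percentage of
#' valued (= 1) cells among the code columns, and per-attribute prevalence.
#' An empty code-column set yields `fraction_valued = 0` by convention.
#'
#' @param fm A `ctrss_matrix`.
#' @return List with `n_patients`, `n_attributes`, `fraction_valued`
#'   (percent), `median_prevalence` (percent), and a `prevalence` tibble
#'   (`attribute`, `n_patients_with`, `prevalence_pct`).
#' @export
summarize_sparsity <- function(fm) {
  stopifnot(inherits(fm, "ctrss_matrix"))
  attrs <- code_attributes(fm)
  n <- nrow(fm)
  if (length(attrs) == 0L || n == 0L) {
    return(list(n_patients = n, n_attributes = length(attrs),
                fraction_valued = 0, median_prevalence = NA_real_,
                prevalence = tibble(attribute = character(),
                                    n_patients_with = integer(),
                                    prevalence_pct = numeric())))
  }
  counts <- vapply(fm[attrs], function(col) sum(col == 1), numeric(1))
  prevalence <- tibble(attribute = attrs,
                       n_patients_with = as.integer(counts),
                       prevalence_pct = 100 * counts / n)
  list(n_patients = n,
       n_attributes = length(attrs),
       fraction_valued = 100 * sum(counts) / (n * length(attrs)),
       median_prevalence = stats::median(prevalence$prevalence_pct),
       prevalence = prevalence)
}
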