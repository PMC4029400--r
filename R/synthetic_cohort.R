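# Synthetic EHR cohorts with the statistical structure of routine hospital
# coding data: sparse binary code occurrence (median per-code prevalence
# around 0.4% before aggregation), mono-hierarchical ICD-like and OPS-like
# code universes, inclusion prevalences anywhere in (0, 1), and eligibility
# driven by a planted rule over code families and age. The signal is planted
# at the family (block) level — many rare child codes share one informative
# family, the regime where hierarchical aggregation should pay off — and the
# ground truth is returned so every pipeline stage has an oracle.

#' Default synthetic code universe
#'
#' Ten diagnosis blocks (letters A-J, five categories of six full codes each)
#' and eight procedure blocks in OPS chapter 5 (four categories of five full
#' codes each): 500 distinct raw codes, 70 categories, 18 blocks.
#'
#' @return Tibble with one row per full code: `system`, `block_start`,
#'   `block_end`, `block_label`, `category`, `code`.
#' @export
default_code_universe <- function() {
  dx <- purrr::map_dfr(LETTERS[1:10], function(letter) {
    cats <- paste0(letter, sprintf("%02d", 0:4))
    purrr::map_dfr(cats, function(cat) {
      tibble(system = "diagnosis",
             block_start = cats[1], block_end = cats[length(cats)],
             block_label = paste0("Synthetic chapter ", letter),
             category = cat, code = paste0(cat, ".", 0:5))
    })
  })
  proc <- purrr::map_dfr(seq_len(8), function(b) {
    cats <- paste0("5-", sprintf("%02d", (4 * (b - 1)):(4 * b - 1)))
    purrr::map_dfr(cats, function(cat) {
      tibble(system = "procedure",
             block_start = cats[1], block_end = cats[length(cats)],
             block_label = paste0("Synthetic procedure block ", b),
             category = cat, code = paste0(cat, 0:4, ".1"))
    })
  })
  bind_rows(dx, proc)
}

#' Block map implied by a code universe
#' @param universe A universe tibble (see [default_code_universe()]).
#' @return A `ctrss_block_map` covering every block in the universe.
#' @export
universe_block_map <- function(universe) {
  universe |>
    distinct(.data$system, .data$block_start, .data$block_end, .data$block_label) |>
    transmute(system = .data$system, range_start = .data$block_start,
              range_end = .data$block_end, label = .data$block_label) |>
    block_map()
}

block_key_of <- function(start, end) paste0(start, BLOCK_SEP, end)

#' Construct an eligibility-rule clause
#'
#' Rules are conjunctions of clauses. Family clauses test for the presence
#' (`family_any`) or absence (`family_none`) of any code in a block-level
#' family; age clauses compare against a threshold in years.
#'
#' @param type One of `"family_any"`, `"family_none"`, `"age_ge"`, `"age_lt"`.
#' @param system Code system, for family clauses.
#' @param block Block key (`"C00…C04"`), for family clauses.
#' @param threshold Age in years, for age clauses.
#' @return A clause list.
#' @export
rule_clause <- function(type, system = NULL, block = NULL, threshold = NULL) {
  type <- match.arg(type, c("family_any", "family_none", "age_ge", "age_lt"))
  if (type %in% c("family_any", "family_none")) {
    stopifnot(!is.null(system), !is.null(block))
    list(type = type, system = match.arg(system, CODE_SYSTEMS), block = block)
  } else {
    stopifnot(is.numeric(threshold))
    list(type = type, threshold = threshold)
  }
}

#' Default planted eligibility rule
#'
#' Eligible iff the patient has any code in diagnosis block C00-C04, no code
#' in diagnosis block H00-H04 (mirroring exclusion by a code family, like
#' pregnancy chapters excluding trial participation), and is at least 18
#' years old.
#'
#' @return List of clauses (a conjunction).
#' @export
default_eligibility_rule <- function() {
  list(rule_clause("family_any", "diagnosis", block_key_of("C00", "C04")),
       rule_clause("family_none", "diagnosis", block_key_of("H00", "H04")),
       rule_clause("age_ge", threshold = 18))
}

#' Synthetic cohort configuration
#'
#' @param n_patients Number of screened (labeled) patients.
#' @param inclusion_prevalence Fraction of patients truly eligible, in (0, 1).
#' @param target_code_prevalence Target median per-code documentation
#'   prevalence before aggregation (default 0.004 = 0.4%). Per-code
#'   prevalences are drawn lognormally around this median (sdlog 0.8).
#' @param label_noise Probability that an emitted label is flipped relative
#'   to the planted rule (default 0.02).
#' @param universe Code universe tibble (default [default_code_universe()]).
#' @param rule Planted rule, a conjunction of [rule_clause()]s referencing
#'   blocks of the universe (default [default_eligibility_rule()]).
#' @param age_range Two integers, inclusive uniform age range (default 16-90).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Object of class `ctrss_cohort_config`.
#' @export
cohort_config <- function(n_patients = 1500L, inclusion_prevalence = 0.10,
                          target_code_prevalence = 0.004, label_noise = 0.02,
                          universe = default_code_universe(),
                          rule = default_eligibility_rule(),
                          age_range = c(16L, 90L), seed = 1L) {
  if (!(inclusion_prevalence > 0 && inclusion_prevalence < 1)) {
    abort("inclusion_prevalence must be in (0, 1)")
  }
  if (n_patients * inclusion_prevalence < 2 ||
      n_patients * (1 - inclusion_prevalence) < 2) {
    abort("unattainable inclusion prevalence: expected class count below 2")
  }
  if (target_code_prevalence <= 0 || target_code_prevalence > 0.5) {
    abort("target_code_prevalence must be in (0, 0.5]")
  }
  if (target_code_prevalence * n_patients < 1) {
    abort("unattainable sparsity: target prevalence below 1 patient per code")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    abort("label_noise must be in [0, 0.5)")
  }
  blocks <- unique(block_key_of(universe$block_start, universe$block_end))
  for (cl in rule) {
    if (cl$type %in% c("family_any", "family_none") && !cl$block %in% blocks) {
      abort(paste0("rule references a family absent from the universe: ", cl$block))
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 inclusion_prevalence = inclusion_prevalence,
                 target_code_prevalence = target_code_prevalence,
                 label_noise = label_noise, universe = universe, rule = rule,
                 age_range = as.integer(age_range), seed = as.integer(seed)),
            class = "ctrss_cohort_config")
}

age_bounds <- function(rule, age_range) {
  lo <- age_range[1]; hi <- age_range[2]
  for (cl in rule) {
    if (cl$type == "age_ge") lo <- max(lo, cl$threshold)
    if (cl$type == "age_lt") hi <- min(hi, cl$threshold - 1L)
  }
  c(lo, hi)
}

#' Evaluate an eligibility rule against cohort data
#'
#' @param rule Conjunction of [rule_clause()]s.
#' @param records EAV records tibble.
#' @param demographics Demographics tibble (defines the patient set and
#'   order).
#' @param map Block map used to resolve family membership.
#' @return Logical vector, one entry per demographics row.
#' @export
evaluate_rule <- function(rule, records, demographics, map) {
  ids <- demographics$patient_id
  out <- rep(TRUE, length(ids))
  rec_block <- NULL
  if (nrow(records) > 0) {
    rec_block <- records |>
      group_by(.data$system) |>
      mutate(block = suppressWarnings(
        block_of(.data$code, .data$system[1], map))) |>
      ungroup()
  }
  for (cl in rule) {
    sat <- switch(
      cl$type,
      age_ge = demographics$age >= cl$threshold,
      age_lt = demographics$age < cl$threshold,
      family_any = ,
      family_none = {
        hit_ids <- if (is.null(rec_block)) character() else
          unique(rec_block$patient_id[rec_block$system == cl$system &
                                        rec_block$block == cl$block])
        has <- ids %in% hit_ids
        if (cl$type == "family_any") has else !has
      })
    out <- out & sat
  }
  out
}

#' Generate a synthetic cohort with planted eligibility
#'
#' Draws a latent eligibility class per patient at the configured inclusion
#' prevalence, then samples codes and age so that the planted rule evaluates
#' exactly to that class: rule families are forced present (1 plus a Poisson
#' number of distinct child codes, spread uniformly over the family) or
#' absent as each clause requires; ineligible patients violate one uniformly
#' chosen clause and sample the rest unconditionally. All other codes are
#' independent background noise at their per-code prevalence. Emitted labels
#' flip the true label with probability `label_noise`.
#'
#' @param config A `ctrss_cohort_config`.
#' @return Object of class `ctrss_synthetic`: list with `cohort`
#'   (a `ctrss_cohort`), `map` (the universe's `ctrss_block_map`), `truth`
#'   (planted rule, per-patient true labels, rule-relevant attribute names at
#'   each aggregation level) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ctrss_cohort_config"))
  uni <- config$universe
  map <- universe_block_map(uni)
  n <- config$n_patients
  m <- nrow(uni)
  ids <- sprintf("P%05d", seq_len(n))
  set.seed(config$seed)

  # per-code background prevalence: lognormal around the target median
  prev <- pmin(config$target_code_prevalence * exp(stats::rnorm(m, 0, 0.8)), 0.5)

  z <- stats::rbinom(n, 1, config$inclusion_prevalence) == 1

  # which clause each ineligible patient violates
  viol <- integer(n)
  viol[!z] <- sample.int(length(config$rule), sum(!z), replace = TRUE)

  # ages
  full_range <- config$age_range
  sat_range <- age_bounds(config$rule, full_range)
  if (sat_range[1] > sat_range[2]) abort("rule's age clauses are unsatisfiable")
  age <- sample(seq(full_range[1], full_range[2]), n, replace = TRUE)
  age[z] <- sample(seq(sat_range[1], sat_range[2]), sum(z), replace = TRUE)
  for (j in seq_along(config$rule)) {
    cl <- config$rule[[j]]
    if (!cl$type %in% c("age_ge", "age_lt")) next
    bad_range <- if (cl$type == "age_ge") {
      c(full_range[1], cl$threshold - 1L)
    } else {
      c(cl$threshold, full_range[2])
    }
    if (bad_range[1] > bad_range[2]) {
      abort("rule age clause cannot be violated within the age range")
    }
    who <- which(!z & viol == j)
    age[who] <- sample(seq(bad_range[1], bad_range[2]), length(who), replace = TRUE)
  }

  # background code occurrence
  occ <- matrix(stats::runif(n * m), n, m) < rep(prev, each = n)

  uni_block <- block_key_of(uni$block_start, uni$block_end)
  for (j in seq_along(config$rule)) {
    cl <- config$rule[[j]]
    if (!cl$type %in% c("family_any", "family_none")) next
    fam_cols <- which(uni$system == cl$system & uni_block == cl$block)
    need_present <- if (cl$type == "family_any") {
      which(z)                      # eligible must satisfy presence
    } else {
      which(!z & viol == j)         # violators of an absence clause
    }
    need_absent <- if (cl$type == "family_any") {
      which(!z & viol == j)         # violators of a presence clause
    } else {
      which(z)                      # eligible must satisfy absence
    }
    occ[need_absent, fam_cols] <- FALSE
    if (length(need_present) > 0) {
      n_codes <- 1L + stats::rpois(length(need_present), 0.7)
      for (i in seq_along(need_present)) {
        pick <- sample(fam_cols, min(n_codes[i], length(fam_cols)))
        occ[need_present[i], pick] <- TRUE
      }
    }
  }

  hits <- which(occ, arr.ind = TRUE)
  records <- tibble(patient_id = ids[hits[, 1]],
                    code = uni$code[hits[, 2]],
                    system = uni$system[hits[, 2]]) |>
    arrange(.data$patient_id, .data$system, .data$code)
  demographics <- tibble(patient_id = ids, age = as.integer(age),
                         gender = sample(c("female", "male"), n, replace = TRUE))

  true_eligible <- evaluate_rule(config$rule, records, demographics, map)
  stopifnot(identical(true_eligible, z))  # constructive sampling invariant

  flip <- stats::runif(n) < config$label_noise
  labels <- tibble(patient_id = ids, eligible = xor(true_eligible, flip))

  relevant <- relevant_attributes(config$rule, uni)
  structure(list(cohort = cohort(records, demographics, labels), map = map,
                 truth = list(rule = config$rule,
                              true_labels = tibble(patient_id = ids,
                                                   true_eligible = true_eligible),
                              relevant_attributes = relevant),
                 config = config),
            class = "ctrss_synthetic")
}

# rule-relevant attribute names at each aggregation level
relevant_attributes <- function(rule, universe) {
  uni_block <- block_key_of(universe$block_start, universe$block_end)
  none <- character(); category <- character(); block <- character()
  for (cl in rule) {
    if (!cl$type %in% c("family_any", "family_none")) next
    fam <- universe[universe$system == cl$system & uni_block == cl$block, ]
    none <- c(none, namespace_attr(fam$code, fam$system))
    category <- c(category, unique(namespace_attr(fam$category, fam$system)))
    block <- c(block, unique(namespace_attr(cl$block, cl$system)))
  }
  list(none = unique(none), category = unique(category), block = unique(block))
}

#' Bayes AUC of a synthetic cohort
#'
#' The AUC of the planted rule's true eligibility (a perfect binary scorer)
#' against the emitted, possibly noise-flipped labels: the ceiling any
#' trained model can approach on this cohort. 1.0 at zero label noise.
#'
#' @param synth A `ctrss_synthetic` from [generate_cohort()].
#' @return AUC value in `[0, 1]`.
#' @export
bayes_auc <- function(synth) {
  stopifnot(inherits(synth, "ctrss_synthetic"))
  truth <- synth$truth$true_labels
  labels <- synth$cohort$labels
  stopifnot(identical(truth$patient_id, labels$patient_id))
  roc_auc(as.numeric(truth$true_eligible), labels$eligible)
}

#' Write a synthetic cohort plus sidecar files
#'
#' Emits exactly the formats [read_cohort()] and [load_block_map()] read,
#' plus a ground-truth sidecar (`ground_truth.csv`) with the per-patient true
#' labels.
#'
#' @param synth A `ctrss_synthetic`.
#' @param dir Output directory.
#' @return Invisibly, named vector of written paths.
#' @export
write_synthetic <- function(synth, dir) {
  stopifnot(inherits(synth, "ctrss_synthetic"))
  paths <- write_cohort(synth$cohort, dir)
  bm <- file.path(dir, "block_map.csv")
  write_block_map(synth$map, bm)
  gt <- file.path(dir, "ground_truth.csv")
  readr::write_csv(synth$truth$true_labels, gt)
  invisible(c(paths, block_map = bm, ground_truth = gt))
}
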