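# Independent oracles and fixture builders shared across the suite.

# Pair-counting AUC: concordant pairs get full credit, tied pairs half.
# Deliberately quadratic and independent of the ROC-curve implementation.
pair_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(cmp) / (length(pos) * length(neg))
}

# Pearson chi-squared statistic and p-value evaluated cell by cell.
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
# 2x2 tables with the observed margins.
fisher_oracle <- function(tab) {
  m <- rowSums(tab)[1]; n <- rowSums(tab)[2]; k <- colSums(tab)[1]
  x_obs <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Tiny perfectly separable cohort: eligible iff diagnosis code A00.0 present.
toy_separable_cohort <- function(n_per_class = 15) {
  pos_ids <- sprintf("e%02d", seq_len(n_per_class))
  neg_ids <- sprintf("i%02d", seq_len(n_per_class))
  records <- dplyr::bind_rows(
    tibble::tibble(patient_id = pos_ids, code = "A00.0", system = "diagnosis"),
    tibble::tibble(patient_id = c(pos_ids, neg_ids), code = "B17.1",
                   system = "diagnosis"),
    tibble::tibble(patient_id = neg_ids[seq_len(floor(n_per_class / 2))],
                   code = "5-121.1", system = "procedure"))
  demographics <- tibble::tibble(
    patient_id = c(pos_ids, neg_ids),
    age = rep(c(40L, 60L), n_per_class),
    gender = rep(c("female", "male"), n_per_class))
  labels <- tibble::tibble(patient_id = c(pos_ids, neg_ids),
                           eligible = rep(c(TRUE, FALSE), each = n_per_class))
  cohort(records, demographics, labels)
}

small_synth <- function(seed, n = 400, prevalence = 0.2, noise = 0,
                        code_prev = 0.01) {
  generate_cohort(cohort_config(n_patients = n,
                                inclusion_prevalence = prevalence,
                                target_code_prevalence = code_prev,
                                label_noise = noise, seed = seed))
}
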