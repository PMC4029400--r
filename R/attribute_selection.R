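# Univariate reduction of the code attribute pool: rank by documentation
# frequency or by association with eligibility (chi-squared test of
# independence, falling back to Fisher's exact test when Cochran's rule is
# violated), then keep the top k. Age and gender bypass selection and are
# always retained.

#' Association p-value of a binary attribute with eligibility
#'
#' Builds the 2x2 contingency table attribute x eligibility and applies the
#' chi-squared test of independence without continuity correction; when any
#' expected cell count is below 5 (Cochran's rule) the two-sided Fisher exact
#' test is used instead. A degenerate table (constant attribute or
#' single-class labels, i.e. an all-zero margin) has no measurable
#' association and returns p = 1 with a degeneracy flag.
#'
#' @param x Binary (0/1 or logical) attribute vector.
#' @param y Logical eligibility labels, same length.
#' @return List with `p` (p-value), `test` (`"chi_squared"` or
#'   `"fisher_exact"`), and `degenerate` (logical).
#' @export
association_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  x <- as.integer(as.logical(x))
  y <- as.logical(y)
  tab <- table(factor(x, levels = c(0L, 1L)), factor(y, levels = c(FALSE, TRUE)))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  expected <- outer(rs, cs) / n
  fisher_branch <- any(expected < 5)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(p = 1, test = if (fisher_branch) "fisher_exact" else "chi_squared",
                degenerate = TRUE))
  }
  if (fisher_branch) {
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    list(p = unname(p), test = "fisher_exact", degenerate = FALSE)
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    list(p = unname(p), test = "chi_squared", degenerate = FALSE)
  }
}

#' Rank code attributes by frequency or association with eligibility
#'
#' Frequency ranking orders attributes by descending documentation prevalence
#' and never touches the labels (leakage-free by construction). Association
#' ranking orders by ascending p-value from [association_p()]. Ties are
#' broken lexicographically by attribute name, so the ranking is stable
#' across runs. Age and gender are never ranked; they are always retained by
#' [select_top_k()].
#'
#' @param fm A `ctrss_matrix` with labels (required for association ranking).
#' @param method `"frequency"` or `"association"`.
#' @return Tibble of class `ctrss_ranking` with columns `attribute`, `score`
#'   (prevalence count for frequency, p-value for association), `test_used`
#'   (`"none"` for frequency), `degenerate`, ordered best-first.
#' @export
rank_attributes <- function(fm, method = c("association", "frequency")) {
  method <- match.arg(method)
  attrs <- code_attributes(fm)
  if (method == "frequency") {
    counts <- vapply(fm[attrs], function(col) sum(col == 1), numeric(1))
    out <- tibble(attribute = attrs, score = counts,
                  test_used = "none", degenerate = FALSE) |>
      arrange(desc(.data$score), .data$attribute)
  } else {
    if (!"eligible" %in% names(fm)) {
      abort("association ranking requires eligibility labels")
    }
    y <- fm$eligible
    if (length(unique(y)) < 2) {
      abort(paste0("association ranking needs both eligible and ineligible ",
                   "patients; screen more patients before selecting attributes"))
    }
    res <- purrr::map(fm[attrs], association_p, y = y)
    out <- tibble(attribute = attrs,
                  score = purrr::map_dbl(res, "p"),
                  test_used = purrr::map_chr(res, "test"),
                  degenerate = purrr::map_lgl(res, "degenerate")) |>
      arrange(.data$score, .data$attribute)
  }
  structure(out, class = c("ctrss_ranking", class(out)), method = method)
}

#' Select the top k ranked code attributes
#'
#' Returns the first `min(k, available)` code attributes plus the always-kept
#' `age` and `gender`, i.e. `k = 20` yields up to 22 model inputs.
#'
#' @param ranking A `ctrss_ranking` from [rank_attributes()].
#' @param k Number of code attributes to keep (>= 1).
#' @return Character vector of selected attribute names.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "ctrss_ranking"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    abort("k must be a single number >= 1")
  }
  c(utils::head(ranking$attribute, k), "age", "gender")
}

#' Export a ranking as a delimited file
#' @param ranking A `ctrss_ranking`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  readr::write_csv(as_tibble(ranking), path)
  invisible(path)
}
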