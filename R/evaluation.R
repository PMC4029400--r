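# Holdout evaluation: ROC curves and trapezoidal AUC with tie-midpoint
# handling, bootstrap percentile confidence intervals, learning curves by
# iterative 30% training-set reduction against a fixed test set, and the full
# experiment grid over aggregation levels x selection methods x model
# families x k x training sizes.

subset_rows <- function(fm, idx) {
  level <- attr(fm, "level")
  df <- fm
  class(df) <- setdiff(class(df), "ctrss_matrix")
  new_feature_matrix(df[idx, , drop = FALSE], level)
}

#' Split a feature matrix into training and test partitions
#'
#' Single holdout partition, one third of patients in the test set by
#' default. Stratified by eligibility label by default: with inclusion
#' prevalences down to 1.6%, an unstratified third can lose every eligible
#' patient from one side. Deterministic per seed; the partition is disjoint
#' and exhaustive.
#'
#' @param fm A `ctrss_matrix` with labels.
#' @param test_fraction Fraction of patients held out (default 1/3).
#' @param stratified Stratify by label (default `TRUE`).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both `ctrss_matrix`.
#' @export
holdout_split <- function(fm, test_fraction = 1 / 3, stratified = TRUE, seed = 1L) {
  stopifnot(inherits(fm, "ctrss_matrix"), "eligible" %in% names(fm))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    abort("test_fraction must be in (0, 1)")
  }
  n <- nrow(fm)
  set.seed(seed)
  if (stratified) {
    test_idx <- integer()
    for (cls in c(FALSE, TRUE)) {
      idx <- which(fm$eligible == cls)
      n_test <- round(test_fraction * length(idx))
      if (n_test < 1 || n_test >= length(idx)) {
        abort(paste0("stratified split would leave the ",
                     if (cls) "eligible" else "ineligible",
                     " class absent from one side (class size ", length(idx), ")"))
      }
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  } else {
    n_test <- round(test_fraction * n)
    if (n_test < 1 || n_test >= n) abort("degenerate split")
    test_idx <- sample.int(n, n_test)
  }
  list(train = subset_rows(fm, setdiff(seq_len(n), test_idx)),
       test = subset_rows(fm, sort(test_idx)))
}

#' Empirical ROC curve points
#'
#' Thresholds at every distinct score value; the curve starts at (0, 0), ends
#' at (1, 1) and is monotone non-decreasing in both coordinates. Tied scores
#' enter the curve as a single diagonal segment, so trapezoidal integration
#' gives tied pairs half credit.
#'
#' @param scores Numeric scores (higher = more likely eligible).
#' @param labels Logical labels, both classes present.
#' @return Tibble with columns `fpr` (1 - specificity), `tpr` (sensitivity),
#'   `threshold`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    abort("ROC is undefined with single-class labels")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last_of_run <- which(c(s[-1] != s[-length(s)], TRUE))
  pos <- sum(y)
  neg <- sum(!y)
  tibble(fpr = c(0, cumsum(!y)[last_of_run] / neg),
         tpr = c(0, cumsum(y)[last_of_run] / pos),
         threshold = c(Inf, s[last_of_run]))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical ROC of [roc_points()]. Equivalent to
#' the concordant-pair (Mann-Whitney) statistic with half credit for tied
#' scores; all scores identical gives 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Logical labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Resamples (score, label) pairs with replacement `n_boot` times and returns
#' empirical quantiles of the resulting AUC distribution. A resample that
#' loses one class (possible at low prevalence) is redrawn, keeping the count
#' of usable resamples exact.
#'
#' @param scores Numeric scores.
#' @param labels Logical labels, both classes present.
#' @param n_boot Number of bootstrap resamples (default 1,000).
#' @param seed Integer seed.
#' @param probs Quantile probabilities (default 2.5% and 97.5%).
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000L, seed = 1L,
                             probs = c(0.025, 0.975)) {
  labels <- as.logical(labels)
  if (n_boot < 2) abort("n_boot must be at least 2")
  if (length(unique(labels)) < 2) abort("both classes required")
  n <- length(scores)
  set.seed(seed)
  aucs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      if (any(labels[i]) && any(!labels[i])) break
    }
    aucs[b] <- roc_auc(scores[i], labels[i])
  }
  q <- stats::quantile(aucs, probs = probs, names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' ROC evaluation of scores against labels
#'
#' Bundles the ROC curve, its AUC and the bootstrap percentile CI.
#'
#' @param scores Numeric scores.
#' @param labels Logical labels.
#' @param n_boot Bootstrap resamples (default 1,000); `0` skips the CI.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `ctrss_roc`: list with `curve`, `auc`, `ci_low`,
#'   `ci_high`, `n_boot`, `n`.
#' @export
roc_result <- function(scores, labels, n_boot = 1000L, seed = 1L) {
  curve <- roc_points(scores, labels)
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  if (n_boot > 0) {
    ci <- bootstrap_auc_ci(scores, labels, n_boot = n_boot, seed = seed)
  } else {
    ci <- c(ci_low = NA_real_, ci_high = NA_real_)
  }
  structure(list(curve = curve, auc = auc, ci_low = unname(ci[1]),
                 ci_high = unname(ci[2]), n_boot = as.integer(n_boot),
                 n = length(scores)),
            class = "ctrss_roc")
}

#' @export
print.ctrss_roc <- function(x, ...) {
  cat(sprintf("<ctrss_roc> AUC = %.3f (95%% CI %.3f-%.3f, %d bootstrap resamples, n = %d)\n",
              x$auc, x$ci_low, x$ci_high, x$n_boot, x$n))
  invisible(x)
}

#' @method tidy ctrss_roc
#' @export
tidy.ctrss_roc <- function(x, ...) x$curve

#' @method glance ctrss_roc
#' @export
glance.ctrss_roc <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n = x$n, n_boot = x$n_boot)
}

#' Remove a random 30% of training patients
#'
#' One step of the iterative training-set reduction: removes
#' `round(fraction * n)` patients uniformly at random (unstratified) and
#' returns the remainder. Returns `NULL` (a stop signal, not an error) when
#' removal would leave fewer than `min_size` patients or a single class.
#'
#' @param fm Training `ctrss_matrix`.
#' @param fraction Fraction removed per step (default 0.3).
#' @param seed Integer seed.
#' @param min_size Minimum allowed remaining size (default 10).
#' @return A smaller `ctrss_matrix`, or `NULL` to stop.
#' @export
reduce_training <- function(fm, fraction = 0.3, seed = 1L, min_size = 10L) {
  stopifnot(inherits(fm, "ctrss_matrix"), nrow(fm) > 0)
  n <- nrow(fm)
  n_remove <- round(fraction * n)
  if (n - n_remove < min_size) return(NULL)
  set.seed(seed)
  keep <- setdiff(seq_len(n), sample.int(n, n_remove))
  out <- subset_rows(fm, keep)
  if ("eligible" %in% names(out) && length(unique(out$eligible)) < 2) return(NULL)
  out
}

#' Learning curve: holdout AUC versus training-set size
#'
#' Splits once, then repeatedly shrinks the training set by
#' [reduce_training()] while always evaluating on the same fixed test set, so
#' differences along the curve reflect training size only. By default,
#' attribute selection is recomputed on each training subset
#' (`selection_scope = "train"`, leakage-consistent); `"all"` ranks once on
#' the full matrix instead. Failures of individual points (e.g. a family that
#' cannot fit a tiny subset) are recorded in the `status` column, not thrown.
#'
#' @param fm A `ctrss_matrix` with labels.
#' @param family One of [model_families()].
#' @param method Attribute selection method, `"association"` or `"frequency"`.
#' @param k Number of code attributes to keep.
#' @param seed Integer seed; split, per-size fits and bootstraps derive their
#'   own seeds from it.
#' @param test_fraction,stratified Passed to [holdout_split()].
#' @param reduction Fraction removed per reduction step (default 0.3).
#' @param min_train Minimum training size (default 10).
#' @param n_boot Bootstrap resamples per point (default 1,000); `0` skips CIs.
#' @param selection_scope `"train"` or `"all"`.
#' @return Tibble of class `ctrss_learning_curve`: one row per training size
#'   with `train_n`, `auc`, `ci_low`, `ci_high`, `n_test`, `seed`, `status`.
#' @export
learning_curve <- function(fm, family, method = "association", k = 20L,
                           seed = 1L, test_fraction = 1 / 3, stratified = TRUE,
                           reduction = 0.3, min_train = 10L, n_boot = 1000L,
                           selection_scope = c("train", "all")) {
  selection_scope <- match.arg(selection_scope)
  split <- holdout_split(fm, test_fraction, stratified,
                         seed = derive_seed(seed, "split"))
  test <- split$test
  full_ranking <- if (selection_scope == "all") rank_attributes(fm, method) else NULL
  rows <- list()
  train <- split$train
  while (!is.null(train)) {
    n_i <- nrow(train)
    point_seed <- derive_seed(seed, paste0("train-", n_i))
    res <- tryCatch({
      ranking <- full_ranking %||% rank_attributes(train, method)
      sel <- select_top_k(ranking, k)
      model <- train_model(train, family, seed = point_seed, attributes = sel)
      sc <- score_model(model, select_attributes(test, sel))
      rr <- roc_result(sc$score, test$eligible, n_boot = n_boot,
                       seed = derive_seed(seed, paste0("boot-", n_i)))
      tibble(train_n = n_i, auc = rr$auc, ci_low = rr$ci_low,
             ci_high = rr$ci_high, n_test = nrow(test),
             seed = point_seed, status = "ok")
    }, error = function(e) {
      tibble(train_n = n_i, auc = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, n_test = nrow(test),
             seed = point_seed, status = paste0("error: ", conditionMessage(e)))
    })
    rows[[length(rows) + 1]] <- res
    train <- reduce_training(train, fraction = reduction,
                             seed = derive_seed(seed, paste0("reduce-", n_i)),
                             min_size = min_train)
  }
  out <- bind_rows(rows)
  structure(out, class = c("ctrss_learning_curve", class(out)))
}

#' Run the full experiment grid
#'
#' Iterates the cross-product of aggregation levels, model families,
#' selection methods and k values; each cell runs a full learning curve (one
#' row per training size) with a seed derived deterministically from the
#' master seed and the cell coordinates, so any cell is reproducible in
#' isolation and a rerun with the same master seed is identical. Cell-level
#' failures are recorded in `status`; the grid continues.
#'
#' @param x A `ctrss_cohort`.
#' @param map Block map (required when `"block"` is among `levels`).
#' @param families,levels,methods,ks Grid axes (defaults: all five families,
#'   all three levels, both selection methods, k of 20 and 40).
#' @param master_seed Integer master seed.
#' @param cohort_id Identifier written into the result rows.
#' @param ... Passed to [learning_curve()] (`test_fraction`, `n_boot`,
#'   `min_train`, ...).
#' @return Tibble of class `ctrss_grid`: one row per grid cell and training
#'   size with AUC, CI, seed and status.
#' @export
run_grid <- function(x, map = NULL, families = model_families(),
                     levels = aggregation_levels(),
                     methods = c("association", "frequency"),
                     ks = c(20L, 40L), master_seed = 1L,
                     cohort_id = "cohort", ...) {
  stopifnot(inherits(x, "ctrss_cohort"))
  if ("block" %in% levels && is.null(map)) {
    abort("configuration error: block level requested without a block map")
  }
  rows <- list()
  for (level in levels) {
    fm <- pivot_cohort(x, level, map = map)
    for (family in families) {
      for (method in methods) {
        for (k in ks) {
          cell <- paste(cohort_id, level, family, method, k, sep = "|")
          cell_seed <- derive_seed(master_seed, cell)
          lc <- tryCatch(
            learning_curve(fm, family, method = method, k = k,
                           seed = cell_seed, ...),
            error = function(e) {
              tibble(train_n = NA_integer_, auc = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, n_test = NA_integer_, seed = cell_seed,
                     status = paste0("error: ", conditionMessage(e)))
            })
          rows[[length(rows) + 1]] <- lc |>
            mutate(cohort = cohort_id, level = level, family = family,
                   method = method, k = as.integer(k), .before = 1)
        }
      }
    }
  }
  out <- bind_rows(rows)
  structure(as_tibble(out), class = c("ctrss_grid", class(as_tibble(out))))
}

#' @method glance ctrss_grid
#' @export
glance.ctrss_grid <- function(x, ...) {
  x |>
    filter(.data$status == "ok") |>
    group_by(.data$level, .data$family, .data$method, .data$k) |>
    summarise(max_auc = max(.data$auc), best_train_n = .data$train_n[which.max(.data$auc)],
              n_points = dplyr::n(), .groups = "drop")
}
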