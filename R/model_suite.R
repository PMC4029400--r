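# The five classifier families compared by the pipeline, behind one
# family-agnostic interface: CART decision trees (rpart), random forests
# (randomForest), logistic regression with and without backward stepwise
# selection by AIC (stats::glm / stats::step), and RBF-kernel support vector
# machines with sigmoid-calibrated probabilities (e1071). Hyperparameters
# default to the originating packages' documented defaults.
#
# Attribute names carry ICD/OPS punctuation that R formulas cannot digest, so
# fitting happens on an internal copy with positional names (x1..xp); the
# frozen schema keeps the mapping and every scoring call is checked against it.

MODEL_FAMILIES <- c("cart_tree", "random_forest", "logistic",
                    "logistic_stepwise", "svm")

#' Supported model families
#' @return Character vector of the five family names.
#' @export
model_families <- function() MODEL_FAMILIES

# internal fitting frame with syntactic names
safe_frame <- function(fm, schema) {
  X <- as.data.frame(fm[schema], check.names = FALSE)
  names(X) <- paste0("x", seq_along(schema))
  X
}

#' Train an eligibility classifier
#'
#' Fits one of the five families on a feature matrix (optionally restricted
#' to a selected attribute subset) and freezes the attribute schema so that
#' scoring refuses mismatched columns. The fit is deterministic given the
#' seed. Stepwise logistic regression performs backward elimination from the
#' full model by AIC; the random forest draws a bootstrap resample per tree
#' (500 trees, `sqrt(p)` candidate attributes per split by default — set
#' `mtry = p` in `hyper` for pure bagging); the SVM uses an RBF kernel with
#' cost 1 and sigmoid-fitted probabilities. More attributes than patients is
#' permitted but flagged with a message.
#'
#' @param fm A `ctrss_matrix` with an `eligible` column and at least two
#'   patients of each class.
#' @param family One of [model_families()].
#' @param seed Integer seed fixing all randomness in the fit.
#' @param attributes Optional character vector of model inputs (e.g. from
#'   [select_top_k()]); defaults to all code attributes plus age and gender.
#' @param hyper Named list of family-specific overrides (`ntree`, `mtry`,
#'   `cost`, `gamma`, `cp`, ...).
#' @return Object of class `ctrss_model`.
#' @export
train_model <- function(fm, family, seed = 1L, attributes = NULL, hyper = list()) {
  family <- match.arg(family, MODEL_FAMILIES)
  stopifnot(inherits(fm, "ctrss_matrix"))
  if (!"eligible" %in% names(fm)) abort("training requires an 'eligible' column")
  schema <- attributes %||% model_attributes(fm)
  missing <- setdiff(schema, names(fm))
  if (length(missing) > 0) {
    abort(paste0("attributes not present in matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  y <- factor(as.integer(fm$eligible), levels = c(0L, 1L))
  if (min(table(y)) < 2) {
    abort("training requires at least 2 patients of each eligibility class")
  }
  if (length(schema) > nrow(fm)) {
    rlang::inform(paste0("more attributes (", length(schema), ") than patients (",
                         nrow(fm), ")"))
  }
  X <- safe_frame(fm, schema)
  set.seed(seed)
  fit <- switch(
    family,
    cart_tree = rpart::rpart(y ~ ., data = cbind(X, y = y), method = "class"),
    random_forest = randomForest::randomForest(
      x = X, y = y,
      ntree = hyper$ntree %||% 500,
      mtry = hyper$mtry %||% max(1, floor(sqrt(ncol(X))))),
    logistic = suppressWarnings(
      stats::glm(y ~ ., data = cbind(X, y = y), family = stats::binomial())),
    logistic_stepwise = suppressWarnings({
      full <- stats::glm(y ~ ., data = cbind(X, y = y), family = stats::binomial())
      stats::step(full, direction = "backward", trace = 0)
    }),
    svm = {
      # constant columns cannot be standardized; exempt them from scaling
      scale_vec <- vapply(X, function(col) stats::var(col) > 0, logical(1))
      e1071::svm(x = X, y = y, probability = TRUE, kernel = "radial",
                 cost = hyper$cost %||% 1,
                 gamma = hyper$gamma %||% (1 / ncol(X)),
                 scale = scale_vec)
    })
  structure(list(family = family, seed = as.integer(seed), schema = schema,
                 fit = fit, level = attr(fm, "level") %||% "none",
                 n = nrow(fm), n_eligible = sum(fm$eligible),
                 version = 1L),
            class = "ctrss_model")
}

#' Score patients with a trained model
#'
#' Emits one eligibility score per patient, in input order, always in
#' `[0, 1]`: leaf class fractions for CART, out-of-bag-style vote fractions
#' for the forest, fitted probabilities for the logistic models, calibrated
#' probabilities for the SVM. The input columns must match the model's frozen
#' schema exactly.
#'
#' @param model A `ctrss_model`.
#' @param fm A `ctrss_matrix` (labels not required).
#' @return Tibble with columns `patient_id`, `score`.
#' @export
score_model <- function(model, fm) {
  stopifnot(inherits(model, "ctrss_model"))
  have <- model_attributes(fm)
  missing <- setdiff(model$schema, have)
  extra <- setdiff(have, model$schema)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0("schema mismatch",
                 if (length(missing) > 0)
                   paste0("; missing: ", paste(utils::head(missing, 5), collapse = ", ")),
                 if (length(extra) > 0)
                   paste0("; extra: ", paste(utils::head(extra, 5), collapse = ", "))))
  }
  if (nrow(fm) == 0L) return(tibble(patient_id = character(), score = numeric()))
  X <- safe_frame(fm, model$schema)
  p <- switch(
    model$family,
    cart_tree = stats::predict(model$fit, newdata = X, type = "prob")[, "1"],
    random_forest = stats::predict(model$fit, newdata = X, type = "prob")[, "1"],
    logistic = ,
    logistic_stepwise = suppressWarnings(
      stats::predict(model$fit, newdata = X, type = "response")),
    svm = {
      pr <- stats::predict(model$fit, newdata = X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    })
  tibble(patient_id = fm$patient_id, score = pmin(pmax(unname(p), 0), 1))
}

#' Persist a trained model to a versioned file
#' @param model A `ctrss_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ctrss_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a persisted model
#' @param path Path written by [save_model()].
#' @return A `ctrss_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ctrss_model") || is.null(model$version)) {
    abort(paste0("not a ctrss model file: ", path))
  }
  model
}

#' @export
print.ctrss_model <- function(x, ...) {
  cat("<ctrss_model>", x$family, "\n")
  cat("  trained on", x$n, "patients (", x$n_eligible, "eligible ),",
      length(x$schema), "attributes, level =", x$level, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-attribute information from a fitted eligibility model
#'
#' Logistic models yield a coefficient table; trees and forests yield
#' variable importance; the SVM yields the schema with the number of support
#' vectors as metadata. Internal positional names are mapped back to the
#' original attribute names.
#'
#' @param x A `ctrss_model`.
#' @param ... Unused.
#' @return A tibble with one row per attribute/term.
#' @method tidy ctrss_model
#' @export
tidy.ctrss_model <- function(x, ...) {
  unmap <- function(term) {
    idx <- match(term, paste0("x", seq_along(x$schema)))
    ifelse(is.na(idx), term, x$schema[idx])
  }
  switch(
    x$family,
    logistic = ,
    logistic_stepwise = {
      cf <- summary(x$fit)$coefficients
      tibble(term = unmap(rownames(cf)), estimate = cf[, 1],
             std.error = cf[, 2], statistic = cf[, 3], p.value = cf[, 4])
    },
    random_forest = {
      imp <- randomForest::importance(x$fit)
      tibble(term = unmap(rownames(imp)), importance = imp[, 1]) |>
        arrange(desc(.data$importance))
    },
    cart_tree = {
      imp <- x$fit$variable.importance
      if (is.null(imp)) return(tibble(term = character(), importance = numeric()))
      tibble(term = unmap(names(imp)), importance = unname(imp))
    },
    svm = tibble(term = x$schema, n_support_vectors = x$fit$tot.nSV))
}

#' One-row summary of a fitted eligibility model
#' @param x A `ctrss_model`.
#' @param ... Unused.
#' @return One-row tibble: family, n, class balance, attribute count, level,
#'   seed.
#' @method glance ctrss_model
#' @export
glance.ctrss_model <- function(x, ...) {
  tibble(family = x$family, n = x$n, n_eligible = x$n_eligible,
         prevalence = x$n_eligible / x$n,
         n_attributes = length(x$schema), level = x$level, seed = x$seed)
}
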