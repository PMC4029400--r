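test_that("holdout split arithmetic, stratification and determinism", {
  synth <- small_synth(seed = 31, n = 300, prevalence = 0.3)
  fm <- pivot_cohort(synth$cohort, "none")
  sp <- holdout_split(fm, test_fraction = 1 / 3, stratified = FALSE, seed = 5)
  expect_equal(nrow(sp$test), 100L)
  expect_equal(nrow(sp$train), 200L)
  expect_equal(sort(c(sp$train$patient_id, sp$test$patient_id)),
               sort(fm$patient_id))  # disjoint and exhaustive
  n_elig <- sum(fm$eligible)
  sps <- holdout_split(fm, stratified = TRUE, seed = 5)
  expect_equal(sum(sps$test$eligible), round(n_elig / 3))
  sps2 <- holdout_split(fm, stratified = TRUE, seed = 5)
  expect_equal(sps$test$patient_id, sps2$test$patient_id)
})

test_that("stratified split fails when a class cannot appear on both sides", {
  fm <- pivot_cohort(toy_separable_cohort(2), "none")
  fm$eligible <- c(TRUE, rep(FALSE, 3))
  expect_error(holdout_split(fm, stratified = TRUE), "absent from one side")
})

test_that("AUC matches hand-computable cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
})

test_that("trapezoidal AUC equals the pair-counting oracle, including ties", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), pair_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:10) {
    scores <- stats::rnorm(80)
    labels <- stats::rbinom(80, 1, 0.4) == 1
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-10)
  }
})

test_that("ROC curves are anchored and monotone", {
  set.seed(99)
  for (i in 1:20) {
    scores <- sample(seq(0, 1, 0.2), 40, replace = TRUE)
    labels <- stats::rbinom(40, 1, 0.5) == 1
    if (length(unique(labels)) < 2) next
    pts <- roc_points(scores, labels)
    expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
  }
})

test_that("bootstrap CI is degenerate for separated scores and deterministic", {
  scores <- c(rep(0.9, 10), rep(0.1, 10))
  labels <- rep(c(TRUE, FALSE), each = 10)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = 100, seed = 1)
  expect_equal(unname(ci), c(1, 1))
  set.seed(11); s <- stats::rnorm(40); l <- rep(c(TRUE, FALSE), 20)
  expect_equal(bootstrap_auc_ci(s, l, n_boot = 200, seed = 3),
               bootstrap_auc_ci(s, l, n_boot = 200, seed = 3))
  expect_error(bootstrap_auc_ci(s, l, n_boot = 1), "at least 2")
})

test_that("bootstrap CI width shrinks with test-set size on average", {
  widths <- vapply(c(50, 200, 800), function(n) {
    mean(vapply(1:8, function(s) {
      set.seed(s)
      scores <- stats::rnorm(n) + rep(c(0.5, 0), c(n / 2, n / 2))
      labels <- rep(c(TRUE, FALSE), each = n / 2)
      ci <- bootstrap_auc_ci(scores, labels, n_boot = 300, seed = s)
      ci[2] - ci[1]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("training reduction follows round(0.3 n) and signals stop", {
  synth <- small_synth(seed = 41, n = 300, prevalence = 0.3)
  fm <- pivot_cohort(synth$cohort, "none")
  r1 <- reduce_training(fm, seed = 1)
  expect_equal(nrow(r1), 210L)
  expect_equal(nrow(reduce_training(r1, seed = 2)), 147L)
  # full ladder from 200 under the default minimum size of 10
  sizes <- 200L
  n <- 200L
  repeat {
    nxt <- n - round(0.3 * n)
    if (nxt < 10) break
    sizes <- c(sizes, nxt); n <- nxt
  }
  expect_equal(sizes, c(200L, 140L, 98L, 69L, 48L, 34L, 24L, 17L, 12L))
  fm200 <- holdout_split(fm, test_fraction = 1 / 3, seed = 1)$train
  lad <- nrow(fm200)
  cur <- fm200
  observed <- integer()
  while (!is.null(cur)) {
    observed <- c(observed, nrow(cur))
    cur <- reduce_training(cur, seed = nrow(cur))
  }
  expect_equal(observed, sizes)
})

test_that("learning curves keep the test set fixed and track the ladder", {
  fm <- pivot_cohort(toy_separable_cohort(30), "none")
  # logistic regression fits the separating code at any training size; trees
  # cannot split below rpart's default minsplit, so they are tested elsewhere
  lc <- learning_curve(fm, "logistic", method = "frequency", k = 3,
                       seed = 5, n_boot = 0, min_train = 10)
  expect_s3_class(lc, "ctrss_learning_curve")
  expect_true(all(lc$n_test == lc$n_test[1]))
  expect_true(all(diff(lc$train_n) < 0))
  # separable: every point that trained successfully reaches AUC 1
  ok <- lc[lc$status == "ok", ]
  expect_true(all(ok$auc == 1.0))
  # ladder arithmetic from the initial training size
  expected <- integer(); n <- lc$train_n[1]
  repeat {
    expected <- c(expected, n)
    nxt <- n - round(0.3 * n)
    if (nxt < 10) break
    n <- nxt
  }
  expect_equal(lc$train_n, expected)
})

test_that("run_grid covers the requested cross-product deterministically", {
  synth <- small_synth(seed = 51, n = 200, prevalence = 0.25)
  g1 <- run_grid(synth$cohort, map = synth$map,
                 families = c("cart_tree", "logistic"),
                 levels = c("none", "block"), methods = "association",
                 ks = 10, master_seed = 7, n_boot = 20, min_train = 40)
  expect_s3_class(g1, "ctrss_grid")
  expect_equal(nrow(dplyr::distinct(g1, level, family, method, k)), 4L)
  g2 <- run_grid(synth$cohort, map = synth$map,
                 families = c("cart_tree", "logistic"),
                 levels = c("none", "block"), methods = "association",
                 ks = 10, master_seed = 7, n_boot = 20, min_train = 40)
  expect_equal(as.data.frame(g1), as.data.frame(g2))
  expect_error(run_grid(synth$cohort, map = NULL, levels = "block"),
               "block map")
})
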