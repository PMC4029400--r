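# association_p works on vectors; build them from a 2x2 table
vectors_from_table <- function(tab) {
  # tab rows = attribute 0/1, cols = ineligible/eligible
  x <- rep(c(0, 0, 1, 1), times = c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  y <- rep(c(FALSE, TRUE, FALSE, TRUE),
           times = c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  list(x = x, y = y)
}

test_that("chi-squared branch matches the cell-by-cell oracle", {
  tab <- matrix(c(10, 30, 20, 40), 2)  # [[10,20],[30,40]], all expected >= 5
  oracle <- chisq_oracle(tab)
  expect_equal(oracle$stat, 0.7937, tolerance = 1e-4)
  v <- vectors_from_table(tab)
  res <- association_p(v$x, v$y)
  expect_equal(res$test, "chi_squared")
  expect_false(res$degenerate)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
})

test_that("Fisher branch matches exhaustive hypergeometric enumeration", {
  tab <- matrix(c(1, 12, 9, 2), 2)  # [[1,9],[12,2]]: min expected 4.58 < 5
  v <- vectors_from_table(tab)
  res <- association_p(v$x, v$y)
  expect_equal(res$test, "fisher_exact")
  expect_equal(res$p, fisher_oracle(tab), tolerance = 1e-12)
})

test_that("the Fisher fallback triggers exactly at minimum expected count 5", {
  # boundary pair: min expected exactly 5 (chi-squared) vs just below (Fisher)
  tab5 <- matrix(c(5, 45, 5, 45), 2)   # margins (10, 90) x (50, 50): min E = 5
  e5 <- outer(rowSums(tab5), colSums(tab5)) / sum(tab5)
  expect_equal(min(e5), 5)
  v5 <- vectors_from_table(tab5)
  expect_equal(association_p(v5$x, v5$y)$test, "chi_squared")
  tab4 <- matrix(c(5, 45, 4, 46), 2)
  e4 <- outer(rowSums(tab4), colSums(tab4)) / sum(tab4)
  expect_lt(min(e4), 5)
  v4 <- vectors_from_table(tab4)
  expect_equal(association_p(v4$x, v4$y)$test, "fisher_exact")
})

test_that("degenerate tables return p = 1 with a flag", {
  res <- association_p(rep(0, 20), rep(c(TRUE, FALSE), 10))
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
})

test_that("association_p is symmetric under joint complementation", {
  set.seed(42)
  for (i in 1:20) {
    x <- stats::rbinom(60, 1, 0.3)
    y <- stats::rbinom(60, 1, 0.4) == 1
    a <- association_p(x, y)
    b <- association_p(1 - x, !y)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_equal(a$test, b$test)
  }
})

test_that("frequency ranking orders by prevalence and ignores labels", {
  fm <- structure(tibble::tibble(
    patient_id = sprintf("p%d", 1:10),
    `dx:C01` = c(rep(1, 5), rep(0, 5)),
    `dx:C02` = c(1, rep(0, 9)),
    `dx:C03` = c(rep(1, 3), rep(0, 7)),
    age = 40, gender = 0L,
    eligible = rep(c(TRUE, FALSE), 5)),
    class = c("ctrss_matrix", "tbl_df", "tbl", "data.frame"), level = "none")
  r <- rank_attributes(fm, "frequency")
  expect_equal(r$attribute, c("dx:C01", "dx:C03", "dx:C02"))
  expect_true(all(r$test_used == "none"))
  fm2 <- fm
  fm2$eligible <- rev(fm$eligible)
  expect_equal(rank_attributes(fm2, "frequency")$attribute, r$attribute)
})

test_that("tied ranks break lexicographically and are stable", {
  fm <- structure(tibble::tibble(
    patient_id = sprintf("p%d", 1:8),
    `dx:B01` = c(1, 1, 0, 0, 0, 0, 0, 0),
    `dx:A01` = c(0, 0, 1, 1, 0, 0, 0, 0),
    age = 40, gender = 0L,
    eligible = rep(c(TRUE, FALSE), 4)),
    class = c("ctrss_matrix", "tbl_df", "tbl", "data.frame"), level = "none")
  for (method in c("frequency", "association")) {
    r <- rank_attributes(fm, method)
    expect_equal(r$attribute[1], "dx:A01")
  }
})

test_that("select_top_k clamps and always keeps age and gender", {
  ranking <- structure(tibble::tibble(attribute = sprintf("dx:C%02d", 1:30),
                                      score = seq(0.001, 0.03, length.out = 30),
                                      test_used = "chi_squared", degenerate = FALSE),
                       class = c("ctrss_ranking", "tbl_df", "tbl", "data.frame"))
  sel <- select_top_k(ranking, 20)
  expect_length(sel, 22)
  expect_equal(utils::tail(sel, 2), c("age", "gender"))
  expect_length(select_top_k(ranking[1:10, ], 40), 12)
  expect_error(select_top_k(ranking, 0), "k must")
})

test_that("association ranking refuses single-class labels", {
  fm <- structure(tibble::tibble(patient_id = c("p1", "p2"), `dx:A01` = c(0L, 1L),
                                 age = 40, gender = 0L, eligible = c(TRUE, TRUE)),
                  class = c("ctrss_matrix", "tbl_df", "tbl", "data.frame"),
                  level = "none")
  expect_error(rank_attributes(fm, "association"), "screen more")
})
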