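demo_map <- load_block_map(system.file("extdata", "demo_block_map.csv",
                                       package = "ctrss"))

two_code_cohort <- function() {
  cohort(tibble::tibble(patient_id = "p1", code = c("L40.4", "L41.0"),
                        system = "diagnosis"),
         tibble::tibble(patient_id = c("p1", "p2"), age = c(45L, 30L),
                        gender = c("female", "male")),
         tibble::tibble(patient_id = c("p1", "p2"), eligible = c(TRUE, FALSE)))
}

test_that("pivot ORs subordinate codes into aggregated columns", {
  ch <- two_code_cohort()
  fm_cat <- pivot_cohort(ch, "category")
  expect_equal(code_attributes(fm_cat), c("dx:L40", "dx:L41"))
  expect_equal(unlist(fm_cat[1, c("dx:L40", "dx:L41")], use.names = FALSE), c(1L, 1L))
  fm_blk <- pivot_cohort(ch, "block", map = demo_map)
  expect_equal(code_attributes(fm_blk), "dx:L40…L45")
  expect_equal(fm_blk[["dx:L40…L45"]], c(1L, 0L))
})

test_that("zero-record patients get all-zero code columns with demographics", {
  fm <- pivot_cohort(two_code_cohort(), "none")
  p2 <- fm[fm$patient_id == "p2", ]
  expect_true(all(p2[code_attributes(fm)] == 0))
  expect_equal(p2$age, 30)
  expect_equal(p2$gender, 1L)
})

test_that("block level without a map is a configuration error", {
  expect_error(pivot_cohort(two_code_cohort(), "block"), "block map")
})

test_that("pivot is invariant to EAV record order", {
  synth <- small_synth(seed = 11, n = 150)
  ch <- synth$cohort
  set.seed(1)
  shuffled <- cohort(ch$records[sample(nrow(ch$records)), ],
                     ch$demographics, ch$labels)
  expect_equal(as.data.frame(pivot_cohort(shuffled, "category")),
               as.data.frame(pivot_cohort(ch, "category")))
})

test_that("sparsity summary counts valued cells and degenerate cases", {
  ch <- cohort(tibble::tibble(patient_id = c("p1", "p1", "p2"),
                              code = c("A01.0", "B02.0", "A01.0"),
                              system = "diagnosis"),
               tibble::tibble(patient_id = c("p1", "p2"), age = c(40L, 50L),
                              gender = c("female", "male")),
               tibble::tibble(patient_id = c("p1", "p2"), eligible = c(TRUE, FALSE)))
  s <- summarize_sparsity(pivot_cohort(ch, "none"))
  expect_equal(s$fraction_valued, 75)  # three 1-cells of four
  empty <- cohort(tibble::tibble(patient_id = character(), code = character(),
                                 system = character()),
                  ch$demographics, ch$labels)
  expect_equal(summarize_sparsity(pivot_cohort(empty, "none"))$fraction_valued, 0)
})

test_that("prevalence never decreases under aggregation", {
  synth <- small_synth(seed = 5, n = 300)
  fm_none <- pivot_cohort(synth$cohort, "none")
  fm_cat <- pivot_cohort(synth$cohort, "category")
  fm_blk <- pivot_cohort(synth$cohort, "block", map = synth$map)
  prev <- function(fm) {
    s <- summarize_sparsity(fm)
    stats::setNames(s$prevalence$prevalence_pct, s$prevalence$attribute)
  }
  p_none <- prev(fm_none); p_cat <- prev(fm_cat); p_blk <- prev(fm_blk)
  # each raw code's parent category is at least as prevalent
  raw <- sub("^(dx|proc):", "", names(p_none))
  sys <- ifelse(startsWith(names(p_none), "dx:"), "diagnosis", "procedure")
  parents <- paste0(ifelse(sys == "diagnosis", "dx:", "proc:"),
                    vapply(seq_along(raw),
                           function(i) category_of(raw[i], sys[i]), character(1)))
  expect_true(all(p_cat[parents] >= p_none - 1e-12))
  # and each category's block parent likewise
  cats <- sub("^(dx|proc):", "", names(p_cat))
  sys_c <- ifelse(startsWith(names(p_cat), "dx:"), "diagnosis", "procedure")
  blocks <- paste0(ifelse(sys_c == "diagnosis", "dx:", "proc:"),
                   vapply(seq_along(cats), function(i) {
                     block_of(cats[i], sys_c[i], synth$map)
                   }, character(1)))
  expect_true(all(p_blk[blocks] >= p_cat - 1e-12))
})

test_that("scoring matrices freeze the schema", {
  synth <- small_synth(seed = 9, n = 120)
  fm <- pivot_cohort(synth$cohort, "category")
  schema <- model_attributes(fm)
  new_demo <- tibble::tibble(patient_id = c("q1", "q2"), age = c(25L, 70L),
                             gender = c("female", "male"))
  new_recs <- tibble::tibble(patient_id = "q1",
                             code = c("C01.2", "Y99.9"),  # Y99 unseen in training
                             system = "diagnosis")
  sm <- build_scoring_matrix(schema, new_recs, new_demo, level = "category")
  expect_equal(model_attributes(sm), schema)
  expect_false("eligible" %in% names(sm))
  expect_equal(sm[["dx:C01"]], c(1L, 0L))
})
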