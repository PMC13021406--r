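ref_with_counts <- function(counts, g = image_grid(200, 200)) {
  lesions <- list()
  # microaneurysm-sized dots on a spaced lattice; class decides the label only
  spots <- expand.grid(r = seq(2, 196, by = 4), c = seq(2, 196, by = 4))
  used <- 0L
  for (p in names(counts)) {
    n <- counts[[p]]
    if (n == 0L) next
    lesions[[p]] <- lapply(seq_len(n), function(i) {
      s <- spots[used + i, ]
      one_lesion(s$r, s$c, g$height, g$width, p)
    })
    used <- used + n
  }
  annotation_set("grading", g, "REFERENCE", lesions)
}

test_that("the default table maps canonical presentations to their grades", {
  tab <- default_grading_rules()
  expect_equal(grade_severity(ref_with_counts(list()), tab)$grade, 0L)
  expect_equal(grade_severity(ref_with_counts(list()), tab)$label, "no DR")
  expect_equal(grade_severity(ref_with_counts(list(MICROANEURYSM = 3L)), tab)$grade, 1L)
  expect_equal(grade_severity(ref_with_counts(list(HARD_EXUDATE = 2L)), tab)$grade, 2L)
  expect_gte(grade_severity(ref_with_counts(list(HEMORRHAGE = 20L)), tab)$grade, 3L)
  expect_equal(grade_severity(ref_with_counts(list(HEMORRHAGE = 2L, SOFT_EXUDATE = 1L)),
                              tab)$grade, 3L)
  expect_equal(grade_severity(ref_with_counts(list()), tab, proliferative = TRUE)$grade, 4L)
  expect_equal(grade_severity(ref_with_counts(list(HEMORRHAGE = 40L, SOFT_EXUDATE = 5L)),
                              tab)$grade, 4L)
  # determinism
  r <- ref_with_counts(list(MICROANEURYSM = 2L, HEMORRHAGE = 1L))
  expect_identical(grade_severity(r, tab), grade_severity(r, tab))
  expect_error(grade_severity(annotation_set("x", image_grid(5, 5), "MARKED"), tab),
               class = "funduseval_input_error")
})

test_that("grade 0 exactly characterizes the lesion-free, non-proliferative eye", {
  tab <- default_grading_rules()
  for (p in PATHOLOGY_CLASSES) {
    cl <- list(1L); names(cl) <- p
    expect_gt(grade_severity(ref_with_counts(cl), tab)$grade, 0L)
  }
  expect_equal(grade_severity(ref_with_counts(list()), tab)$grade, 0L)
})

test_that("reachable grades are enumerated exhaustively", {
  expect_equal(enumerate_reachable_grades(default_grading_rules(), 40L), 0:4)
  base_only <- grading_rule_table(list(), default_grade = 0L)
  expect_equal(enumerate_reachable_grades(base_only, 5L), 0L)
  # caps below a rule's threshold make its grade unreachable
  high <- grading_rule_table(list(list(grade = 2L, min_counts = list(HEMORRHAGE = 5L))))
  expect_equal(enumerate_reachable_grades(high, 3L), 0L)
  expect_equal(enumerate_reachable_grades(high, 5L), c(0L, 2L))
  expect_error(enumerate_reachable_grades(default_grading_rules(), 0L),
               class = "funduseval_input_error")
})

test_that("the default table is monotone in every lesion count", {
  tab <- default_grading_rules()
  cap <- 6L
  grid_counts <- expand.grid(MICROANEURYSM = 0:cap, HEMORRHAGE = 0:cap,
                             SOFT_EXUDATE = 0:cap, HARD_EXUDATE = 0:cap)
  g_of <- function(cnt, flag) funduseval:::eval_rules(tab, cnt, flag)$grade
  for (flag in c(FALSE, TRUE)) {
    g0 <- apply(grid_counts, 1, function(row) g_of(as.list(row), flag))
    for (p in PATHOLOGY_CLASSES) {
      bumped <- grid_counts
      bumped[[p]] <- bumped[[p]] + 1L
      g1 <- apply(bumped, 1, function(row) g_of(as.list(row), flag))
      expect_true(all(g1 >= g0))
    }
    # the flag itself never lowers a grade
    g_flag <- apply(grid_counts, 1, function(row) g_of(as.list(row), TRUE))
    expect_true(all(g_flag >= g0))
  }
})

test_that("rule tables are validated on construction and on load", {
  expect_error(grading_rule_table(list(list(grade = 5L, min_counts = list(HEMORRHAGE = 1L)))),
               class = "funduseval_config_error")
  expect_error(grading_rule_table(list(list(min_counts = list(HEMORRHAGE = 1L)))),
               class = "funduseval_config_error")
  expect_error(grading_rule_table(list(list(grade = 2L))),
               class = "funduseval_config_error")
  expect_error(grading_rule_table(list(
    list(grade = 1L, min_counts = list(MICROANEURYSM = 1L)),
    list(grade = 3L, min_counts = list(HEMORRHAGE = 1L)))),
    class = "funduseval_config_error")   # must be ordered, first match wins
  expect_error(grading_rule_table(list(list(grade = 2L, min_counts = list(CYST = 1L)))),
               class = "funduseval_config_error")

  f <- tempfile(fileext = ".json")
  write_rule_table(default_grading_rules(), f)
  tab2 <- read_rule_table(f)
  expect_equal(enumerate_reachable_grades(tab2, 40L), 0:4)
  expect_equal(grade_severity(ref_with_counts(list(HEMORRHAGE = 25L)), tab2)$grade, 3L)
  writeLines('{"not_rules": []}', f)
  expect_error(read_rule_table(f), class = "funduseval_config_error")
})
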