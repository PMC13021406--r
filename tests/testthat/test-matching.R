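test_that("iou matches hand-counted pixel arithmetic", {
  a <- rect_lesion(2, 2, 2, 2, 10, 10)
  expect_equal(iou(a, a), 1)
  b <- rect_lesion(6, 6, 2, 2, 10, 10)
  expect_equal(iou(a, b), 0)
  # two 2x2 blocks sharing a 1x2 strip: intersection 2, union 6
  c_ <- rect_lesion(3, 2, 2, 2, 10, 10)
  expect_equal(iou(a, c_), 1 / 3)
  expect_equal(iou(c_, a), iou(a, c_))
  expect_error(iou(integer(0), integer(0)), class = "funduseval_input_error")
})

test_that("shifted strips realize the analytic IOU (30 - s) / (30 + s)", {
  strip <- function(shift) {
    one_lesion(rep(1L, 30), (0:29) + shift, 3, 70)
  }
  for (s in c(0L, 5L, 10L, 15L, 30L)) {
    expect_equal(iou(strip(0), strip(s)), (30 - s) / (30 + s))
  }
  # boundary inclusive: shift 10 gives exactly 0.5 and is classified correct
  e10 <- match_pathology(list(strip(0)), list(strip(10)))
  expect_length(e10$correct_pairs, 1)
  expect_equal(e10$correct_pairs[[1]]$iou, 0.5)
  e11 <- match_pathology(list(strip(0)), list(strip(11)))
  expect_length(e11$correct_pairs, 0)
  expect_equal(e11$false_marked, 1L)
  expect_equal(e11$missed_detected, 1L)
})

test_that("greedy assignment is deterministic and threshold-gated", {
  h <- 20L; w <- 40L
  # identity: one pair at IOU 1
  d <- rect_lesion(5, 5, 3, 10, h, w)
  e <- match_pathology(list(d), list(d))
  expect_equal(entry_counts(e), c(correct = 1, false = 0, missed = 0))

  # two detected lesions over one marked lesion: the first in canonical
  # order (larger area) wins the pair
  marked <- rect_lesion(5, 5, 2, 12, h, w)       # area 24
  d_big <- rect_lesion(5, 5, 2, 14, h, w)        # iou 24/28 >= 0.5
  d_small <- rect_lesion(5, 5, 2, 13, h, w)      # iou 24/26 >= 0.5
  e2 <- match_pathology(list(d_big, d_small), list(marked))
  expect_equal(e2$correct_pairs[[1]]$detected_index, 1L)
  expect_equal(e2$missed_detected, 2L)

  # sub-threshold overlap does not consume the marked lesion: a weakly
  # overlapping detected lesion (visited first) must leave it available
  m_strip <- one_lesion(rep(5L, 30), 0:29, 20, 40)      # area 30
  d_weak <- rect_lesion(5, 0, 2, 20, 20, 40)            # iou 20/50 = 0.4
  d_copy <- m_strip                                     # area 30 < 40
  e3 <- match_pathology(list(d_weak, d_copy), list(m_strip))
  expect_length(e3$correct_pairs, 1)
  expect_equal(e3$correct_pairs[[1]]$detected_index, 2L)
  expect_equal(e3$correct_pairs[[1]]$iou, 1)
  expect_equal(e3$missed_detected, 1L)
  expect_length(e3$false_marked, 0)

  expect_error(match_pathology(list(d), list(rect_lesion(1, 1, 2, 2, 10, 10))),
               class = "funduseval_input_error")  # grids differ
})

test_that("match_all stays within pathology and validates its inputs", {
  g <- image_grid(20, 20)
  he <- rect_lesion(3, 3, 4, 4, 20, 20, "HARD_EXUDATE")
  hm <- rect_lesion(3, 3, 4, 4, 20, 20, "HEMORRHAGE")
  ref <- annotation_set("img1", g, "REFERENCE", list(HARD_EXUDATE = list(he)))
  mk <- annotation_set("img1", g, "MARKED", list(HEMORRHAGE = list(hm)))
  res <- match_all(ref, mk)
  expect_equal(res$pathologies$HARD_EXUDATE$missed_detected, 1L)
  expect_equal(res$pathologies$HEMORRHAGE$false_marked, 1L)
  expect_length(res$pathologies$HARD_EXUDATE$correct_pairs, 0)

  empty_ref <- annotation_set("img1", g, "REFERENCE")
  empty_mk <- annotation_set("img1", g, "MARKED")
  res0 <- match_all(empty_ref, empty_mk)
  for (p in PATHOLOGY_CLASSES) {
    expect_equal(entry_counts(res0$pathologies[[p]]),
                 c(correct = 0, false = 0, missed = 0))
  }

  expect_error(match_all(ref, annotation_set("img2", g, "MARKED")),
               class = "funduseval_input_error")
  expect_error(match_all(mk, mk), class = "funduseval_input_error")
  expect_error(match_all(ref, annotation_set("img1", image_grid(10, 10), "MARKED")),
               class = "funduseval_input_error")
})

test_that("optimal oracle enumerates assignments correctly on small cases", {
  d1 <- rect_lesion(2, 2, 2, 2, 15, 15)
  d2 <- rect_lesion(10, 10, 2, 2, 15, 15)
  e0 <- optimal_match_oracle(list(d1), list(d2), 0.5)
  expect_equal(entry_counts(e0), c(correct = 0, false = 1, missed = 1))

  ident <- lapply(c(0, 5, 10), function(o) rect_lesion(2 + o, 2, 2, 2, 20, 20))
  ei <- optimal_match_oracle(ident, ident, 0.5)
  expect_equal(entry_counts(ei), c(correct = 3, false = 0, missed = 0))

  # 2 detected / 1 marked overlap case: oracle finds exactly 1 pair
  marked <- rect_lesion(5, 5, 2, 12, 20, 40)
  eb <- optimal_match_oracle(list(rect_lesion(5, 5, 2, 14, 20, 40),
                                  rect_lesion(5, 5, 2, 13, 20, 40)),
                             list(marked), 0.5)
  expect_length(eb$correct_pairs, 1)

  too_many <- lapply(1:8, function(i) rect_lesion(i, 1, 1, 1, 20, 20))
  expect_error(optimal_match_oracle(too_many, list(d1)),
               class = "funduseval_input_error")
})

test_that("greedy respects conservation, monotonicity and the oracle bound", {
  thresholds <- c(0, 0.25, 0.5, 0.75, 1)
  for (seed in 1:60) {
    inst <- random_instance(seed)
    prev_correct <- Inf
    for (th in thresholds) {
      e <- match_pathology(inst$detected, inst$marked, match_config(th))
      cm <- entry_counts(e)
      # partition/conservation and one-to-one pairing
      expect_equal(cm[["correct"]] + cm[["false"]], length(inst$marked))
      expect_equal(cm[["correct"]] + cm[["missed"]], length(inst$detected))
      mi <- vapply(e$correct_pairs, function(p) p$marked_index, integer(1))
      di <- vapply(e$correct_pairs, function(p) p$detected_index, integer(1))
      expect_false(anyDuplicated(mi) > 0 || anyDuplicated(di) > 0)
      expect_true(all(vapply(e$correct_pairs, function(p) p$iou, numeric(1)) >= th))
      # raising the threshold never gains pairs (thresholds ascend)
      expect_lte(cm[["correct"]], prev_correct)
      prev_correct <- cm[["correct"]]
    }
    eg <- match_pathology(inst$detected, inst$marked, match_config(0.5))
    eo <- optimal_match_oracle(inst$detected, inst$marked, 0.5)
    expect_lte(length(eg$correct_pairs), length(eo$correct_pairs))
    if (one_to_one_overlaps(inst$detected, inst$marked)) {
      expect_equal(length(eg$correct_pairs), length(eo$correct_pairs))
    }
  }
})
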