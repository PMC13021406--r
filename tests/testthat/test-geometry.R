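test_that("rasterize_contours draws points, segments and closed outlines", {
  g <- image_grid(5, 5)

  expect_equal(sum(rasterize_contours(list(), g)), 0)

  m <- rasterize_contours(list(rbind(c(2, 2))), g)
  expect_equal(sum(m), 1)
  expect_equal(m[3, 3], 1L)

  # closed square outline: 8 boundary pixels, interior stays empty
  sq <- rasterize_contours(list(rbind(c(1, 1), c(1, 3), c(3, 3), c(3, 1))), g)
  expect_equal(sum(sq), 8)
  expect_equal(sq[3, 3], 0L)
  expect_true(all(sq[2:4, 2] == 1L) && all(sq[2:4, 4] == 1L))
  expect_true(all(sq[2, 2:4] == 1L) && all(sq[4, 2:4] == 1L))

  # two-vertex contours are open segments; endpoints always covered
  seg <- rasterize_contours(list(rbind(c(0, 0), c(4, 3))), g)
  expect_equal(seg[1, 1], 1L)
  expect_equal(seg[5, 4], 1L)

  expect_error(rasterize_contours(list(rbind(c(0, 5))), g),
               class = "funduseval_input_error")
  expect_error(rasterize_contours(list(rbind(c(1, 1)), rbind(c(-1, 0))), g),
               regexp = "contour 2")
})

test_that("close_and_fill seals outlines and matches the brute-force oracle", {
  g <- image_grid(5, 5)
  expect_equal(close_and_fill(matrix(0L, 5, 5)), matrix(0L, 5, 5))

  # hole filling alone (radius 0) recovers the square interior
  sq <- rasterize_contours(list(rbind(c(1, 1), c(1, 3), c(3, 3), c(3, 1))), g)
  filled <- close_and_fill(sq, morphology_config(dilation_radius = 0))
  expect_equal(filled[3, 3], 1L)
  expect_equal(sum(filled), 9)

  # solid block, radius-1 disk: agree with per-pixel morphology oracle
  blk <- matrix(0L, 9, 9); blk[4:6, 4:6] <- 1L
  expect_equal(close_and_fill(blk, morphology_config(1, structuring_element = "disk")),
               brute_close_and_fill(blk, 1, "disk"))

  # seeded random masks, both elements and radii 0..2
  set.seed(11)
  for (k in 1:12) {
    m <- matrix(rbinom(15 * 15, 1, 0.25), 15, 15)
    el <- sample(c("disk", "square"), 1)
    r <- sample(0:2, 1)
    got <- close_and_fill(m, morphology_config(r, structuring_element = el))
    expect_equal(got, brute_close_and_fill(m, r, el))
    # extensive, and hole-free: all remaining background touches the border flood
    expect_true(all(got >= m))
    reach <- brute_border_flood(got)
    expect_true(all(got[!reach] == 1L))
    # re-applying with radius 0 changes nothing
    expect_equal(close_and_fill(got, morphology_config(0)), got)
  }
})

test_that("morphology agrees with EBImage on interior shapes", {
  # independent cross-check: square-element dilation against EBImage's box
  # brush, and hole filling against fillHull (masks kept away from the
  # border so brush border conventions cannot differ)
  set.seed(21)
  for (k in 1:6) {
    m <- matrix(0L, 20, 20)
    m[5:16, 5:16] <- rbinom(144, 1, 0.3)
    d_pkg <- close_and_fill(m, morphology_config(1, structuring_element = "square"))
    d_ebi <- EBImage::fillHull(EBImage::erode(
      EBImage::dilate(EBImage::dilate(m, EBImage::makeBrush(3, "box")),
                      EBImage::makeBrush(3, "box")),
      EBImage::makeBrush(3, "box")))
    expect_equal(d_pkg, matrix(as.integer(d_ebi), 20, 20))
  }
})

test_that("extract_lesions splits components under the configured connectivity", {
  expect_equal(extract_lesions(matrix(0L, 4, 4), "HEMORRHAGE"), list())

  m <- matrix(0L, 8, 8)
  m[2:3, 2:3] <- 1L
  m[6:7, 5:6] <- 1L
  ls <- extract_lesions(m, "HARD_EXUDATE")
  expect_length(ls, 2)
  expect_equal(vapply(ls, function(l) l$area, integer(1)), c(4L, 4L))
  expect_true(all(vapply(ls, function(l) l$pathology, character(1)) == "HARD_EXUDATE"))

  diagm <- matrix(0L, 5, 5)
  diagm[cbind(2:3, 2:3)] <- 1L
  expect_length(extract_lesions(diagm, "MICROANEURYSM", morphology_config(connectivity = 8)), 1)
  expect_length(extract_lesions(diagm, "MICROANEURYSM", morphology_config(connectivity = 4)), 2)
  # 4-connected labeling cross-check: EBImage::bwlabel is 4-connected
  set.seed(31)
  for (k in 1:5) {
    rm_ <- matrix(rbinom(12 * 12, 1, 0.3), 12, 12)
    expect_length(extract_lesions(rm_, "MICROANEURYSM", morphology_config(connectivity = 4)),
                  max(EBImage::bwlabel(rm_)))
  }

  expect_error(extract_lesions(m, "CYST"), class = "funduseval_input_error")
})

test_that("lesions are canonically ordered and carry consistent metadata", {
  m <- matrix(0L, 10, 10)
  m[2, 2] <- 1L               # area 1
  m[5:7, 5:7] <- 1L           # area 9
  ls <- extract_lesions(m, "HEMORRHAGE")
  expect_equal(vapply(ls, function(l) l$area, integer(1)), c(9L, 1L))
  expect_equal(unname(ls[[1]]$bbox), c(4L, 4L, 6L, 6L))
  expect_equal(unname(ls[[1]]$centroid), c(5, 5))
  expect_equal(ls[[2]]$area, nrow(ls[[2]]$pixels))

  # equal areas: tie broken by top-left corner
  m2 <- matrix(0L, 10, 10)
  m2[8, 8] <- 1L; m2[2, 5] <- 1L; m2[2, 3] <- 1L
  ls2 <- extract_lesions(m2, "MICROANEURYSM")
  tl <- t(vapply(ls2, function(l) l$bbox[c("min_row", "min_col")], integer(2)))
  expect_equal(tl, rbind(c(1L, 2L), c(1L, 4L), c(7L, 7L)), ignore_attr = TRUE)
})

test_that("rasterize-fill-extract recovers one lesion containing the interior", {
  # convex toy contours on grids up to 50 x 50, checked against the
  # border-flood oracle
  polys <- list(
    list(g = c(20, 20), v = rbind(c(3, 3), c(3, 14), c(14, 14), c(14, 3))),
    list(g = c(50, 50), v = rbind(c(5, 25), c(25, 45), c(45, 25), c(25, 5))),
    list(g = c(30, 40), v = rbind(c(4, 6), c(4, 30), c(20, 36), c(25, 18), c(15, 4)))
  )
  for (pl in polys) {
    g <- image_grid(pl$g[1], pl$g[2])
    outline <- rasterize_contours(list(pl$v), g)
    filled <- close_and_fill(outline, morphology_config())
    ls <- extract_lesions(filled, "SOFT_EXUDATE")
    expect_length(ls, 1)
    interior <- brute_fill_holes(outline) - outline
    in_px <- which(interior == 1L, arr.ind = TRUE) - 1L
    keys <- in_px[, 1] * g$width + in_px[, 2]
    expect_true(all(keys %in% ls[[1]]$keys))
  }
})

test_that("lesion pixel sets round-trip through a painted mask", {
  set.seed(41)
  for (k in 1:5) {
    m <- matrix(rbinom(20 * 20, 1, 0.2), 20, 20)
    ls <- extract_lesions(m, "HEMORRHAGE")
    back <- funduseval:::lesions_to_mask(ls, image_grid(20, 20))
    expect_equal(back, m)
    ls2 <- extract_lesions(back, "HEMORRHAGE")
    expect_equal(lapply(ls2, `[[`, "keys"), lapply(ls, `[[`, "keys"))
  }
})
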