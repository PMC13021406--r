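# Greedy IOU matching of learner-marked lesions against reference
# (detector) lesions, strictly within each pathology class.

#' Matching configuration
#'
#' @param iou_threshold Minimum intersection-over-union for a marked lesion
#'   to count as correct (default 0.5, boundary inclusive).
#' @param detected_order Iteration order over reference lesions; only
#'   `"canonical"` (descending area, then top-left corner) is provided —
#'   it makes the greedy assignment deterministic.
#' @param tie_break Policy when two marked lesions reach the same maximal
#'   IOU; `"lowest_index"` picks the earlier lesion in canonical order.
#' @return A `match_config` object.
#' @export
match_config <- function(iou_threshold = 0.5,
                         detected_order = "canonical",
                         tie_break = "lowest_index") {
  if (!(is.numeric(iou_threshold) && length(iou_threshold) == 1L &&
        !is.na(iou_threshold) && iou_threshold >= 0 && iou_threshold <= 1)) {
    abort_config("iou_threshold must be a single number in [0, 1]")
  }
  detected_order <- match.arg(detected_order, "canonical")
  tie_break <- match.arg(tie_break, "lowest_index")
  structure(list(iou_threshold = as.numeric(iou_threshold),
                 detected_order = detected_order, tie_break = tie_break),
            class = "match_config")
}

#' Intersection over union of two lesions (or pixel-key sets)
#'
#' `|A n B| / |A u B|`: 1 for identical pixel sets, 0 for disjoint ones.
#' Both-empty input is rejected (the ratio is undefined).
#'
#' @param a,b `lesion` objects, or integer vectors of pixel keys
#'   (`row * width + col`).
#' @return IOU ratio in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ka <- if (inherits(a, "lesion")) a$keys else as.integer(a)
  kb <- if (inherits(b, "lesion")) b$keys else as.integer(b)
  if (inherits(a, "lesion") && inherits(b, "lesion") &&
      !identical(a$grid, b$grid)) {
    abort_input("iou: lesions come from different grids")
  }
  if (!length(ka) && !length(kb)) {
    abort_input("iou is undefined for two empty pixel sets")
  }
  ni <- length(intersect(ka, kb))
  ni / (length(ka) + length(kb) - ni)
}

check_same_pathology_grid <- function(detected, marked) {
  all_l <- c(detected, marked)
  if (!length(all_l)) return(invisible(NULL))
  p0 <- all_l[[1]]$pathology; g0 <- all_l[[1]]$grid
  for (l in all_l) {
    if (!identical(l$pathology, p0)) {
      abort_input("matching requires a single pathology (got %s and %s)",
                  p0, l$pathology)
    }
    if (!identical(l$grid, g0)) abort_input("matching requires a single grid")
  }
  invisible(NULL)
}

new_match_entry <- function(correct_pairs, false_marked, missed_detected) {
  list(correct_pairs = correct_pairs,
       false_marked = as.integer(false_marked),
       missed_detected = as.integer(missed_detected))
}

#' Match marked lesions to detected lesions of one pathology
#'
#' The greedy assignment used to produce feedback: reference (detected)
#' lesions are visited in canonical order; each computes its IOU against all
#' still-unassigned marked lesions and takes the maximum. If that maximum
#' reaches the threshold the pair is recorded as correct and the marked
#' lesion is removed from the pool; otherwise the marked lesion stays
#' available for later detected lesions. Afterwards, unassigned marked
#' lesions are falsely input and unpaired detected lesions are missed.
#'
#' @param detected,marked Lists of lesions of one pathology on one grid;
#'   `detected` must already be in canonical order (as produced by
#'   [extract_lesions()] / [annotation_set()]).
#' @param cfg A [match_config()].
#' @return List with `correct_pairs` (each `detected_index`, `marked_index`,
#'   `iou`), `false_marked` and `missed_detected` index vectors. Indices are
#'   1-based positions in the input lists.
#' @export
match_pathology <- function(detected, marked, cfg = match_config()) {
  check_same_pathology_grid(detected, marked)
  nd <- length(detected); nm <- length(marked)
  available <- rep(TRUE, nm)
  pairs <- list()
  for (i in seq_len(nd)) {
    cand <- which(available)
    if (!length(cand)) break
    sc <- vapply(cand, function(j) iou(detected[[i]], marked[[j]]), numeric(1))
    best <- which.max(sc)   # ties: lowest canonical index wins
    if (sc[best] >= cfg$iou_threshold) {
      j <- cand[best]
      pairs[[length(pairs) + 1L]] <-
        list(detected_index = i, marked_index = j, iou = sc[best])
      available[j] <- FALSE
    }
  }
  paired_d <- vapply(pairs, function(p) p$detected_index, integer(1))
  new_match_entry(pairs,
                  false_marked = which(available),
                  missed_detected = setdiff(seq_len(nd), paired_d))
}

#' Match a learner annotation set against a reference set
#'
#' Applies [match_pathology()] independently to each of the four pathology
#' classes; lesions never match across classes.
#'
#' @param reference Annotation set with `source = "REFERENCE"`.
#' @param marked Annotation set with `source = "MARKED"`, same image and grid.
#' @param cfg A [match_config()].
#' @return A `match_result`: per-pathology list of match entries, plus the
#'   image id and config echo.
#' @export
match_all <- function(reference, marked, cfg = match_config()) {
  if (!inherits(reference, "annotation_set") || !inherits(marked, "annotation_set")) {
    abort_input("match_all expects two annotation sets")
  }
  if (reference$source != "REFERENCE" || marked$source != "MARKED") {
    abort_input("match_all expects (REFERENCE, MARKED) sources, got (%s, %s)",
                reference$source, marked$source)
  }
  if (!identical(reference$image_id, marked$image_id)) {
    abort_input("image_id mismatch: '%s' vs '%s'",
                reference$image_id, marked$image_id)
  }
  if (!identical(unclass(reference$grid), unclass(marked$grid))) {
    abort_input("grid mismatch between reference and marked annotation sets")
  }
  per <- lapply(PATHOLOGY_CLASSES, function(p) {
    match_pathology(reference$lesions[[p]], marked$lesions[[p]], cfg)
  })
  names(per) <- PATHOLOGY_CLASSES
  structure(list(image_id = reference$image_id, config = cfg,
                 pathologies = per),
            class = "match_result")
}

#' Exhaustive optimal matching (test oracle)
#'
#' Enumerates one-to-one assignments of marked to detected lesions via
#' dynamic programming over subsets of marked lesions, and returns an
#' assignment maximizing the number of pairs with IOU at or above the
#' threshold (ties broken by total IOU, then by canonical order). Intended
#' as an independent check on the greedy production path; limited to seven
#' lesions per side.
#'
#' @param detected,marked Lists of lesions (at most 7 each).
#' @param threshold IOU threshold.
#' @return Same structure as [match_pathology()].
#' @export
optimal_match_oracle <- function(detected, marked, threshold = 0.5) {
  nd <- length(detected); nm <- length(marked)
  if (nd > 7L || nm > 7L) {
    abort_input("optimal_match_oracle handles at most 7 lesions per side")
  }
  check_same_pathology_grid(detected, marked)
  sc <- matrix(0, nd, nm)
  for (i in seq_len(nd)) for (j in seq_len(nm)) {
    sc[i, j] <- iou(detected[[i]], marked[[j]])
  }
  # dp over detected index x bitmask of used marked lesions;
  # value = (pair count, total IOU), choice recorded for reconstruction
  nstate <- bitwShiftL(1L, nm)
  cnt <- matrix(0L, nd + 1L, nstate)
  tot <- matrix(0, nd + 1L, nstate)
  choice <- matrix(0L, nd + 1L, nstate)   # 0 = skip, j = pair with marked j
  for (i in rev(seq_len(nd))) {
    for (s in 0:(nstate - 1L)) {
      bc <- cnt[i + 1L, s + 1L]; bt <- tot[i + 1L, s + 1L]; ch <- 0L
      for (j in seq_len(nm)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) == 0L && sc[i, j] >= threshold) {
          c2 <- cnt[i + 1L, bitwOr(s, bit) + 1L] + 1L
          t2 <- tot[i + 1L, bitwOr(s, bit) + 1L] + sc[i, j]
          if (c2 > bc || (c2 == bc && t2 > bt + 1e-12)) {
            bc <- c2; bt <- t2; ch <- j
          }
        }
      }
      cnt[i, s + 1L] <- bc; tot[i, s + 1L] <- bt; choice[i, s + 1L] <- ch
    }
  }
  pairs <- list(); s <- 0L
  for (i in seq_len(nd)) {
    j <- choice[i, s + 1L]
    if (j > 0L) {
      pairs[[length(pairs) + 1L]] <-
        list(detected_index = i, marked_index = j, iou = sc[i, j])
      s <- bitwOr(s, bitwShiftL(1L, j - 1L))
    }
  }
  paired_d <- vapply(pairs, function(p) p$detected_index, integer(1))
  paired_m <- vapply(pairs, function(p) p$marked_index, integer(1))
  new_match_entry(pairs,
                  false_marked = setdiff(seq_len(nm), paired_m),
                  missed_detected = setdiff(seq_len(nd), paired_d))
}
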