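# Feedback aggregation: per-pathology counts, percent-found, and the
# color-coded lesion lists behind the ALL / CORRECT / MISSED / FALSE views.

lesion_ref <- function(lesion, source, index, color, iou = NULL,
                       paired_index = NULL) {
  out <- list(source = source, index = index,
              area = lesion$area,
              bbox = as.list(lesion$bbox),
              centroid = as.list(lesion$centroid),
              color = color)
  if (!is.null(iou)) out$iou <- iou
  if (!is.null(paired_index)) out$paired_index <- paired_index
  out
}

#' Build a feedback report from a match result
#'
#' Mirrors the tool's feedback interface: one entry per pathology with
#' counts, the percentage of reference lesions found correctly, and the
#' categorized lesion lists (correct lesions green, falsely input yellow,
#' missed red). The percentage uses the reference-lesion denominator
#' (`100 * n_correct / n_reference`); when the reference contains no lesion
#' of a pathology there was nothing to find and the percentage is 100,
#' with any false marks still counted and listed.
#'
#' @param match A `match_result` from [match_all()].
#' @param reference,marked The annotation sets the match was produced from.
#' @return A `feedback_report` object.
#' @export
build_report <- function(match, reference, marked) {
  if (!inherits(match, "match_result")) {
    abort_input("build_report expects a match_result")
  }
  per <- lapply(PATHOLOGY_CLASSES, function(p) {
    entry <- match$pathologies[[p]]
    det <- reference$lesions[[p]]
    mar <- marked$lesions[[p]]
    nd <- length(det); nm <- length(mar)
    idx_d <- vapply(entry$correct_pairs, function(q) q$detected_index, integer(1))
    idx_m <- vapply(entry$correct_pairs, function(q) q$marked_index, integer(1))
    if (any(idx_d > nd) || any(idx_m > nm) ||
        any(entry$false_marked > nm) || any(entry$missed_detected > nd)) {
      abort_internal("match result indices out of range for pathology %s", p)
    }
    correct <- lapply(seq_along(entry$correct_pairs), function(k) {
      q <- entry$correct_pairs[[k]]
      lesion_ref(mar[[q$marked_index]], "MARKED", q$marked_index, "green",
                 iou = q$iou, paired_index = q$detected_index)
    })
    false_ <- lapply(entry$false_marked, function(j) {
      lesion_ref(mar[[j]], "MARKED", j, "yellow")
    })
    missed <- lapply(entry$missed_detected, function(i) {
      lesion_ref(det[[i]], "REFERENCE", i, "red")
    })
    n_correct <- length(correct)
    pct <- if (nd > 0L) 100 * n_correct / nd else 100
    list(pathology = p,
         n_reference = nd, n_marked = nm,
         n_correct = n_correct,
         n_false = length(false_), n_missed = length(missed),
         percent_found = pct,
         lesion_lists = list(ALL = c(correct, missed, false_),
                             CORRECT = correct, MISSED = missed,
                             `FALSE` = false_))
  })
  names(per) <- PATHOLOGY_CLASSES
  structure(list(image_id = match$image_id,
                 config = list(matching = unclass(match$config)),
                 pathologies = per),
            class = "feedback_report")
}

#' Retrieve one detail view of a feedback report
#'
#' @param report A `feedback_report`.
#' @param pathology One of [PATHOLOGY_CLASSES].
#' @param category One of [FEEDBACK_CATEGORIES]; `ALL` is the union of the
#'   other three.
#' @return List of lesion references with display colors.
#' @export
filter_view <- function(report, pathology, category = "ALL") {
  check_pathology(pathology)
  if (!(length(category) == 1L && category %in% FEEDBACK_CATEGORIES)) {
    abort_input("category must be one of %s",
                paste(FEEDBACK_CATEGORIES, collapse = ", "))
  }
  report$pathologies[[pathology]]$lesion_lists[[category]]
}

#' @export
print.feedback_report <- function(x, ...) {
  cat(sprintf("<feedback_report '%s'>\n", x$image_id))
  for (p in PATHOLOGY_CLASSES) {
    e <- x$pathologies[[p]]
    cat(sprintf("  %-14s found %5.1f%%  (ref %d, marked %d: %d correct, %d false, %d missed)\n",
                p, e$percent_found, e$n_reference, e$n_marked,
                e$n_correct, e$n_false, e$n_missed))
  }
  invisible(x)
}

#' Flatten a feedback report to one row per pathology
#'
#' @param report A `feedback_report`.
#' @return A data.frame with columns image_id, pathology, n_reference,
#'   n_marked, n_correct, n_false, n_missed, percent_found.
#' @export
report_to_table <- function(report) {
  rows <- lapply(PATHOLOGY_CLASSES, function(p) {
    e <- report$pathologies[[p]]
    data.frame(image_id = report$image_id, pathology = p,
               n_reference = e$n_reference, n_marked = e$n_marked,
               n_correct = e$n_correct, n_false = e$n_false,
               n_missed = e$n_missed, percent_found = e$percent_found,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
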