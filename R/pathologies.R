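#' The four diabetic-retinopathy pathology classes
#'
#' Lesions are annotated and matched strictly within one of four pathology
#' classes: microaneurysms (the smallest, earliest lesions), hemorrhages,
#' soft exudates (cotton-wool spots) and hard exudates. The serialization
#' names are stable and appear verbatim in annotation and report files.
#'
#' @format Character vector of length 4.
#' @export
PATHOLOGY_CLASSES <- c("MICROANEURYSM", "HEMORRHAGE", "SOFT_EXUDATE", "HARD_EXUDATE")

#' Feedback display categories
#'
#' Detail views of a feedback report: `ALL`, `CORRECT` (green), `MISSED`
#' (red), `FALSE` (yellow).
#'
#' @format Character vector of length 4.
#' @export
FEEDBACK_CATEGORIES <- c("ALL", "CORRECT", "MISSED", "FALSE")

#' Display colors of the feedback categories
#' @format Named character vector mapping CORRECT/FALSE/MISSED to colors.
#' @export
CATEGORY_COLORS <- c(CORRECT = "green", FALSE. = "yellow", MISSED = "red")
names(CATEGORY_COLORS) <- c("CORRECT", "FALSE", "MISSED")

check_pathology <- function(pathology) {
  if (!(is.character(pathology) && length(pathology) == 1L &&
        pathology %in% PATHOLOGY_CLASSES)) {
    abort_input("unknown pathology class '%s' (must be one of %s)",
                paste(pathology, collapse = ","),
                paste(PATHOLOGY_CLASSES, collapse = ", "))
  }
  pathology
}
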