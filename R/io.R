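# File formats: annotation JSON (contours and/or mask files), 8-bit
# PNG/TIFF binary masks, report JSON/CSV. All payloads are deterministic —
# identical inputs and config produce byte-identical files (timestamps, if
# any, belong in logs, never in payloads).

#' Read a binary lesion mask from PNG or TIFF
#'
#' 8-bit single-channel convention: 0 = background, any nonzero = lesion.
#' Multi-channel images use the first channel.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Binary integer mask (H x W).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort_input("mask file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort_input("unsupported mask format '%s' (use png/tif/tiff): %s", ext, path))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask <- matrix(as.integer(img != 0), nrow(img), ncol(img))
  mask
}

#' Write a binary lesion mask to PNG or TIFF
#'
#' @param mask Binary mask.
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  img <- matrix(as.numeric(mask != 0L), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    abort_input("unsupported mask format '%s' (use png/tif/tiff): %s", ext, path))
  invisible(path)
}

#' Read an annotation file into an annotation set
#'
#' The annotation JSON holds, per pathology class, a list of lesion records,
#' each either `{"contour": [[row, col], ...]}` (0-based pixel coordinates)
#' or `{"mask_file": "relative/path.png"}`. Contour records of a pathology
#' are rasterized together and sealed with [close_and_fill()] (so freehand
#' strokes with small gaps become filled shapes); mask files are loaded
#' as-is. The union is split into lesions by connected components in
#' canonical order.
#'
#' @param path Path to the annotation JSON; `mask_file` entries resolve
#'   relative to its directory.
#' @param cfg A [morphology_config()].
#' @return An `annotation_set`.
#' @export
read_annotation <- function(path, cfg = morphology_config()) {
  if (!file.exists(path)) abort_input("annotation file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) abort_input("cannot parse %s: %s", path,
                                                  conditionMessage(e)))
  for (f in c("image_id", "height", "width", "source", "pathologies")) {
    if (is.null(doc[[f]])) abort_input("%s: missing field '%s'", path, f)
  }
  if (!(doc$source %in% c("reference", "marked"))) {
    abort_input("%s: source must be 'reference' or 'marked' (got '%s')",
                path, doc$source)
  }
  grid <- image_grid(doc$height, doc$width)
  missing_p <- setdiff(PATHOLOGY_CLASSES, names(doc$pathologies))
  if (length(missing_p)) {
    abort_input("%s: /pathologies lacks class '%s'", path, missing_p[1])
  }
  base <- dirname(path)
  lesions <- stats::setNames(lapply(PATHOLOGY_CLASSES, function(p) {
    recs <- doc$pathologies[[p]]
    contours <- list()
    mask <- empty_mask(grid)
    for (k in seq_along(recs)) {
      rec <- recs[[k]]
      if (!is.null(rec$contour)) {
        v <- tryCatch(do.call(rbind, lapply(rec$contour, function(pt) {
          as.integer(unlist(pt)[1:2])
        })), warning = function(w) NULL, error = function(e) NULL)
        if (is.null(v) || anyNA(v)) {
          abort_input("%s: /pathologies/%s/%d/contour is malformed", path, p, k - 1L)
        }
        contours[[length(contours) + 1L]] <- v
      } else if (!is.null(rec$mask_file)) {
        mp <- file.path(base, rec$mask_file)
        m <- read_mask(mp)
        if (!identical(dim(m), c(grid$height, grid$width))) {
          abort_input("%s: mask %s is %dx%d, annotation grid is %dx%d",
                      path, mp, nrow(m), ncol(m), grid$height, grid$width)
        }
        mask <- mask | m
      } else {
        abort_input("%s: /pathologies/%s/%d has neither contour nor mask_file",
                    path, p, k - 1L)
      }
    }
    if (length(contours)) {
      outline <- tryCatch(rasterize_contours(contours, grid),
                          funduseval_input_error = function(e) {
                            abort_input("%s: /pathologies/%s: %s", path, p,
                                        conditionMessage(e))
                          })
      mask <- mask | close_and_fill(outline, cfg)
    }
    storage.mode(mask) <- "integer"
    extract_lesions(mask, p, cfg)
  }), PATHOLOGY_CLASSES)
  annotation_set(doc$image_id, grid,
                 source = if (doc$source == "reference") "REFERENCE" else "MARKED",
                 lesions = lesions)
}

#' Write an annotation set to JSON plus per-pathology mask files
#'
#' Lesion pixel sets are written as one binary PNG per non-empty pathology
#' (named `<image_id>_<source>_<pathology>.png` next to the JSON) and referenced via
#' `mask_file` records, so that [read_annotation()] recovers the exact
#' pixel sets.
#'
#' @param aset An `annotation_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(aset, path) {
  if (!inherits(aset, "annotation_set")) abort_input("not an annotation_set")
  base <- dirname(path)
  safe_id <- gsub("[^A-Za-z0-9._-]", "_", aset$image_id)
  pathologies <- stats::setNames(lapply(PATHOLOGY_CLASSES, function(p) {
    ls <- aset$lesions[[p]]
    if (!length(ls)) return(list())
    fn <- sprintf("%s_%s_%s.png", safe_id, tolower(aset$source), tolower(p))
    write_mask(lesions_to_mask(ls, aset$grid), file.path(base, fn))
    list(list(mask_file = fn))
  }), PATHOLOGY_CLASSES)
  doc <- list(image_id = aset$image_id,
              height = aset$grid$height, width = aset$grid$width,
              source = tolower(aset$source),
              pathologies = pathologies)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a feedback report to JSON
#'
#' The payload embeds the matching/morphology config echo and is fully
#' deterministic, so identical inputs yield byte-identical files.
#'
#' @param report A `feedback_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "feedback_report")) abort_input("not a feedback_report")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a feedback report written by [write_report()]
#'
#' @param path Report JSON path.
#' @return A `feedback_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort_input("report file not found: %s", path)
  doc <- jsonlite::read_json(path)
  structure(doc, class = "feedback_report")
}

#' Write the flat per-pathology report CSV
#'
#' One row per pathology: image_id, pathology, n_reference, n_marked,
#' n_correct, n_false, n_missed, percent_found.
#'
#' @param report A `feedback_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report_to_table(report), path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic case to disk
#'
#' Writes the reference and marked annotations (JSON + per-pathology PNG
#' masks) and an expected-outcomes JSON for test harnesses.
#'
#' @param case A `synthetic_case` from [simulate_case()] /
#'   [perturb_annotation()].
#' @param dir Output directory (created if needed).
#' @return Named list of the files written, invisibly.
#' @export
write_synthetic_case <- function(case, dir) {
  if (!inherits(case, "synthetic_case")) abort_input("not a synthetic_case")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref_path <- file.path(dir, "reference.json")
  mk_path <- file.path(dir, "marked.json")
  exp_path <- file.path(dir, "expected.json")
  ref <- case$reference
  attr(ref, "blobs") <- NULL; attr(ref, "spec") <- NULL
  mk <- case$marked
  write_annotation(ref, ref_path)
  write_annotation(mk, mk_path)
  jsonlite::write_json(case$expected, exp_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE,
                       dataframe = "columns")
  invisible(list(reference = ref_path, marked = mk_path, expected = exp_path))
}
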