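# Lesion geometry: rasterization of drawn contours, binary-mask morphology
# (dilation + closing + hole filling) and connected-component extraction.
#
# Conventions used throughout the package:
#   * masks are integer H x W matrices with values 0/1; mask[r + 1, c + 1]
#     holds pixel (row = r, col = c)
#   * pixel coordinates are 0-based (row, col), top-left pixel is (0, 0) —
#     this makes mask files and annotation JSON round-trip bit-exactly
#   * lesion pixel sets are also keyed as row * width + col for fast set
#     arithmetic (intersection-over-union)

#' Define an image grid
#'
#' @param height,width Grid dimensions in pixels (each at least 1).
#' @return An `image_grid` object (named list with `height`, `width`).
#' @export
image_grid <- function(height, width) {
  if (!is_count(height, 1L) || !is_count(width, 1L)) {
    abort_input("image grid dimensions must be positive integers (got %s x %s)",
                format(height), format(width))
  }
  structure(list(height = as.integer(height), width = as.integer(width)),
            class = "image_grid")
}

#' Morphology configuration
#'
#' Controls how drawn contours are turned into filled lesions: the contour
#' raster is dilated, morphologically closed (sealing small gaps left by
#' freehand drawing), and hole-filled. Foreground connectivity is used for
#' connected-component extraction; hole filling always floods the background
#' 4-connectedly from the border (the standard duality to 8-connected
#' foreground).
#'
#' @param dilation_radius Radius in pixels of the structuring element
#'   (default 1, the smallest element that bridges 1-px gaps).
#' @param connectivity Foreground pixel adjacency, 4 or 8 (default 8).
#' @param structuring_element `"disk"` (offsets with dy^2+dx^2 <= r^2) or
#'   `"square"` (Chebyshev ball).
#' @return A `morphology_config` object.
#' @export
morphology_config <- function(dilation_radius = 1L, connectivity = 8L,
                              structuring_element = c("disk", "square")) {
  structuring_element <- match.arg(structuring_element)
  if (!is_count(dilation_radius, 0L)) {
    abort_config("dilation_radius must be a non-negative integer")
  }
  if (!(length(connectivity) == 1L && connectivity %in% c(4L, 8L))) {
    abort_config("connectivity must be 4 or 8")
  }
  structure(list(dilation_radius = as.integer(dilation_radius),
                 connectivity = as.integer(connectivity),
                 structuring_element = structuring_element),
            class = "morphology_config")
}

empty_mask <- function(grid) {
  matrix(0L, nrow = grid$height, ncol = grid$width)
}

mask_grid <- function(mask) image_grid(nrow(mask), ncol(mask))

check_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L))) {
    abort_input("a binary mask must be a matrix of 0/1 values")
  }
  mask
}

# Structuring-element offsets as an n x 2 (dr, dc) integer matrix.
struct_offsets <- function(radius, element) {
  d <- seq.int(-radius, radius)
  off <- as.matrix(expand.grid(dr = d, dc = d))
  if (element == "disk") {
    off <- off[off[, 1]^2 + off[, 2]^2 <= radius^2, , drop = FALSE]
  }
  off
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
    off[off[, 1] != 0L | off[, 2] != 0L, , drop = FALSE]
  }
}

# Translate a logical/integer mask by (dr, dc); pixels shifted in from
# outside the grid take the value `pad`.
shift_mask <- function(m, dr, dc, pad = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(pad, h, w)
  if (abs(dr) >= h || abs(dc) >= w) return(out)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

dilate_mask <- function(mask, offsets) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offsets))) {
    out <- out | shift_mask(mask, offsets[i, 1], offsets[i, 2], pad = 0L)
  }
  storage.mode(out) <- "integer"
  out
}

# Erosion treating pixels outside the grid as foreground, so that closing
# (dilation then erosion) never removes original pixels at the border.
erode_mask <- function(mask, offsets) {
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offsets))) {
    out <- out & shift_mask(mask, offsets[i, 1], offsets[i, 2], pad = 1L)
  }
  storage.mode(out) <- "integer"
  out
}

# Set every background region not 4-connected to the grid border.
fill_holes <- function(mask) {
  bg <- mask == 0L
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1L, ] <- bg[1L, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
  reach[, 1L] <- bg[, 1L]; reach[, ncol(mask)] <- bg[, ncol(mask)]
  off <- neighbor_offsets(4L)
  repeat {
    grown <- reach
    for (i in seq_len(nrow(off))) {
      grown <- grown | shift_mask(reach, off[i, 1], off[i, 2], pad = 0L)
    }
    grown <- grown & bg
    if (identical(sum(grown), sum(reach))) break
    reach <- grown
  }
  out <- mask
  out[bg & !reach] <- 1L
  storage.mode(out) <- "integer"
  out
}

#' Rasterize drawn contours onto a binary mask
#'
#' Each contour is an ordered list of 0-based `(row, col)` pixel coordinates,
#' as captured from a drawing canvas. Consecutive vertices are joined by
#' discrete (Bresenham) line segments; contours with three or more vertices
#' are closed by joining the last vertex back to the first. The result is an
#' outline raster: use [close_and_fill()] to obtain filled lesion shapes.
#'
#' @param contours List of contours; each contour an n x 2 integer matrix
#'   (or coercible) of 0-based `(row, col)` coordinates.
#' @param grid An [image_grid()].
#' @return Binary mask with 1 at every vertex and along every segment.
#' @export
rasterize_contours <- function(contours, grid) {
  mask <- empty_mask(grid)
  for (k in seq_along(contours)) {
    v <- contours[[k]]
    if (is.list(v)) v <- do.call(rbind, lapply(v, as.integer))
    v <- matrix(as.integer(v), ncol = 2)
    if (nrow(v) == 0L) {
      abort_input("contour %d is empty", k)
    }
    if (any(v[, 1] < 0L | v[, 1] >= grid$height |
            v[, 2] < 0L | v[, 2] >= grid$width)) {
      abort_input("contour %d has coordinates outside the %d x %d grid",
                  k, grid$height, grid$width)
    }
    n <- nrow(v)
    segs <- if (n == 1L) cbind(1L, 1L)
            else if (n == 2L) cbind(1L, 2L)
            else cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
    for (s in seq_len(nrow(segs))) {
      pts <- bresenham(v[segs[s, 1], 1], v[segs[s, 1], 2],
                       v[segs[s, 2], 1], v[segs[s, 2], 2])
      mask[cbind(pts[, 1] + 1L, pts[, 2] + 1L)] <- 1L
    }
  }
  mask
}

# Discrete line segment from (r0,c0) to (r1,c1), endpoints included.
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  out <- matrix(0L, nrow = dr + dc + 1L, ncol = 2)
  i <- 0L
  repeat {
    i <- i + 1L
    out[i, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc)  { err <- err + dc; r0 <- r0 + sr }
  }
  out[seq_len(i), , drop = FALSE]
}

#' Dilate, close and hole-fill a binary mask
#'
#' The shape-sealing step applied to every contour raster before matching:
#' the mask is dilated by the configured structuring element, morphologically
#' closed (dilation then erosion with the same element), and every hole —
#' background region not 4-connected to the grid border — is filled. The
#' output is always a superset of the input, and contains no holes.
#'
#' @param mask Binary mask.
#' @param cfg A [morphology_config()].
#' @return Binary mask of the same dimensions.
#' @export
close_and_fill <- function(mask, cfg = morphology_config()) {
  check_mask(mask)
  if (cfg$dilation_radius > 0L) {
    off <- struct_offsets(cfg$dilation_radius, cfg$structuring_element)
    mask <- dilate_mask(mask, off)            # dilation
    mask <- erode_mask(dilate_mask(mask, off), off)  # closing
  }
  fill_holes(mask)
}

# Connected-component labels (0 = background) under 4- or 8-connectivity,
# by breadth-first search over foreground pixels.
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask != 0L)
  if (!length(fg)) return(lab)
  off <- neighbor_offsets(connectivity)
  doff <- off[, 1] + off[, 2] * h   # linear-index deltas
  cur <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      rows <- (frontier - 1L) %% h
      nxt <- integer(0)
      for (j in seq_along(doff)) {
        cand <- frontier + doff[j]
        ok <- rows + off[j, 1] >= 0L & rows + off[j, 1] < h &
              cand >= 1L & cand <= h * w
        cand <- cand[ok]
        cand <- cand[mask[cand] != 0L & lab[cand] == 0L]
        if (length(cand)) {
          lab[cand] <- cur
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

new_lesion <- function(pathology, rows, cols, grid) {
  o <- order(cols, rows)   # column-major like the key ordering
  rows <- rows[o]; cols <- cols[o]
  structure(list(
    pathology = pathology,
    pixels = cbind(row = rows, col = cols),
    area = length(rows),
    bbox = c(min_row = min(rows), min_col = min(cols),
             max_row = max(rows), max_col = max(cols)),
    centroid = c(row = mean(rows), col = mean(cols)),
    keys = sort(rows * grid$width + cols),
    grid = c(height = grid$height, width = grid$width)
  ), class = "lesion")
}

#' @export
format.lesion <- function(x, ...) {
  sprintf("<lesion %s area=%d bbox=(%d,%d)-(%d,%d)>",
          x$pathology, x$area, x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4])
}

#' @export
print.lesion <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# Canonical lesion ordering: descending area, then (min_row, min_col).
# This fixes the greedy matching iteration order, making results
# deterministic across runs and platforms.
canonical_order <- function(lesions) {
  if (!length(lesions)) return(lesions)
  area <- vapply(lesions, function(l) l$area, integer(1))
  mr <- vapply(lesions, function(l) l$bbox[["min_row"]], integer(1))
  mc <- vapply(lesions, function(l) l$bbox[["min_col"]], integer(1))
  lesions[order(-area, mr, mc)]
}

#' Extract lesions from a binary mask
#'
#' One lesion per connected component of the mask's foreground, under the
#' configured connectivity. Components are returned in canonical order:
#' descending area, ties broken by the top-left corner of the bounding box.
#'
#' @param mask Binary mask.
#' @param pathology One of [PATHOLOGY_CLASSES].
#' @param cfg A [morphology_config()] (its `connectivity` is used).
#' @return List of `lesion` objects; the union of their pixel sets equals
#'   the mask's foreground.
#' @export
extract_lesions <- function(mask, pathology, cfg = morphology_config()) {
  check_mask(mask)
  check_pathology(pathology)
  grid <- mask_grid(mask)
  lab <- label_components(mask, cfg$connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  idx <- which(lab != 0L)
  rows <- (idx - 1L) %% nrow(mask)          # 0-based
  cols <- (idx - 1L) %/% nrow(mask)
  lesions <- lapply(seq_len(n), function(k) {
    sel <- lab[idx] == k
    new_lesion(pathology, rows[sel], cols[sel], grid)
  })
  canonical_order(lesions)
}

# Paint lesion pixel sets back onto a fresh mask.
lesions_to_mask <- function(lesions, grid) {
  mask <- empty_mask(grid)
  for (l in lesions) {
    mask[cbind(l$pixels[, 1] + 1L, l$pixels[, 2] + 1L)] <- 1L
  }
  mask
}

#' Bundle per-pathology lesions into an annotation set
#'
#' An annotation set holds all lesions of one image, grouped by the four
#' pathology classes, and is tagged as `REFERENCE` (detector output) or
#' `MARKED` (learner input). Lesion lists are stored in canonical order and
#' must be pairwise disjoint within a pathology.
#'
#' @param image_id Image identifier (character scalar).
#' @param grid An [image_grid()].
#' @param source `"REFERENCE"` or `"MARKED"`.
#' @param lesions Named list mapping pathology class to a list of lesions;
#'   missing classes are filled with empty lists.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(image_id, grid, source = c("REFERENCE", "MARKED"),
                           lesions = list()) {
  source <- match.arg(source)
  if (!(is.character(image_id) && length(image_id) == 1L && nzchar(image_id))) {
    abort_input("image_id must be a non-empty string")
  }
  out <- stats::setNames(vector("list", length(PATHOLOGY_CLASSES)),
                         PATHOLOGY_CLASSES)
  for (p in PATHOLOGY_CLASSES) out[[p]] <- list()
  extra <- setdiff(names(lesions), PATHOLOGY_CLASSES)
  if (length(extra)) {
    abort_input("unknown pathology class '%s' in lesion list", extra[1])
  }
  for (p in names(lesions)) {
    ls <- lesions[[p]]
    for (l in ls) {
      if (!inherits(l, "lesion")) abort_input("lesions must be lesion objects")
      if (!identical(unname(l$grid), c(grid$height, grid$width))) {
        abort_input("lesion grid does not match the annotation grid")
      }
      if (!identical(l$pathology, p)) {
        abort_input("lesion filed under %s has pathology %s", p, l$pathology)
      }
    }
    keys <- unlist(lapply(ls, function(l) l$keys))
    if (anyDuplicated(keys)) {
      abort_input("lesion pixel sets overlap within pathology %s", p)
    }
    out[[p]] <- canonical_order(ls)
  }
  structure(list(image_id = image_id, grid = grid, source = source,
                 lesions = out),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set '%s' %s %dx%d>\n", x$image_id, x$source,
              x$grid$height, x$grid$width))
  for (p in PATHOLOGY_CLASSES) {
    cat(sprintf("  %-14s %d lesion(s)\n", p, length(x$lesions[[p]])))
  }
  invisible(x)
}

n_lesions <- function(aset, pathology = NULL) {
  if (is.null(pathology)) {
    sum(vapply(aset$lesions, length, integer(1)))
  } else {
    length(aset$lesions[[pathology]])
  }
}
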