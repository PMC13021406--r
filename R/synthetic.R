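# Seeded synthetic fixtures: elliptical reference lesions per pathology and
# learner annotations derived from them by keep / small-shift / large-shift /
# drop / spurious-addition perturbations. Every perturbation's match outcome
# is guaranteed at construction time (shift candidates are accepted only
# after verifying the actual pixel IOU bound), so the generator's
# bookkeeping serves as an exact oracle for the matching pipeline.

#' Specification for a synthetic reference annotation
#'
#' Defaults caricature the four pathology classes on a fundus image:
#' microaneurysms are the smallest and most numerous, soft exudates the
#' largest. Sizes are synthetic stand-ins, not clinical morphometry.
#'
#' @param grid An [image_grid()] (default 320 x 320).
#' @param counts Named list of `c(min, max)` lesion-count ranges per
#'   pathology.
#' @param radii Named list of `c(min, max)` lesion semi-axis ranges (pixels)
#'   per pathology.
#' @param min_separation Minimum pixel gap between lesion boundaries
#'   (default `2 * max radius + 2`), large enough that lesions never merge
#'   under the default morphology and that perturbed lesions stay
#'   unambiguous.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec and seed.
#' @return A `synthetic_case_spec` object.
#' @export
synthetic_case_spec <- function(grid = image_grid(320L, 320L),
                                counts = list(MICROANEURYSM = c(2L, 6L),
                                              HEMORRHAGE = c(1L, 5L),
                                              SOFT_EXUDATE = c(0L, 3L),
                                              HARD_EXUDATE = c(1L, 4L)),
                                radii = list(MICROANEURYSM = c(1, 3),
                                             HEMORRHAGE = c(3, 8),
                                             SOFT_EXUDATE = c(4, 10),
                                             HARD_EXUDATE = c(2, 6)),
                                min_separation = NULL,
                                seed = 1L) {
  for (p in PATHOLOGY_CLASSES) {
    if (is.null(counts[[p]]) || is.null(radii[[p]])) {
      abort_config("counts and radii must cover every pathology class")
    }
    if (length(counts[[p]]) != 2L || counts[[p]][1] > counts[[p]][2] ||
        counts[[p]][1] < 0) {
      abort_config("invalid count range for %s", p)
    }
    if (length(radii[[p]]) != 2L || radii[[p]][1] > radii[[p]][2] ||
        radii[[p]][1] < 1) {
      abort_config("invalid radius range for %s (semi-axes must be >= 1)", p)
    }
  }
  max_r <- max(vapply(radii, function(r) r[2], numeric(1)))
  if (is.null(min_separation)) min_separation <- 2 * max_r + 2
  structure(list(grid = grid, counts = counts[PATHOLOGY_CLASSES],
                 radii = radii[PATHOLOGY_CLASSES],
                 min_separation = as.numeric(min_separation),
                 seed = as.integer(seed)),
            class = "synthetic_case_spec")
}

#' Specification of learner-annotation perturbations
#'
#' Each reference lesion is independently kept exactly (outcome CORRECT),
#' shifted slightly (CORRECT: the shift is accepted only if the resulting
#' IOU with the original still reaches `iou_threshold`), shifted far away
#' (the displaced copy FALSE, the original MISSED: the new position is
#' verified disjoint from everything), or dropped (MISSED). Probability
#' mass left over after the four categories is treated as keep-exact.
#' `n_spurious` extra lesions with no reference counterpart (FALSE) are
#' added at verified-disjoint positions.
#'
#' @param p_keep_exact,p_small_shift,p_large_shift,p_drop Category
#'   probabilities; must sum to at most 1.
#' @param n_spurious Number of spurious lesions per case (random pathology).
#' @param iou_threshold Bound guaranteed for small shifts (default 0.5).
#' @param seed Integer seed.
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(p_keep_exact = 0.40, p_small_shift = 0.30,
                              p_large_shift = 0.15, p_drop = 0.15,
                              n_spurious = 2L, iou_threshold = 0.5,
                              seed = 1L) {
  ps <- c(p_keep_exact, p_small_shift, p_large_shift, p_drop)
  if (any(ps < 0) || sum(ps) > 1 + 1e-12) {
    abort_config("perturbation probabilities must be >= 0 and sum to <= 1")
  }
  if (!is_count(n_spurious)) abort_config("n_spurious must be a non-negative integer")
  structure(list(p_keep_exact = p_keep_exact, p_small_shift = p_small_shift,
                 p_large_shift = p_large_shift, p_drop = p_drop,
                 n_spurious = as.integer(n_spurious),
                 iou_threshold = iou_threshold, seed = as.integer(seed)),
            class = "perturbation_spec")
}

# Pixel set of a rotated filled ellipse, clipped check: returns NULL if any
# pixel falls outside the grid. Center always included (semi-axes >= 1).
ellipse_pixels <- function(cr, cc, a, b, theta, grid) {
  r_max <- ceiling(max(a, b))
  rs <- (floor(cr) - r_max):(ceiling(cr) + r_max)
  cs <- (floor(cc) - r_max):(ceiling(cc) + r_max)
  gg <- expand.grid(row = rs, col = cs)
  dy <- gg$row - cr; dx <- gg$col - cc
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  px <- gg[inside, , drop = FALSE]
  if (any(px$row < 0 | px$row >= grid$height |
          px$col < 0 | px$col >= grid$width)) return(NULL)
  cbind(row = as.integer(px$row), col = as.integer(px$col))
}

# A placed blob: pixels + effective radius used for separation checks.
place_blob <- function(pathology, rr, grid, centers, radii, min_sep,
                       retries = 500L) {
  for (t in seq_len(retries)) {
    a <- stats::runif(1, rr[1], rr[2])
    b <- stats::runif(1, rr[1], rr[2])
    theta <- stats::runif(1, 0, pi)
    r_eff <- max(a, b)
    m <- ceiling(r_eff) + 1
    cr <- stats::runif(1, m, grid$height - 1 - m)
    cc <- stats::runif(1, m, grid$width - 1 - m)
    if (length(radii)) {
      d <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
      if (any(d < radii + r_eff + min_sep)) next
    }
    px <- ellipse_pixels(cr, cc, a, b, theta, grid)
    if (is.null(px)) next
    # reject the rare discretization that splits a thin rotated ellipse
    sub <- matrix(0L, max(px[, 1]) - min(px[, 1]) + 1L,
                  max(px[, 2]) - min(px[, 2]) + 1L)
    sub[cbind(px[, 1] - min(px[, 1]) + 1L, px[, 2] - min(px[, 2]) + 1L)] <- 1L
    if (max(label_components(sub, 8L)) != 1L) next
    return(list(pathology = pathology, pixels = px,
                center = c(cr, cc), r_eff = r_eff))
  }
  abort_input("could not place a %s lesion after %d retries; grid too small for the requested counts/separation",
              pathology, retries)
}

blob_to_lesion <- function(blob, grid) {
  new_lesion(blob$pathology, blob$pixels[, 1], blob$pixels[, 2], grid)
}

#' Generate a synthetic reference annotation set
#'
#' Draws elliptical lesions per pathology with counts and sizes from the
#' spec, pairwise separated (across all pathologies) by at least
#' `min_separation` pixels of gap. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_case_spec()].
#' @param image_id Identifier for the generated image.
#' @return An `annotation_set` with `source = "REFERENCE"`. The placed blob
#'   geometry is attached as attribute `"blobs"` for the perturbation step.
#' @export
generate_reference <- function(spec, image_id = sprintf("synthetic-%d", spec$seed)) {
  if (!inherits(spec, "synthetic_case_spec")) {
    abort_config("spec must be a synthetic_case_spec")
  }
  with_seed(spec$seed, {
    want <- lapply(PATHOLOGY_CLASSES, function(p) {
      rng <- spec$counts[[p]]
      n <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
      if (n == 0L) return(NULL)
      data.frame(pathology = p, r_max = spec$radii[[p]][2],
                 idx = seq_len(n), stringsAsFactors = FALSE)
    })
    want <- do.call(rbind, want)
    blobs <- list()
    centers <- matrix(numeric(0), ncol = 2)
    radii <- numeric(0)
    if (!is.null(want)) {
      # place large classes first: improves packing feasibility
      want <- want[order(-want$r_max), ]
      for (k in seq_len(nrow(want))) {
        p <- want$pathology[k]
        bl <- place_blob(p, spec$radii[[p]], spec$grid, centers, radii,
                         spec$min_separation)
        blobs[[length(blobs) + 1L]] <- bl
        centers <- rbind(centers, bl$center)
        radii <- c(radii, bl$r_eff)
      }
    }
    lesions <- stats::setNames(lapply(PATHOLOGY_CLASSES, function(p) {
      lapply(Filter(function(b) b$pathology == p, blobs),
             blob_to_lesion, grid = spec$grid)
    }), PATHOLOGY_CLASSES)
    aset <- annotation_set(image_id, spec$grid, "REFERENCE", lesions)
    attr(aset, "blobs") <- blobs
    attr(aset, "spec") <- spec
    aset
  })
}

shift_pixels <- function(px, dr, dc, grid) {
  out <- cbind(row = px[, 1] + as.integer(dr), col = px[, 2] + as.integer(dc))
  if (any(out[, 1] < 0L | out[, 1] >= grid$height |
          out[, 2] < 0L | out[, 2] >= grid$width)) return(NULL)
  out
}

pixel_iou <- function(px_a, px_b, grid) {
  ka <- px_a[, 1] * grid$width + px_a[, 2]
  kb <- px_b[, 1] * grid$width + px_b[, 2]
  ni <- length(intersect(ka, kb))
  ni / (length(ka) + length(kb) - ni)
}

#' Perturb a reference annotation into a learner annotation
#'
#' Applies the perturbation categories of a [perturbation_spec()] to every
#' reference lesion and adds spurious lesions, recording the expected match
#' outcome of every lesion. Because small shifts are verified to keep
#' IOU at or above the threshold and displaced/spurious lesions are
#' verified disjoint from everything else, running the matcher on the
#' result must reproduce the expected labels exactly.
#'
#' @param reference Output of [generate_reference()] (needs its attached
#'   blob geometry).
#' @param pspec A [perturbation_spec()].
#' @return A `synthetic_case`: list with `reference`, `marked`
#'   (`annotation_set`, source MARKED) and `expected` — per pathology
#'   `n_correct`, `n_false`, `n_missed`, the implied `pairs`
#'   (detected_index, marked_index in canonical order), `false_marked` and
#'   `missed_detected` indices.
#' @export
perturb_annotation <- function(reference, pspec) {
  blobs <- attr(reference, "blobs")
  spec <- attr(reference, "spec")
  if (is.null(blobs) || is.null(spec)) {
    abort_input("reference must come from generate_reference() (blob geometry attached)")
  }
  grid <- reference$grid
  with_seed(pspec$seed, {
    cuts <- cumsum(c(pspec$p_keep_exact, pspec$p_small_shift,
                     pspec$p_large_shift, pspec$p_drop))
    centers <- do.call(rbind, lapply(blobs, function(b) b$center))
    radii <- vapply(blobs, function(b) b$r_eff, numeric(1))
    marked_blobs <- list()   # each: pathology, pixels, center, r_eff, label, src (ref blob index or 0)
    ref_label <- character(length(blobs))

    sep_ok <- function(cr, cc, r_eff, skip_ref = 0L) {
      keep <- seq_along(radii) != skip_ref
      if (any(keep)) {
        d <- sqrt((centers[keep, 1] - cr)^2 + (centers[keep, 2] - cc)^2)
        if (any(d < radii[keep] + r_eff + 1)) return(FALSE)
      }
      for (mb in marked_blobs) {
        d <- sqrt((mb$center[1] - cr)^2 + (mb$center[2] - cc)^2)
        if (d < mb$r_eff + r_eff + 1) return(FALSE)
      }
      TRUE
    }

    for (k in seq_along(blobs)) {
      b <- blobs[[k]]
      u <- stats::runif(1)
      cat_k <- if (u < cuts[1]) "keep" else if (u < cuts[2]) "small"
               else if (u < cuts[3]) "large" else if (u < cuts[4]) "drop"
               else "keep"
      if (cat_k == "small") {
        smax <- max(1L, floor(0.25 * 2 * b$r_eff))  # <= 25% of the diameter
        placed <- FALSE
        for (t in seq_len(50L)) {
          dr <- sample(-smax:smax, 1L); dc <- sample(-smax:smax, 1L)
          if (dr == 0L && dc == 0L) next
          px <- shift_pixels(b$pixels, dr, dc, grid)
          if (is.null(px)) next
          if (pixel_iou(b$pixels, px, grid) < pspec$iou_threshold) next
          marked_blobs[[length(marked_blobs) + 1L]] <-
            list(pathology = b$pathology, pixels = px,
                 center = b$center + c(dr, dc), r_eff = b$r_eff,
                 label = "CORRECT", src = k)
          ref_label[k] <- "CORRECT"
          placed <- TRUE
          break
        }
        if (!placed) cat_k <- "keep"   # smallest lesions: no shift keeps the bound
      }
      if (cat_k == "keep") {
        marked_blobs[[length(marked_blobs) + 1L]] <-
          list(pathology = b$pathology, pixels = b$pixels, center = b$center,
               r_eff = b$r_eff, label = "CORRECT", src = k)
        ref_label[k] <- "CORRECT"
      } else if (cat_k == "large") {
        diam <- 2 * b$r_eff
        placed <- FALSE
        for (t in seq_len(300L)) {
          ang <- stats::runif(1, 0, 2 * pi)
          mag <- stats::runif(1, 3 * diam, 6 * diam)
          dr <- round(mag * sin(ang)); dc <- round(mag * cos(ang))
          px <- shift_pixels(b$pixels, dr, dc, grid)
          if (is.null(px)) next
          if (!sep_ok(b$center[1] + dr, b$center[2] + dc, b$r_eff)) next
          marked_blobs[[length(marked_blobs) + 1L]] <-
            list(pathology = b$pathology, pixels = px,
                 center = b$center + c(dr, dc), r_eff = b$r_eff,
                 label = "FALSE", src = 0L)
          ref_label[k] <- "MISSED"
          placed <- TRUE
          break
        }
        if (!placed) {
          abort_input("could not displace a %s lesion off its reference; grid too small",
                      b$pathology)
        }
      } else if (cat_k == "drop") {
        ref_label[k] <- "MISSED"
      }
    }

    for (s in seq_len(pspec$n_spurious)) {
      p <- sample(PATHOLOGY_CLASSES, 1L)
      placed <- FALSE
      for (t in seq_len(300L)) {
        bl <- tryCatch(place_blob(p, spec$radii[[p]], grid,
                                  rbind(centers,
                                        do.call(rbind, lapply(marked_blobs,
                                                              function(m) m$center))),
                                  c(radii, vapply(marked_blobs,
                                                  function(m) m$r_eff, numeric(1))),
                                  min_sep = spec$min_separation, retries = 50L),
                       funduseval_input_error = function(e) NULL)
        if (is.null(bl)) next
        bl$label <- "FALSE"; bl$src <- 0L
        marked_blobs[[length(marked_blobs) + 1L]] <- bl
        placed <- TRUE
        break
      }
      if (!placed) abort_input("could not place a spurious %s lesion", p)
    }

    # Assemble the marked annotation set and resolve expected outcomes to
    # canonical indices via pixel-key identity.
    mk_lesions <- stats::setNames(lapply(PATHOLOGY_CLASSES, function(p) {
      lapply(Filter(function(m) m$pathology == p, marked_blobs),
             blob_to_lesion, grid = grid)
    }), PATHOLOGY_CLASSES)
    marked <- annotation_set(reference$image_id, grid, "MARKED", mk_lesions)

    key_of <- function(px) paste(px[1, 1], px[1, 2], nrow(px))
    expected <- stats::setNames(lapply(PATHOLOGY_CLASSES, function(p) {
      rb_idx <- which(vapply(blobs, function(b) b$pathology == p, logical(1)))
      mb <- Filter(function(m) m$pathology == p, marked_blobs)
      # canonical index of each reference blob
      ref_canon <- vapply(rb_idx, function(k) {
        key <- key_of(blobs[[k]]$pixels[order(blobs[[k]]$pixels[, 2],
                                              blobs[[k]]$pixels[, 1]), , drop = FALSE])
        which(vapply(reference$lesions[[p]],
                     function(l) identical(key_of(l$pixels), key), logical(1)))[1]
      }, integer(1))
      mk_canon <- vapply(mb, function(m) {
        key <- key_of(m$pixels[order(m$pixels[, 2], m$pixels[, 1]), , drop = FALSE])
        which(vapply(marked$lesions[[p]],
                     function(l) identical(key_of(l$pixels), key), logical(1)))[1]
      }, integer(1))
      pairs <- do.call(rbind, lapply(seq_along(mb), function(j) {
        if (mb[[j]]$label != "CORRECT") return(NULL)
        data.frame(detected_index = ref_canon[match(mb[[j]]$src, rb_idx)],
                   marked_index = mk_canon[j])
      }))
      if (is.null(pairs)) {
        pairs <- data.frame(detected_index = integer(0), marked_index = integer(0))
      }
      list(n_correct = nrow(pairs),
           n_false = sum(vapply(mb, function(m) m$label == "FALSE", logical(1))),
           n_missed = sum(ref_label[rb_idx] == "MISSED"),
           pairs = pairs[order(pairs$detected_index), , drop = FALSE],
           false_marked = sort(mk_canon[vapply(mb, function(m) m$label == "FALSE",
                                               logical(1))]),
           missed_detected = sort(ref_canon[ref_label[rb_idx] == "MISSED"]))
    }), PATHOLOGY_CLASSES)

    structure(list(reference = reference, marked = marked, expected = expected),
              class = "synthetic_case")
  })
}

#' Generate a complete synthetic case
#'
#' Convenience wrapper: [generate_reference()] followed by
#' [perturb_annotation()], both seeded from one case seed.
#'
#' @param seed Integer case seed.
#' @param spec A [synthetic_case_spec()] (its own seed is overridden).
#' @param pspec A [perturbation_spec()] (its seed is overridden).
#' @return A `synthetic_case`.
#' @export
simulate_case <- function(seed = 1L, spec = synthetic_case_spec(),
                          pspec = perturbation_spec()) {
  spec$seed <- as.integer(seed)
  pspec$seed <- as.integer(seed) + 1000000L
  perturb_annotation(generate_reference(spec), pspec)
}
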