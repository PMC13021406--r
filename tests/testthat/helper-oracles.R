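# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately share no code with the package internals:
# morphology is done pixel-by-pixel, hole filling by an explicit
# breadth-first flood from the border.

se_offsets <- function(radius, element = "disk") {
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  if (element == "disk") off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  off
}

brute_dilate <- function(mask, radius, element = "disk") {
  off <- se_offsets(radius, element)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] == 0L) next
    for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask)) {
        out[rr, cc] <- 1L
      }
    }
  }
  out
}

# pixels outside the grid count as foreground, so closing never shrinks
# the original shape at the border
brute_erode <- function(mask, radius, element = "disk") {
  off <- se_offsets(radius, element)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    keep <- TRUE
    for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      inside <- rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask)
      if (inside && mask[rr, cc] == 0L) { keep <- FALSE; break }
    }
    if (keep) out[r, c] <- 1L
  }
  out
}

# background pixels 4-reachable from the border, by queue-based flood
brute_border_flood <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  queue <- list()
  for (r in 1:h) for (c in 1:w) {
    if ((r == 1 || r == h || c == 1 || c == w) && mask[r, c] == 0L) {
      queue[[length(queue) + 1L]] <- c(r, c); seen[r, c] <- TRUE
    }
  }
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- p[1] + d[1]; cc <- p[2] + d[2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
          !seen[rr, cc] && mask[rr, cc] == 0L) {
        seen[rr, cc] <- TRUE
        queue[[length(queue) + 1L]] <- c(rr, cc)
      }
    }
  }
  seen
}

brute_fill_holes <- function(mask) {
  reach <- brute_border_flood(mask)
  out <- mask
  out[mask == 0L & !reach] <- 1L
  out
}

brute_close_and_fill <- function(mask, radius = 1, element = "disk") {
  if (radius > 0) {
    mask <- brute_dilate(mask, radius, element)
    mask <- brute_erode(brute_dilate(mask, radius, element), radius, element)
  }
  brute_fill_holes(mask)
}

# build a single lesion from an explicit pixel set (0-based coordinates)
one_lesion <- function(rows, cols, h, w, pathology = "HEMORRHAGE") {
  m <- matrix(0L, h, w)
  m[cbind(rows + 1L, cols + 1L)] <- 1L
  ls <- extract_lesions(m, pathology)
  stopifnot(length(ls) == 1L)
  ls[[1]]
}

rect_lesion <- function(r0, c0, hh, ww, h, w, pathology = "HEMORRHAGE") {
  px <- expand.grid(row = r0:(r0 + hh - 1L), col = c0:(c0 + ww - 1L))
  one_lesion(px$row, px$col, h, w, pathology)
}

# random small matching instance: possibly-overlapping rectangles on a
# 40 x 40 grid, up to `nmax` lesions per side
random_instance <- function(seed, nmax = 6L) {
  set.seed(seed)
  h <- 40L; w <- 40L
  gen <- function(n) {
    lapply(seq_len(n), function(i) {
      hh <- sample(2:6, 1); ww <- sample(2:6, 1)
      rect_lesion(sample(0:(h - hh), 1), sample(0:(w - ww), 1), hh, ww, h, w)
    })
  }
  list(detected = gen(sample(0:nmax, 1)), marked = gen(sample(0:nmax, 1)))
}

# is the pairwise overlap structure one-to-one?
one_to_one_overlaps <- function(detected, marked) {
  if (!length(detected) || !length(marked)) return(TRUE)
  ov <- outer(seq_along(detected), seq_along(marked),
              Vectorize(function(i, j) iou(detected[[i]], marked[[j]]) > 0))
  all(rowSums(ov) <= 1) && all(colSums(ov) <= 1)
}

entry_counts <- function(entry) {
  c(correct = length(entry$correct_pairs),
    false = length(entry$false_marked),
    missed = length(entry$missed_detected))
}
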