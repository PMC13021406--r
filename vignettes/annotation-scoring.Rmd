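---
title: "Scoring drawn lesion annotations: methods and design notes"
author: "funduseval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drawn lesion annotations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funduseval)
```

## The problem

Training tools for diabetic-retinopathy (DR) interpretation let a learner
draw lesion outlines on a fundus photograph and then compare the drawing
against reference detections — in deployment the output of a lesion-detection
model, here any reference annotation. Four pathology classes are handled:
microaneurysms, hemorrhages, soft exudates and hard exudates. The tool must
answer, per pathology: which learner lesions are correct, which are falsely
input, and which reference lesions were missed — and summarize that as the
percentage of lesions found.

`funduseval` implements that computational core: contour-to-lesion geometry,
greedy intersection-over-union (IOU) matching, feedback aggregation, a
rule-based severity grade, a synthetic fixture generator, and questionnaire
scoring for the usability/cognitive-load instruments such studies use.

## From drawn contours to lesions

A drawn annotation arrives as an ordered list of 0-based `(row, col)` pixel
coordinates. `rasterize_contours()` joins consecutive vertices with discrete
Bresenham segments and closes polygons with three or more vertices.
`close_and_fill()` then dilates the outline, applies a morphological closing
with the same structuring element, and fills every hole (background region
not 4-connected to the grid border). `extract_lesions()` finally splits the
foreground into connected components — one lesion each — so matching operates
on *complete filled lesions*, not outlines.

Tunable parameters (in `morphology_config()`):

* `dilation_radius` (pixels, default 1): the smallest element that bridges
  1-pixel gaps left by freehand strokes. Radius 0 disables
  dilation/closing but still fills holes.
* `structuring_element` (`disk`, default, defined as offsets with
  `dy^2 + dx^2 <= r^2`; or `square`).
* `connectivity` (default 8) for foreground components. Hole filling always
  floods the background 4-connectedly — the standard duality that avoids
  topological paradoxes (a diagonal foreground chain would otherwise both
  enclose and not enclose its background).

Two deliberate numerical choices: erosion (inside the closing) treats
out-of-grid pixels as foreground, so `close_and_fill()` is extensive
(output ⊇ input) even at the image border; and lesions are always reported
in a canonical order — descending area, ties by bounding-box top-left — so
every downstream result is deterministic across runs and platforms.
Whether learners draw closed polygons or open freehand strokes is
unknowable at this layer; both are accepted, and the closing step is what
seals small gaps either way.

## Matching

For one pathology, `match_pathology()` iterates reference (detected) lesions
in canonical order. Each computes the IOU `|A∩B| / |A∪B|` against every
still-unassigned marked lesion and takes the maximum. If that maximum is at
least `iou_threshold` (default 0.5, boundary **inclusive**), the pair is
recorded as correct and the marked lesion leaves the pool. Afterwards,
unassigned marked lesions are *falsely input* and unpaired detected lesions
are *missed*.

Two points here were genuinely open and are package decisions:

* **Conditional deletion.** A marked lesion is removed from the pool only
  when the pairing clears the threshold. The alternative — always deleting
  the highest-IOU marked lesion — would let a sub-threshold overlap consume
  a lesion that a later detected lesion matches well, and would contradict
  the correctness criterion itself.
* **Order and ties.** The iteration order over detected lesions and the
  tie-break between equal maximal IOUs are not dictated by the method
  definition; the canonical order plus lowest-index tie-break make the
  greedy result a pure function of the input.

IOU is computed on the filled pixel sets produced by the geometry layer;
both sides are processed identically.

Greedy assignment can be suboptimal when several lesions overlap each
other. `optimal_match_oracle()` — a dynamic program over subsets, capped at
seven lesions per side — exists purely as an independent check: the test
suite verifies greedy never exceeds the optimum and equals it whenever the
overlap structure is one-to-one, which is the regime drawn annotations
almost always occupy (lesions are separated; a learner blob overlaps at
most one reference lesion).

## Feedback reports

`build_report()` aggregates a match into the feedback structure: exactly
four pathology entries, each with counts satisfying
`n_reference = n_correct + n_missed` and `n_marked = n_correct + n_false`,
the percentage found, and the categorized lesion lists (correct → green,
falsely input → yellow, missed → red; `ALL` is their union).

The percentage's denominator is the reference count (recall-style):
`100 * n_correct / n_reference`. False marks are reported as counts and
lists, not folded into the percentage. When a pathology has no reference
lesion there was nothing to find: the percentage is 100 by convention
(avoiding 0/0) while false marks remain visible. Percentages are stored at
full precision; rounding is a display concern.

## Severity grading

The deployed system derives a DR severity grade (0–4) from lesion
prominence with a trained classifier; that classifier is out of scope here.
`grade_severity()` instead applies an ordered first-match rule table to the
per-pathology lesion counts. The shipped default is an ICDR-inspired
caricature — **a configuration stand-in, not a clinical claim**:

| order | condition | grade |
|---|---|---|
| 1 | proliferative flag | 4 |
| 2 | ≥ 40 hemorrhages and ≥ 5 soft exudates | 4 |
| 3 | ≥ 20 hemorrhages | 3 |
| 4 | hemorrhages and soft exudates both present | 3 |
| 5–7 | any hemorrhage / soft / hard exudate | 2 |
| 8 | any microaneurysm | 1 |
| — | otherwise | 0 |

Grade 4 is not inferable from the four lesion classes alone, so it is
reachable through an explicit flag (or the extreme-count rule), keeping the
full five-grade space exercisable. Every condition is monotone (a minimum
count or a flag) and rules are ordered by non-increasing grade, so adding
lesions can only move the first match earlier: the table is provably
monotone, and `enumerate_reachable_grades()` verifies reachability
exhaustively (all count vectors up to a cap, both flag states). Custom
tables load from JSON and are validated on load; lesion *location* (the
quadrant-based 4-2-1 rule) is deliberately not modeled.

## The synthetic generator

`generate_reference()` draws rotated filled ellipses per pathology;
`perturb_annotation()` derives a learner annotation by keeping, slightly
shifting, displacing, or dropping each reference lesion and adding spurious
blobs. The generator emulates the *geometry and bookkeeping* of annotation
comparison — lesion sizes ordered like the real classes (microaneurysm
semi-axes 1–3 px, hemorrhage 3–8, soft exudate 4–10, hard exudate 2–6),
counts per image (MA 2–6, HEM 1–5, SE 0–3, HE 1–4) on a 320×320 grid —
and deliberately none of the appearance of fundus photographs: no texture,
no vessels, no grading-relevant spatial layout. Passing tests therefore
demonstrate correctness of the matching arithmetic under realistic
geometry, not detector or learner performance on real images.

Outcome labels are guaranteed at construction, and the guarantee is
*verified, not assumed*: a candidate small shift (at most 25 % of the
lesion diameter) is accepted only after the actual pixel IOU against the
original is confirmed to reach the threshold — the continuous-geometry
bound behind the 25 % rule fails for pixelated microaneurysms (a radius-1
disk has 5 pixels; any 1-pixel shift yields IOU 0.25), in which case the
lesion is kept exact and remains CORRECT. Displaced copies (shift at least
3× the diameter) and spurious lesions are placed only at positions verified
disjoint from every other lesion, so they are certainly FALSE and their
originals certainly MISSED. Lesions are separated by a minimum gap
(`2 × max radius + 2` pixels by default) so nothing merges under the
default morphology and the overlap structure stays one-to-one; infeasible
packing requests fail with a capacity error after bounded retries. The
perturbation mix defaults to keep 0.40, small-shift 0.30, large-shift 0.15,
drop 0.15, two spurious lesions per case — a mid-ability learner
caricature; any probability mass left unassigned falls to keep-exact.
Everything is a pure function of (spec, seed).

The test suite and the package's own validation lean on this: across 200
seeded cases the full pipeline's per-pathology (correct, false, missed)
counts equal the generator's expectation *exactly* — by construction no
borderline IOU exists, so any deviation is a defect, not noise.

## Questionnaire scoring

`sus_score()` implements standard 10-item SUS scoring (odd items positively
keyed contribute `rating − 1`, even items `5 − rating`, total × 2.5; range
0–100 — the keying follows the standard instrument, since adapted
translations cite but do not restate it). `paas_score()` validates the
single 9-point mental-effort item; `naiive_subscales()` averages the
2-item intrinsic and 3-item extraneous 7-point subscales.
`summarize_scores()` reports n, mean, sample SD (n−1; 0 for a singleton, a
convention chosen over `NA` for stable CSV output), min and max —
descriptive only, no inferential statistics.

## Validation scales

The shipped checks run at sizes chosen to make failures unambiguous while
staying cheap: morphology against a brute-force per-pixel oracle on grids
up to 50×50; greedy-vs-exhaustive matching on 200 random instances of up
to 6 lesions per side; pipeline-vs-construction on 200 synthetic cases;
grade reachability exhaustively up to count 50. EBImage serves as an
additional independent cross-check for square-element morphology,
hole-filling and 4-connected labeling.

## Known limitations

* Sub-pixel geometry is out of scope; contours snap to the pixel grid.
* Greedy matching is order-dependent in pathological overlap stacks; the
  canonical order makes it deterministic, not optimal (the oracle bounds
  the gap in tests).
* The default grading table is a documented stand-in; clinical use would
  require a guideline-validated table and lesion-location modeling.
* Synthetic ellipses do not model real lesion morphology, detector errors,
  or learner behavior beyond the four perturbation categories.
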