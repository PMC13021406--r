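# funduseval

Scoring and feedback for learner-drawn lesion annotations on fundus images,
for people building or validating diabetic-retinopathy (DR) training tools.
A learner draws lesion contours for the four DR pathology classes —
microaneurysms, hemorrhages, soft exudates, hard exudates — and the package
compares them against reference detections and reports, per pathology, which
lesions are correct, falsely input, or missed.

## What it computes

* **Geometry.** Drawn contours are rasterized in pixel space, dilated and
  morphologically closed (sealing freehand gaps), hole-filled, and split
  into connected components: filled lesions, not outlines
  (`rasterize_contours()`, `close_and_fill()`, `extract_lesions()`).
* **Matching.** Within each pathology, reference lesions are visited in a
  canonical order; each takes the still-unassigned marked lesion with the
  highest intersection-over-union, IOU(A, B) = |A∩B| / |A∪B|, and the pair
  counts as *correct* iff IOU ≥ 0.5 (threshold configurable, boundary
  inclusive). Remaining marked lesions are *falsely input*; unpaired
  reference lesions are *missed* (`match_all()`).
* **Feedback.** Per-pathology counts and percent-found
  (100 · n_correct / n_reference), with color-tagged lesion lists —
  correct green, false yellow, missed red (`build_report()`,
  `filter_view()`).
* **Severity.** A configurable ordered rule table maps lesion counts to a
  DR grade 0–4 (`grade_severity()`); the shipped table is an ICDR-inspired
  stand-in, not a clinical claim.
* **Synthetic fixtures.** A seeded generator produces reference lesion sets
  and perturbed learner annotations whose match outcome is guaranteed at
  construction (`simulate_case()`), replacing both the detector and human
  learners for testing.
* **Study instruments.** SUS (0–100), Paas mental-effort and Naiive
  cognitive-load scoring with descriptive summaries
  (`sus_score()`, `score_questionnaires()`).

## Worked example

```r
library(funduseval)

case <- simulate_case(seed = 42)          # reference + perturbed learner annotation
res  <- match_all(case$reference, case$marked)
build_report(res, case$reference, case$marked)
#> <feedback_report 'synthetic-42'>
#>   MICROANEURYSM  found 100.0%  (ref 2, marked 3: 2 correct, 1 false, 0 missed)
#>   HEMORRHAGE     found  80.0%  (ref 5, marked 5: 4 correct, 1 false, 1 missed)
#>   SOFT_EXUDATE   found 100.0%  (ref 0, marked 1: 0 correct, 1 false, 0 missed)
#>   HARD_EXUDATE   found 100.0%  (ref 1, marked 1: 1 correct, 0 false, 0 missed)
```

Reading: of the 5 reference hemorrhages the learner found 4 (80 %); one
learner hemorrhage matched nothing (falsely input) and one reference
hemorrhage was missed. The soft-exudate row shows the zero-reference
convention: nothing to find ⇒ 100 %, with the false mark still counted.

```r
grade_severity(case$reference)$grade      # rule-based severity from lesion counts
#> [1] 3
```

The same pipeline runs from the shell:

```sh
Rscript inst/cli/funduseval.R simulate --seed 42 --out case42
Rscript inst/cli/funduseval.R evaluate --reference case42/reference.json \
        --marked case42/marked.json --out case42/report
Rscript inst/cli/funduseval.R grade --reference case42/reference.json
```

Exit codes: 0 ok, 2 input error, 3 config error, 4 internal error.

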