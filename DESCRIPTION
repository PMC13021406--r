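Package: funduseval
Title: Lesion Annotation Scoring and Feedback for Diabetic Retinopathy Training
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Scores learner-drawn lesion annotations on fundus images against
    reference detections for the four diabetic-retinopathy pathologies
    (microaneurysms, hemorrhages, soft and hard exudates). Drawn contours are
    rasterized, dilated and morphologically closed into filled pixel lesions;
    learner lesions are matched to reference lesions by greedy
    intersection-over-union assignment at a configurable threshold and
    categorized as correct, falsely input, or missed. Includes per-pathology
    feedback reports, a configurable rule-based severity grade (0-4) driven by
    lesion counts, a seeded synthetic fixture generator with
    construction-guaranteed match outcomes, scoring for the SUS, Paas and
    Naiive questionnaires, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
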