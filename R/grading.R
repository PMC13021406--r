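# Rule-based diabetic-retinopathy severity grading (stand-in for a trained
# severity classifier): per-pathology lesion counts, plus an explicit
# proliferative flag, are mapped to a grade 0-4 by an ordered first-match
# rule table.

GRADE_LABELS <- c(`0` = "no DR", `1` = "mild", `2` = "moderate",
                  `3` = "severe", `4` = "proliferative")

#' Construct and validate a grading rule table
#'
#' Rules are evaluated in order; the first whose conditions all hold
#' determines the grade, and `default_grade` applies when none matches.
#' Each rule may require minimum lesion counts per pathology
#' (a conjunction) and/or the proliferative flag. Because every condition
#' is monotone (of the form "count at least t" or "flag set"), a table
#' ordered by non-increasing grade is monotone: adding lesions never lowers
#' the grade.
#'
#' @param rules List of rules; each a list with `grade` (0-4) and optionally
#'   `min_counts` (named list / vector of per-pathology minimum counts) and
#'   `proliferative = TRUE`.
#' @param default_grade Grade when no rule matches (default 0).
#' @return A `grading_rule_table` object.
#' @export
grading_rule_table <- function(rules, default_grade = 0L) {
  if (!is.list(rules)) abort_config("rules must be a list")
  if (!is_count(default_grade) || default_grade > 4) {
    abort_config("default_grade must be an integer in 0..4")
  }
  grades <- numeric(length(rules))
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    if (!is.list(r) || is.null(r$grade)) {
      abort_config("rule %d has no grade", k)
    }
    if (!is_count(r$grade) || r$grade > 4) {
      abort_config("rule %d: grade must be an integer in 0..4", k)
    }
    grades[k] <- r$grade
    mc <- r$min_counts
    if (!is.null(mc)) {
      mc <- unlist(mc)
      bad <- setdiff(names(mc), PATHOLOGY_CLASSES)
      if (length(bad)) {
        abort_config("rule %d: unknown pathology '%s' in min_counts", k, bad[1])
      }
      if (!all(vapply(mc, function(v) is_count(v, 1L), logical(1)))) {
        abort_config("rule %d: min_counts must be positive integers", k)
      }
      rules[[k]]$min_counts <- as.list(mc)
    }
    if (!is.null(r$proliferative) && !isTRUE(r$proliferative)) {
      abort_config("rule %d: proliferative, when present, must be true", k)
    }
    if (is.null(mc) && !isTRUE(r$proliferative)) {
      abort_config("rule %d has no condition; unconditional rules belong in default_grade", k)
    }
    rules[[k]]$grade <- as.integer(r$grade)
  }
  if (is.unsorted(rev(grades))) {
    abort_config("rules must be ordered by non-increasing grade (first match wins)")
  }
  structure(list(rules = rules, default_grade = as.integer(default_grade)),
            class = "grading_rule_table")
}

#' The shipped default grading rule table
#'
#' An ICDR-inspired caricature for exercising the 0-4 grade space; a
#' configuration stand-in, not a clinical claim (in particular no
#' quadrant-based 4-2-1 rule, since lesion positions relative to anatomy
#' are not modeled):
#' grade 4 for the proliferative flag or extreme combined counts
#' (40+ hemorrhages with 5+ soft exudates); grade 3 for 20+ hemorrhages or
#' soft exudates co-occurring with hemorrhages; grade 2 for any hemorrhage
#' or exudate; grade 1 for microaneurysms only; grade 0 otherwise.
#'
#' @return A [grading_rule_table()].
#' @export
default_grading_rules <- function() {
  grading_rule_table(list(
    list(grade = 4L, proliferative = TRUE),
    list(grade = 4L, min_counts = list(HEMORRHAGE = 40L, SOFT_EXUDATE = 5L)),
    list(grade = 3L, min_counts = list(HEMORRHAGE = 20L)),
    list(grade = 3L, min_counts = list(HEMORRHAGE = 1L, SOFT_EXUDATE = 1L)),
    list(grade = 2L, min_counts = list(HEMORRHAGE = 1L)),
    list(grade = 2L, min_counts = list(SOFT_EXUDATE = 1L)),
    list(grade = 2L, min_counts = list(HARD_EXUDATE = 1L)),
    list(grade = 1L, min_counts = list(MICROANEURYSM = 1L))
  ), default_grade = 0L)
}

# First-match evaluation on a named count vector + flag; returns the rule
# index matched (0 for the default).
eval_rules <- function(table, counts, proliferative) {
  for (k in seq_along(table$rules)) {
    r <- table$rules[[k]]
    if (isTRUE(r$proliferative) && !proliferative) next
    ok <- TRUE
    for (p in names(r$min_counts)) {
      if (counts[[p]] < r$min_counts[[p]]) { ok <- FALSE; break }
    }
    if (ok) return(list(grade = r$grade, rule = k))
  }
  list(grade = table$default_grade, rule = 0L)
}

#' Grade disease severity from a reference annotation set
#'
#' @param reference Annotation set with `source = "REFERENCE"`.
#' @param table A [grading_rule_table()]; default [default_grading_rules()].
#' @param proliferative Logical flag for proliferative disease, which is not
#'   inferable from the four lesion classes alone.
#' @return List with `grade` (0-4), `label`, `matched_rule` (rule index,
#'   0 = default) and the `counts` used.
#' @export
grade_severity <- function(reference, table = default_grading_rules(),
                           proliferative = FALSE) {
  if (!inherits(reference, "annotation_set") ||
      reference$source != "REFERENCE") {
    abort_input("grade_severity expects a REFERENCE annotation set")
  }
  if (!inherits(table, "grading_rule_table")) {
    abort_config("table must be a grading_rule_table")
  }
  counts <- vapply(reference$lesions, length, integer(1))
  hit <- eval_rules(table, counts, isTRUE(proliferative))
  list(grade = hit$grade,
       label = unname(GRADE_LABELS[as.character(hit$grade)]),
       matched_rule = hit$rule,
       counts = as.list(counts))
}

#' Enumerate all grades reachable from a rule table
#'
#' Exhaustively evaluates the table over every per-pathology count vector
#' with entries in `[0, count_cap]`, under both proliferative-flag states.
#' Used to validate a configured table (e.g. that all five severity levels
#' remain reachable).
#'
#' @param table A [grading_rule_table()].
#' @param count_cap Maximum per-pathology count to enumerate (at least 1).
#' @return Sorted integer vector of distinct reachable grades.
#' @export
enumerate_reachable_grades <- function(table, count_cap) {
  if (!inherits(table, "grading_rule_table")) {
    abort_config("table must be a grading_rule_table")
  }
  if (!is_count(count_cap, 1L)) abort_input("count_cap must be >= 1")
  v <- 0:count_cap
  n1 <- length(v)
  n <- n1^4
  counts <- list(
    MICROANEURYSM = rep(v, times = n1^3),
    HEMORRHAGE    = rep(rep(v, each = n1), times = n1^2),
    SOFT_EXUDATE  = rep(rep(v, each = n1^2), times = n1),
    HARD_EXUDATE  = rep(v, each = n1^3)
  )
  grades <- integer(0)
  for (flag in c(FALSE, TRUE)) {
    g <- rep(table$default_grade, n)
    assigned <- rep(FALSE, n)
    for (r in table$rules) {
      if (isTRUE(r$proliferative) && !flag) next
      ok <- !assigned
      for (p in names(r$min_counts)) {
        ok <- ok & counts[[p]] >= r$min_counts[[p]]
      }
      g[ok] <- r$grade
      assigned <- assigned | ok
    }
    grades <- union(grades, unique(g))
  }
  sort(as.integer(grades))
}

#' Read a grading rule table from JSON
#'
#' Expected layout: `{"default_grade": 0, "rules": [{"grade": 3,
#' "min_counts": {"HEMORRHAGE": 20}}, {"grade": 4, "proliferative": true},
#' ...]}`. Validated on load.
#'
#' @param path Path to a rule-table JSON file.
#' @return A [grading_rule_table()].
#' @export
read_rule_table <- function(path) {
  if (!file.exists(path)) abort_config("rule table file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) abort_config("cannot parse rule table %s: %s",
                                                   path, conditionMessage(e)))
  if (is.null(doc$rules)) abort_config("rule table %s has no 'rules' field", path)
  grading_rule_table(doc$rules,
                     default_grade = if (is.null(doc$default_grade)) 0L
                                     else doc$default_grade)
}

#' Write a grading rule table to JSON
#' @param table A [grading_rule_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(table, path) {
  jsonlite::write_json(unclass(table), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
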