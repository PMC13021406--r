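# Questionnaire scoring for the evaluation study instruments: the System
# Usability Scale (10 items, 5-point), the Paas mental-effort scale
# (1 item, 9-point) and the Naiive cognitive-load questionnaire
# (intrinsic: 2 items, extraneous: 3 items, both 7-point).

check_rating <- function(x, lo, hi, what) {
  bad <- which(!(x %in% lo:hi))
  if (length(bad)) {
    abort_input("%s item %d out of range: %s (allowed %d..%d)",
                what, bad[1], format(x[bad[1]]), lo, hi)
  }
  as.integer(x)
}

#' Score a System Usability Scale response
#'
#' Standard Brooke scoring with odd items positively and even items
#' negatively keyed: odd items contribute `rating - 1`, even items
#' `5 - rating`; the sum of contributions is multiplied by 2.5, giving a
#' score from 0 to 100 (higher = better usability).
#'
#' @param ratings Integer vector of 10 ratings, each 1-5, items in order.
#' @return SUS score in `[0, 100]`.
#' @export
sus_score <- function(ratings) {
  if (length(ratings) != 10L) abort_input("SUS requires exactly 10 items")
  r <- check_rating(ratings, 1L, 5L, "SUS")
  odd <- seq(1L, 9L, by = 2L)
  even <- seq(2L, 10L, by = 2L)
  2.5 * (sum(r[odd] - 1L) + sum(5L - r[even]))
}

#' Validate a Paas mental-effort rating
#'
#' @param rating Single integer 1-9 (9-point mental-effort scale).
#' @return The rating as integer.
#' @export
paas_score <- function(rating) {
  if (length(rating) != 1L) abort_input("Paas is a single-item scale")
  check_rating(rating, 1L, 9L, "Paas")
}

#' Score the Naiive cognitive-load subscales
#'
#' @param intrinsic Two ratings 1-7 (intrinsic load items).
#' @param extraneous Three ratings 1-7 (extraneous load items).
#' @return Named numeric vector `c(intrinsic = ..., extraneous = ...)` of
#'   subscale means, each in `[1, 7]`.
#' @export
naiive_subscales <- function(intrinsic, extraneous) {
  if (length(intrinsic) != 2L) abort_input("Naiive intrinsic subscale has 2 items")
  if (length(extraneous) != 3L) abort_input("Naiive extraneous subscale has 3 items")
  ii <- check_rating(intrinsic, 1L, 7L, "Naiive intrinsic")
  ee <- check_rating(extraneous, 1L, 7L, "Naiive extraneous")
  c(intrinsic = mean(ii), extraneous = mean(ee))
}

#' Descriptive summary of a score vector
#'
#' @param scores Non-empty numeric vector.
#' @return Named list `n`, `mean`, `sd` (sample SD, n-1 denominator;
#'   0 by convention for a single observation), `min`, `max`.
#' @export
summarize_scores <- function(scores) {
  if (!length(scores) || !is.numeric(scores) || anyNA(scores)) {
    abort_input("scores must be a non-empty numeric vector without NAs")
  }
  s <- if (length(scores) > 1L) stats::sd(scores) else 0
  list(n = length(scores), mean = mean(scores), sd = s,
       min = min(scores), max = max(scores))
}

#' Score a questionnaire CSV
#'
#' Reads one respondent per row with columns `sus_1`..`sus_10`, `paas`,
#' `naiive_int_1`, `naiive_int_2`, `naiive_ext_1`..`naiive_ext_3`, scores
#' every instrument, and returns both per-respondent scores and a
#' descriptive summary table (one row per scale: N, Mean, SD, Min, Max).
#'
#' @param path Path to the questionnaire CSV.
#' @return List with `scores` (data.frame, one row per respondent) and
#'   `summary` (data.frame, one row per scale).
#' @export
score_questionnaires <- function(path) {
  if (!file.exists(path)) abort_input("questionnaire file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(paste0("sus_", 1:10), "paas",
            paste0("naiive_int_", 1:2), paste0("naiive_ext_", 1:3))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_input("questionnaire CSV lacks column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) abort_input("questionnaire CSV has no respondents")
  scores <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    sus <- sus_score(as.numeric(df[i, paste0("sus_", 1:10)]))
    paas <- paas_score(as.numeric(df[i, "paas"]))
    nv <- naiive_subscales(as.numeric(df[i, paste0("naiive_int_", 1:2)]),
                           as.numeric(df[i, paste0("naiive_ext_", 1:3)]))
    data.frame(respondent = i, sus = sus, paas = paas,
               naiive_intrinsic = nv[["intrinsic"]],
               naiive_extraneous = nv[["extraneous"]])
  }))
  summary_row <- function(name, x) {
    s <- summarize_scores(x)
    data.frame(scale = name, n = s$n, mean = s$mean, sd = s$sd,
               min = s$min, max = s$max)
  }
  summary <- rbind(summary_row("SUS", scores$sus),
                   summary_row("Paas", scores$paas),
                   summary_row("Naiive intrinsic", scores$naiive_intrinsic),
                   summary_row("Naiive extraneous", scores$naiive_extraneous))
  list(scores = scores, summary = summary)
}
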