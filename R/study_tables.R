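# Printed per-category outcome breakdowns from a published evaluation of
# the HIrisPlex-S system in a Spanish population cohort (412 individuals;
# 378/380/408 usable for eye/hair/skin).  The raw genotype data of that
# study are not distributable, but the printed percentages per observed
# category, together with the category sample sizes, determine the
# underlying integer counts exactly — which is what these tables carry.
#
# `predicted` holds the call implied by each printed sub-breakdown
# ("a/b" = compound); `status` distinguishes definitive calls, undefined
# compound calls (eye 0.5-0.7 band), empty undefined predictions (skin)
# and unassignable individuals.

#' Printed per-category prediction outcome breakdowns
#'
#' Reference breakdown tables from a published Spanish-population
#' evaluation of HIrisPlex-S pigmentation prediction, one row per
#' (observed category, predicted outcome) cell with its printed percentage.
#' These printed breakdowns, with the per-category sample sizes, pin down
#' the underlying integer counts, so the package can rebuild the study's
#' match tables and contingency-table metrics exactly (see
#' [expand_breakdown()] and [reproduce_tables()]).
#'
#' @param trait `"eye"`, `"hair"` or `"skin"`.
#' @param mode `"strict"` or `"flexible"` (hair was scored one way only;
#'   the mode is ignored for it).
#' @return Tibble: `observed`, `n` (observed-category sample size),
#'   `outcome` (`correct`, `incorrect`, `uncertain`, `undefined`, `na`),
#'   `predicted` (label string, `NA` for empty predictions), `status`,
#'   `pct` (printed percentage, 0-100).
#' @export
study_breakdown <- function(trait = c("eye", "hair", "skin"),
                            mode = c("strict", "flexible")) {
  trait <- match.arg(trait)
  mode <- match.arg(mode)
  if (trait == "eye" && mode == "strict") {
    tibble::tribble(
      ~observed,      ~n,   ~outcome,    ~predicted,            ~status,      ~pct,
      "blue",         32L,  "correct",   "blue",                "definitive", 93.75,
      "blue",         32L,  "incorrect", "intermediate",        "definitive", 3.13,
      "blue",         32L,  "uncertain", "intermediate/brown",  "undefined",  3.33,
      "intermediate", 86L,  "correct",   "intermediate",        "definitive", 10.47,
      "intermediate", 86L,  "incorrect", "blue",                "definitive", 15.12,
      "intermediate", 86L,  "incorrect", "brown",               "definitive", 51.16,
      "intermediate", 86L,  "uncertain", "intermediate/brown",  "undefined",  20.93,
      "intermediate", 86L,  "uncertain", "intermediate/blue",   "undefined",  2.33,
      "brown",        260L, "correct",   "brown",               "definitive", 88.08,
      "brown",        260L, "incorrect", "blue",                "definitive", 0.38,
      "brown",        260L, "incorrect", "intermediate",        "definitive", 1.54,
      "brown",        260L, "uncertain", "intermediate/brown",  "undefined",  8.85,
      "brown",        260L, "uncertain", "intermediate/blue",   "undefined",  0.38,
      "brown",        260L, "na",        NA_character_,         "NA",         0.77
    )
  } else if (trait == "eye") {
    tibble::tribble(
      ~observed,      ~n,   ~outcome,    ~predicted, ~status, ~pct,
      "blue",         32L,  "correct",   "blue",   "definitive", 93.75,
      "blue",         32L,  "incorrect", NA,       "definitive", 6.25,
      "intermediate", 86L,  "correct",   NA,       "definitive", 33.72,
      "intermediate", 86L,  "incorrect", NA,       "definitive", 66.28,
      "brown",        260L, "correct",   "brown",  "definitive", 96.92,
      "brown",        260L, "incorrect", NA,       "definitive", 2.31,
      "brown",        260L, "na",        NA,       "NA",         0.77
    )
  } else if (trait == "hair") {
    tibble::tribble(
      ~observed, ~n,   ~outcome,    ~predicted, ~status,      ~pct,
      "blond",   37L,  "correct",   "blond",    "definitive", 43.24,
      "blond",   37L,  "incorrect", "red",      "definitive", 2.70,
      "blond",   37L,  "incorrect", "brown",    "definitive", 54.05,
      "red",     1L,   "incorrect", "brown",    "definitive", 100,
      "brown",   245L, "correct",   "brown",    "definitive", 96.33,
      "brown",   245L, "incorrect", "blond",    "definitive", 2.45,
      "brown",   245L, "incorrect", "red",      "definitive", 1.22,
      "black",   97L,  "correct",   "black",    "definitive", 44.33,
      "black",   97L,  "incorrect", "blond",    "definitive", 2.06,
      "black",   97L,  "incorrect", "red",      "definitive", 2.06,
      "black",   97L,  "incorrect", "brown",    "definitive", 51.55
    )
  } else if (mode == "strict") {
    tibble::tribble(
      ~observed,      ~n,   ~outcome,    ~predicted,      ~status,      ~pct,
      "dark",         28L,  "correct",   "dark",          "definitive", 39.29,
      "dark",         28L,  "incorrect", "intermediate",  "definitive", 50,
      "dark",         28L,  "incorrect", "dark_black",    "definitive", 7.14,
      "dark",         28L,  "undefined", NA_character_,   "undefined",  3.57,
      "intermediate", 162L, "correct",   "intermediate",  "definitive", 67.90,
      "intermediate", 162L, "incorrect", "pale",          "definitive", 1.23,
      "intermediate", 162L, "incorrect", "dark",          "definitive", 12.96,
      "intermediate", 162L, "incorrect", "dark_black",    "definitive", 3.70,
      "intermediate", 162L, "undefined", NA_character_,   "undefined",  14.20,
      "pale",         218L, "incorrect", "very_pale",     "definitive", 0.92,
      "pale",         218L, "incorrect", "intermediate",  "definitive", 75.23,
      "pale",         218L, "incorrect", "dark",          "definitive", 5.50,
      "pale",         218L, "incorrect", "dark_black",    "definitive", 3.67,
      "pale",         218L, "undefined", NA_character_,   "undefined",  14.68
    )
  } else {
    tibble::tribble(
      ~observed,      ~n,   ~outcome,    ~predicted,      ~status,      ~pct,
      "dark",         28L,  "correct",   "dark",          "definitive", 53.57,
      "dark",         28L,  "incorrect", "intermediate",  "definitive", 39.29,
      "dark",         28L,  "incorrect", "dark_black",    "definitive", 3.57,
      "dark",         28L,  "undefined", NA_character_,   "undefined",  3.57,
      "intermediate", 162L, "correct",   "intermediate",  "definitive", 70.37,
      "intermediate", 162L, "incorrect", "dark",          "definitive", 12.96,
      "intermediate", 162L, "incorrect", "dark_black",    "definitive", 2.47,
      "intermediate", 162L, "undefined", NA_character_,   "undefined",  14.20,
      "pale",         218L, "correct",   "pale",          "definitive", 0.92,
      "pale",         218L, "incorrect", "intermediate",  "definitive", 75.23,
      "pale",         218L, "incorrect", "dark",          "definitive", 5.50,
      "pale",         218L, "incorrect", "dark_black",    "definitive", 3.67,
      "pale",         218L, "undefined", NA_character_,   "undefined",  14.68
    )
  }
}

#' Rebuild individual match records from a printed breakdown
#'
#' Converts each (observed category, outcome, percentage) row of a
#' breakdown table into the implied integer count of individuals (the
#' printed percentage times the category size must land within 0.5 of an
#' integer, absorbing printed rounding) and expands it into one record per
#' individual, in the call-table format of [call_phenotypes()] with the
#' observed category attached.
#'
#' @param breakdown Tibble from [study_breakdown()] (same columns).
#' @param trait Trait label to stamp on the records.
#' @return Tibble: `sample_id`, `trait`, `labels`, `status`, `observed`;
#'   one row per individual.
#' @export
expand_breakdown <- function(breakdown, trait = NULL) {
  trait <- trait %||% infer_trait(breakdown$observed)
  counts <- as.integer(round(breakdown$pct / 100 * breakdown$n))
  # the rounded count must reproduce the printed percentage within the
  # 0.5-point printing window, else the row is internally inconsistent
  off <- abs(breakdown$pct - 100 * counts / breakdown$n)
  if (any(off > 0.5)) {
    bad <- which(off > 0.5)[1]
    stop("non-integral implied count for observed ", breakdown$observed[bad],
         " / ", breakdown$outcome[bad], ": ",
         format(breakdown$pct[bad] / 100 * breakdown$n[bad]))
  }
  idx <- rep(seq_len(nrow(breakdown)), counts)
  out <- tibble::tibble(
    sample_id = sprintf("R%04d", seq_along(idx)),
    trait = trait,
    labels = breakdown$predicted[idx],
    status = breakdown$status[idx],
    observed = breakdown$observed[idx]
  )
  # categories with zero rows surviving (N = 0) are fine: empty records
  out
}

infer_trait <- function(observed) {
  for (trait in c("hair", "skin", "eye")) {
    if (all(observed %in% trait_levels(trait))) return(trait)
  }
  stop("cannot infer trait from observed categories")
}

#' Rebuild the study's match tables and metrics from printed breakdowns
#'
#' Runs the full reconstruction chain on the bundled breakdown tables:
#' expands the strict eye breakdown into individual records, rescores it
#' under the flexible rule (reproducing the printed flexible table), and
#' derives the contingency-table metrics for eye (flexible) and hair.
#'
#' @return A named list of tibbles: `eye_strict` and `eye_flexible`
#'   per-category outcome summaries, `eye_metrics`, `hair_metrics`, and
#'   `checks` — a two-column tibble (`quantity`, `value`) of the headline
#'   reconstructed values (percent scale).
#' @export
#' @examples
#' reproduce_tables()$checks
reproduce_tables <- function() {
  eye_records <- expand_breakdown(study_breakdown("eye", "strict"))
  eye_strict <- classify_match(
    eye_records[, c("sample_id", "trait", "labels", "status")],
    eye_records$observed, mode = "strict")
  eye_flex <- classify_match(
    eye_records[, c("sample_id", "trait", "labels", "status")],
    eye_records$observed, mode = "flexible")
  eye_metrics <- concordance_metrics(eye_flex)

  hair_records <- expand_breakdown(study_breakdown("hair"))
  hair_match <- classify_match(
    hair_records[, c("sample_id", "trait", "labels", "status")],
    hair_records$observed, mode = "flexible")
  hair_metrics <- concordance_metrics(hair_match)

  pick <- function(metrics, cat, col) {
    100 * metrics[[col]][metrics$category == cat]
  }
  flex_sum <- summarize_matches(eye_flex)
  checks <- tibble::tribble(
    ~quantity, ~value,
    "eye_intermediate_flexible_correct_pct",
      flex_sum$correct[flex_sum$observed == "intermediate"],
    "eye_blue_flexible_incorrect_pct",
      flex_sum$incorrect[flex_sum$observed == "blue"],
    "eye_brown_flexible_correct_pct",
      flex_sum$correct[flex_sum$observed == "brown"],
    "eye_blue_ppv_pct", pick(eye_metrics, "blue", "ppv"),
    "eye_blue_specificity_pct", pick(eye_metrics, "blue", "specificity"),
    "eye_blue_sensitivity_pct", pick(eye_metrics, "blue", "sensitivity"),
    "eye_brown_sensitivity_pct", pick(eye_metrics, "brown", "sensitivity"),
    "eye_brown_specificity_pct", pick(eye_metrics, "brown", "specificity"),
    "eye_intermediate_ppv_pct", pick(eye_metrics, "intermediate", "ppv"),
    "eye_intermediate_npv_pct", pick(eye_metrics, "intermediate", "npv"),
    "hair_black_npv_pct", pick(hair_metrics, "black", "npv"),
    "hair_black_ppv_pct", pick(hair_metrics, "black", "ppv"),
    "hair_black_specificity_pct", pick(hair_metrics, "black", "specificity")
  )
  list(
    eye_strict = summarize_matches(eye_strict),
    eye_flexible = flex_sum,
    eye_metrics = eye_metrics,
    hair_metrics = hair_metrics,
    checks = checks
  )
}
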