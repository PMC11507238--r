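#' Score calls against observed phenotypes
#'
#' Compares each phenotype call with the observed category and classifies
#' the match.  Under the strict approach a compound call with status
#' `"undefined"` (eye 0.5-0.7 band) is an *uncertain* match; definitive
#' calls are correct when the observed category is among the predicted
#' labels and incorrect otherwise.  Under the flexible approach undefined
#' compound calls are rescored by the same membership rule ("at least one
#' predicted colour included in the actual colour"), so uncertain matches
#' disappear.  Empty undefined calls (skin with no dominant tone) stay
#' *undefined* matches in both modes; `NA` calls and unknown observed
#' phenotypes give `NA` matches.
#'
#' A single resolved category per individual is also derived for building
#' two-by-two contingency tables (see [resolve_label()]).
#'
#' @param calls Call tibble from [call_phenotypes()] (columns `sample_id`,
#'   `trait`, `labels`, `status`).
#' @param observed Phenotype tibble (joined on `sample_id`) or a character
#'   vector aligned with `calls`.
#' @param mode `"strict"` or `"flexible"`.
#' @return `calls` with added columns `observed`, `match` (`correct`,
#'   `incorrect`, `uncertain`, `undefined`, `NA`) and `resolved`.
#' @export
classify_match <- function(calls, observed, mode = c("strict", "flexible")) {
  mode <- match.arg(mode)
  trait <- calls$trait[1]
  obs <- if (is.data.frame(observed)) {
    observed[[trait]][match(calls$sample_id, observed$sample_id)]
  } else {
    stopifnot(length(observed) == nrow(calls))
    observed
  }
  obs[!is.na(obs) & obs == "unknown"] <- NA_character_
  bad <- !is.na(obs) & !obs %in% trait_levels(trait)
  if (any(bad)) stop("unknown observed category: ", obs[which(bad)[1]])
  labels <- strsplit(ifelse(is.na(calls$labels), "", calls$labels), "/", fixed = TRUE)
  match_v <- character(nrow(calls))
  resolved <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    st <- calls$status[i]
    lab <- labels[[i]]
    if (st == "NA" || is.na(obs[i])) {
      match_v[i] <- "NA"
      next
    }
    if (st == "undefined" && length(lab) == 0) {
      match_v[i] <- "undefined"
      next
    }
    if (mode == "strict" && st == "undefined") {
      match_v[i] <- "uncertain"
      next
    }
    hit <- obs[i] %in% lab
    match_v[i] <- if (hit) "correct" else "incorrect"
    resolved[i] <- if (hit) obs[i] else lab[1]
  }
  dplyr::bind_cols(calls, tibble::tibble(observed = obs, match = match_v,
                                         resolved = resolved))
}

#' Resolve a (possibly compound) call to a single category
#'
#' Compound calls contribute a single category to the contingency tables:
#' the observed category when it is among the predicted labels, otherwise
#' the call's leading label (for eye compounds that is the intermediate
#' component, so an intermediate-brown call for a blue-eyed individual
#' counts as an intermediate prediction).
#'
#' @param labels Character vector of call label strings (`"a/b"` compounds).
#' @param observed Observed categories, same length.
#' @return Character vector of single categories.
#' @export
#' @examples
#' resolve_label("intermediate/brown", "brown")  # "brown"
#' resolve_label("intermediate/brown", "blue")   # "intermediate"
resolve_label <- function(labels, observed) {
  purrr::map2_chr(strsplit(labels, "/", fixed = TRUE), observed, function(lab, obs) {
    if (length(lab) == 0 || all(is.na(lab))) return(NA_character_)
    if (!is.na(obs) && obs %in% lab) obs else lab[1]
  })
}

#' Two-by-two contingency counts per category
#'
#' Builds per-category TP/FP/FN/TN counts from scored match records, using
#' each record's resolved single category.  `NA`, undefined and (strict)
#' uncertain records carry no resolved category and are excluded from all
#' four cells; their counts are reported alongside.
#'
#' @param matches Scored tibble from [classify_match()].
#' @param levels Category vocabulary (default: the trait's).
#' @return Tibble: `category`, `tp`, `fp`, `fn`, `tn`, plus constant
#'   columns `n_na`, `n_undefined`, `n_uncertain`, `n_scored`.
#' @export
confusion_counts <- function(matches, levels = NULL) {
  trait <- matches$trait[1]
  levels <- levels %||% trait_levels(trait)
  scored <- matches[!is.na(matches$resolved), ]
  n_scored <- nrow(scored)
  purrr::map_dfr(levels, function(cat) {
    tp <- sum(scored$observed == cat & scored$resolved == cat)
    fp <- sum(scored$observed != cat & scored$resolved == cat)
    fn <- sum(scored$observed == cat & scored$resolved != cat)
    tibble::tibble(category = cat, tp = tp, fp = fp, fn = fn,
                   tn = n_scored - tp - fp - fn)
  }) |>
    dplyr::mutate(
      n_na = sum(matches$match == "NA"),
      n_undefined = sum(matches$match == "undefined"),
      n_uncertain = sum(matches$match == "uncertain"),
      n_scored = n_scored
    )
}

#' Per-category prediction performance metrics
#'
#' The contingency-table metric suite: sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`, and
#' accuracy as the fraction of correct matches among all individuals
#' observed in the category — including unassignable (`NA`-call)
#' individuals, which the cell counts exclude.  One-vs-rest AUC is added
#' when a probability table is supplied.  Zero denominators give `NA`,
#' never an error.
#'
#' @param matches Scored tibble from [classify_match()].
#' @param levels Category vocabulary (default: the trait's).
#' @param probs Optional probability tibble (as from [predict.mlr_fit()])
#'   for the same samples, used to compute per-category AUC.
#' @return Tibble: one row per category with `n_observed`, cell counts and
#'   `accuracy`, `auc`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   (proportions in `[0, 1]`).
#' @export
concordance_metrics <- function(matches, levels = NULL, probs = NULL) {
  trait <- matches$trait[1]
  levels <- levels %||% trait_levels(trait)
  cells <- confusion_counts(matches, levels)
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  out <- purrr::map_dfr(levels, function(cat) {
    row <- cells[cells$category == cat, ]
    in_cat <- matches$observed == cat & !is.na(matches$observed)
    tibble::tibble(
      category = cat,
      n_observed = sum(in_cat),
      tp = row$tp, fp = row$fp, fn = row$fn, tn = row$tn,
      accuracy = safe_div(sum(in_cat & matches$match == "correct"), sum(in_cat)),
      auc = if (is.null(probs)) NA_real_ else {
        p <- probs[[cat]][match(matches$sample_id, probs$sample_id)]
        keep <- !is.na(p) & !is.na(matches$observed)
        if (!any(keep) || length(unique(in_cat[keep])) < 2) NA_real_
        else roc_auc(p[keep], in_cat[keep])
      },
      sensitivity = safe_div(row$tp, row$tp + row$fn),
      specificity = safe_div(row$tn, row$tn + row$fp),
      ppv = safe_div(row$tp, row$tp + row$fp),
      npv = safe_div(row$tn, row$tn + row$fn)
    )
  })
  out
}

#' Summarise matches as a per-category outcome table
#'
#' Tabulates, for each observed category, the percentage of correct,
#' incorrect, uncertain, undefined and unassigned (`NA`) matches — the
#' presentation used for reporting calling performance per observed
#' phenotype.
#'
#' @param matches Scored tibble from [classify_match()].
#' @return Tibble: `observed`, `n`, and percentage columns
#'   `correct`, `incorrect`, `uncertain`, `undefined`, `na` (0-100 scale).
#' @export
summarize_matches <- function(matches) {
  trait <- matches$trait[1]
  kept <- matches[!is.na(matches$observed), ]
  kept |>
    dplyr::group_by(observed = .data$observed) |>
    dplyr::summarise(
      n = dplyr::n(),
      correct = 100 * mean(.data$match == "correct"),
      incorrect = 100 * mean(.data$match == "incorrect"),
      uncertain = 100 * mean(.data$match == "uncertain"),
      undefined = 100 * mean(.data$match == "undefined"),
      na = 100 * mean(.data$match == "NA"),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$observed, trait_levels(trait)))
}
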