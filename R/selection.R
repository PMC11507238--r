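#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, counting ties as one half.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param positive Logical vector marking the positive class.
#' @return The AUC in `[0, 1]`, or `NA` (with a warning) when either class
#'   is empty.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
roc_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  keep <- !is.na(scores) & !is.na(positive)
  scores <- scores[keep]
  positive <- as.logical(positive[keep])
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) {
    warning("degenerate class: AUC undefined")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Forward stepwise predictor selection by AIC
#'
#' Starts from an intercept-only model and greedily adds, at each step, the
#' candidate marker that lowers AIC the most, stopping when no addition
#' improves AIC.  Ties are broken by candidate order, so the procedure is
#' deterministic given the data.  All candidate models are fitted on the
#' samples complete for every candidate, keeping AICs comparable.
#'
#' @inheritParams fit_mlr
#' @param candidates Character vector of candidate rsIDs.
#' @param max_steps Optional cap on the number of predictors added.
#' @return An object of class `mlr_selection` with the final `mlr_fit`,
#'   the selected predictors in inclusion order, and a `trace` tibble
#'   (step, added marker, AIC).  Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
forward_select <- function(genotypes, phenotypes, trait, candidates,
                           ref = NULL, exclude = NULL, max_steps = Inf) {
  stopifnot(length(candidates) >= 1)
  y <- align_phenotype(genotypes, phenotypes, trait)
  ok <- !is.na(y) & y != "unknown" & !y %in% exclude &
    stats::complete.cases(as.matrix(genotypes[, candidates, drop = FALSE]))
  g <- genotypes[ok, , drop = FALSE]
  yv <- y[ok]
  fit0 <- fit_mlr(g, yv, trait, predictors = character(0), ref = ref)
  selected <- character(0)
  current_aic <- 2 * fit0$n_params - 2 * fit0$log_lik
  trace <- tibble::tibble(step = 0L, added = NA_character_, aic = current_aic)
  best_fit <- fit0
  repeat {
    if (length(selected) >= min(max_steps, length(candidates))) break
    remaining <- setdiff(candidates, selected)
    aics <- vapply(remaining, function(m) {
      f <- suppressWarnings(fit_mlr(g, yv, trait, predictors = c(selected, m), ref = ref))
      2 * f$n_params - 2 * f$log_lik
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= current_aic) break
    selected <- c(selected, remaining[best])
    current_aic <- aics[best]
    best_fit <- suppressWarnings(fit_mlr(g, yv, trait, predictors = selected, ref = ref))
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = length(selected), added = remaining[best], aic = current_aic))
  }
  structure(
    list(trait = trait, selected = selected, fit = best_fit,
         trace = trace, candidates = candidates, n = best_fit$n),
    class = "mlr_selection"
  )
}

#' @export
print.mlr_selection <- function(x, ...) {
  cat("Forward AIC selection for", x$trait, "colour\n")
  cat("  candidates:", length(x$candidates), " selected:", length(x$selected), "\n")
  if (length(x$selected)) cat("  order:", paste(x$selected, collapse = " > "), "\n")
  cat(sprintf("  final AIC: %.2f (empty model %.2f)\n",
              x$trace$aic[nrow(x$trace)], x$trace$aic[1]))
  invisible(x)
}

#' @rdname pigmentr-tidiers
#' @export
tidy.mlr_selection <- function(x, ...) x$trace

#' @rdname pigmentr-tidiers
#' @export
glance.mlr_selection <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$candidates),
    n_selected = length(x$selected),
    aic_start = x$trace$aic[1],
    aic_final = x$trace$aic[nrow(x$trace)],
    nobs = x$n
  )
}

#' Repeated stratified k-fold cross-validation of a pigmentation model
#'
#' For each repeat, samples are assigned to folds stratified by phenotype
#' category; each fold is held out once, the model refitted on the rest,
#' and held-out probabilities collected.  Per-category one-vs-rest AUCs are
#' then either pooled over each repeat's full set of held-out predictions
#' (`pool = "repeat"`, the default — stable for rare categories) or
#' computed per fold and averaged, skipping folds lacking the category
#' (`pool = "fold"`).  All randomness flows from `seed`.
#'
#' @inheritParams fit_mlr
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats (default 10).
#' @param seed Integer seed for the fold assignments.
#' @param pool `"repeat"` or `"fold"` AUC aggregation.
#' @return An object of class `mlr_cv`: `auc` tibble (category, mean AUC),
#'   `per_repeat` tibble of the underlying values, and the settings.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
cross_validate <- function(genotypes, phenotypes, trait, predictors,
                           folds = 10, repeats = 10, seed = 1,
                           ref = NULL, exclude = NULL,
                           pool = c("repeat", "fold")) {
  pool <- match.arg(pool)
  y <- align_phenotype(genotypes, phenotypes, trait)
  Xok <- stats::complete.cases(as.matrix(genotypes[, predictors, drop = FALSE]))
  ok <- !is.na(y) & y != "unknown" & !y %in% exclude & Xok
  g <- genotypes[ok, , drop = FALSE]
  yv <- y[ok]
  n <- length(yv)
  stopifnot(n >= folds)
  cats <- intersect(trait_levels(trait), unique(yv))
  per <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      fold_id <- stratified_folds(yv, folds)
      held <- matrix(NA_real_, n, length(cats), dimnames = list(NULL, cats))
      for (f in seq_len(folds)) {
        test <- fold_id == f
        fit <- suppressWarnings(
          fit_mlr(g[!test, , drop = FALSE], yv[!test], trait,
                  predictors = predictors, ref = ref)
        )
        pr <- predict(fit, g[test, , drop = FALSE])
        for (cat in cats) {
          held[test, cat] <- if (cat %in% names(pr)) pr[[cat]] else 0
        }
      }
      if (pool == "repeat") {
        purrr::map_dfr(cats, function(cat) tibble::tibble(
          repeat_id = r, category = cat,
          auc = suppressWarnings(roc_auc(held[, cat], yv == cat))))
      } else {
        purrr::map_dfr(cats, function(cat) {
          vals <- vapply(seq_len(folds), function(f) {
            test <- fold_id == f
            if (length(unique(yv[test] == cat)) < 2) return(NA_real_)
            roc_auc(held[test, cat], yv[test] == cat)
          }, numeric(1))
          tibble::tibble(repeat_id = r, category = cat, auc = mean(vals, na.rm = TRUE))
        })
      }
    })
  })
  auc <- per |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(auc = mean(.data$auc, na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(match(.data$category, trait_levels(trait)))
  structure(
    list(trait = trait, auc = auc, per_repeat = per, folds = folds,
         repeats = repeats, seed = seed, pool = pool, n = n,
         predictors = predictors),
    class = "mlr_cv"
  )
}

# Stratified fold assignment: within each category, shuffle and deal fold
# labels round-robin so every fold gets its share of rare categories.
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cat in unique(y)) {
    idx <- sample(which(y == cat))
    fold_id[idx] <- rep_len(sample(folds), length(idx))
  }
  fold_id
}

#' @export
print.mlr_cv <- function(x, ...) {
  cat(sprintf("Repeated %d-fold cross-validation (%d repeats, seed %d) for %s colour\n",
              x$folds, x$repeats, x$seed, x$trait))
  cat(sprintf("  n = %d, predictors = %d, AUC pooled per %s\n",
              x$n, length(x$predictors), x$pool))
  print(x$auc)
  invisible(x)
}

#' @rdname pigmentr-tidiers
#' @export
tidy.mlr_cv <- function(x, ...) x$auc

#' @rdname pigmentr-tidiers
#' @export
glance.mlr_cv <- function(x, ...) {
  tibble::tibble(
    folds = x$folds, repeats = x$repeats, nobs = x$n,
    mean_auc = mean(x$auc$auc, na.rm = TRUE)
  )
}
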