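#' Run the full pigmentation-prediction analysis
#'
#' Orchestrates, per trait: population-genetic QC, optional forward AIC
#' marker selection, repeated stratified cross-validation of the working
#' model, a final fit, probability prediction with mean-dosage imputation
#' (required markers excepted), threshold calling, concordance scoring
#' against the observed phenotypes, and the per-category metric suite.
#'
#' Exactly one of (`genotypes` + `phenotypes`) or `sim` must be supplied:
#' either observed data (tibbles or file paths in the package dialect) or
#' a [cohort_spec()] to simulate.  Identical inputs and `seed` give an
#' identical result bundle.
#'
#' @param genotypes Genotype tibble or file path (see [read_genotypes()]).
#' @param phenotypes Phenotype tibble or file path.
#' @param sim A [cohort_spec()] to generate the cohort instead.
#' @param traits Traits to analyse (default all three).
#' @param mode Calling mode, `"strict"` or `"flexible"`.
#' @param thresholds A [calling_thresholds()] object.
#' @param select Run forward AIC selection and use the selected markers
#'   for CV and the final model (default `TRUE`; the full panel is used
#'   when `FALSE`).
#' @param folds,repeats Cross-validation settings.
#' @param seed Seed for all randomness (CV folds; the simulation uses the
#'   spec's own seed).
#' @param exclude Named list of categories to exclude from modelling per
#'   trait; default drops red hair, whose representation is too small to
#'   model (its observed marginal is ~0.26%).
#' @param reference Optional reference allele-frequency tibble for the QC
#'   comparison (see [compare_frequencies()]).
#' @param out_dir Optional directory; each result tibble is also written
#'   there as a TSV.
#' @return A named list of class `pigment_run`: per-trait list with
#'   `qc`, `selection`, `cv`, `fit`, `probs`, `calls`, `matches`,
#'   `match_summary`, `metrics`, `log`.
#' @export
run_pipeline <- function(genotypes = NULL, phenotypes = NULL, sim = NULL,
                         traits = c("eye", "hair", "skin"),
                         mode = c("flexible", "strict"),
                         thresholds = calling_thresholds(),
                         select = TRUE, folds = 10, repeats = 10, seed = 1,
                         exclude = list(hair = "red"),
                         reference = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  have_data <- !is.null(genotypes) || !is.null(phenotypes)
  if (have_data == !is.null(sim)) {
    stop("supply either genotypes+phenotypes or a simulation spec, not both")
  }
  if (!is.null(sim)) {
    cohort <- generate_cohort(sim)
    genotypes <- cohort$genotypes
    phenotypes <- cohort$phenotypes
  } else {
    if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
    if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  }
  traits <- match.arg(traits, c("eye", "hair", "skin"), several.ok = TRUE)
  result <- list()
  for (trait in traits) {
    panel <- pigment_panel(trait)
    panel_geno <- genotypes[, c("sample_id", intersect(panel$rsid, names(genotypes)))]
    qc <- qc_report(panel_geno, reference = reference)
    usable <- qc$rsid[qc$n > 0]
    failed <- setdiff(panel$rsid, usable)
    excl <- exclude[[trait]]
    log <- c(
      sprintf("trait=%s n_samples=%d markers=%d usable=%d failed=%d",
              trait, nrow(genotypes), nrow(panel), length(usable), length(failed)),
      if (length(failed)) paste("failed markers:", paste(failed, collapse = ", "))
    )
    selection <- NULL
    predictors <- usable
    if (select) {
      selection <- forward_select(genotypes, phenotypes, trait,
                                  candidates = usable, exclude = excl)
      predictors <- selection$selected
      if (length(predictors) == 0) predictors <- usable
      log <- c(log, sprintf("forward selection kept %d of %d markers",
                            length(selection$selected), length(usable)))
    }
    cv <- cross_validate(genotypes, phenotypes, trait, predictors,
                         folds = folds, repeats = repeats, seed = seed,
                         exclude = excl)
    fit <- suppressWarnings(
      fit_mlr(genotypes, phenotypes, trait, predictors, exclude = excl))
    log <- c(log, sprintf("final fit: n=%d dropped=%d AIC=%.2f converged=%s",
                          fit$n, fit$n_dropped, 2 * fit$n_params - 2 * fit$log_lik,
                          fit$converged))
    probs <- predict(fit, genotypes, impute = "mean")
    calls <- call_phenotypes(probs, trait, mode = mode, thresholds = thresholds)
    matches <- classify_match(calls, phenotypes, mode = mode)
    result[[trait]] <- list(
      qc = qc, selection = selection, cv = cv, fit = fit, probs = probs,
      calls = calls, matches = matches,
      match_summary = summarize_matches(matches),
      metrics = concordance_metrics(matches, probs = probs),
      log = log
    )
  }
  out <- structure(result, class = "pigment_run",
                   mode = mode, seed = seed)
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (trait in names(run)) {
    parts <- run[[trait]]
    tabs <- list(
      qc = parts$qc,
      selection_trace = if (!is.null(parts$selection)) parts$selection$trace,
      cv_auc = parts$cv$auc,
      calls = parts$calls,
      match_summary = parts$match_summary,
      metrics = parts$metrics
    )
    for (nm in names(tabs)) {
      if (is.null(tabs[[nm]])) next
      readr::write_tsv(tabs[[nm]], file.path(out_dir, paste0(trait, "_", nm, ".tsv")))
    }
    writeLines(parts$log, file.path(out_dir, paste0(trait, "_log.txt")))
  }
  invisible(out_dir)
}

#' @export
print.pigment_run <- function(x, ...) {
  cat("Pigmentation prediction run (mode:", attr(x, "mode"),
      "seed:", attr(x, "seed"), ")\n")
  for (trait in names(x)) {
    cat("\n==", trait, "==\n")
    writeLines(paste(" ", x[[trait]]$log))
    print(x[[trait]]$match_summary)
  }
  invisible(x)
}
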