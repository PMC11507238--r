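# Multinomial logistic regression on effect-allele dosages.
#
# The log-likelihood is concave, so a quasi-Newton search started at zero
# with the analytic gradient is deterministic and reaches the global
# maximum whenever one exists.  Complete separation (likelihood maximised
# only as coefficients diverge) is detected by a coefficient-magnitude cap.

rowmax <- function(M) M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]

mlr_nll <- function(beta, X, yidx, K) {
  P <- ncol(X)
  B <- matrix(beta, nrow = K - 1, ncol = P)
  eta <- cbind(0, X %*% t(B))               # n x K, reference in column 1
  m <- rowmax(eta)
  lse <- m + log(rowSums(exp(eta - m)))
  -sum(eta[cbind(seq_along(yidx), yidx)] - lse)
}

mlr_grad <- function(beta, X, yidx, K) {
  P <- ncol(X)
  B <- matrix(beta, nrow = K - 1, ncol = P)
  eta <- cbind(0, X %*% t(B))
  m <- rowmax(eta)
  Pr <- exp(eta - m) / rowSums(exp(eta - m))
  g <- matrix(0, K - 1, P)
  for (k in 2:K) {
    g[k - 1, ] <- crossprod(X, Pr[, k] - (yidx == k))
  }
  as.vector(g)
}

mlr_optimize <- function(X, yidx, K, max_coef = 15, maxit = 1000) {
  npar <- (K - 1) * ncol(X)
  fit <- optim(rep(0, npar), fn = mlr_nll, gr = mlr_grad,
               X = X, yidx = yidx, K = K, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-14))
  beta <- fit$par
  grad <- mlr_grad(beta, X, yidx, K)
  separated <- max(abs(beta)) > max_coef
  if (separated) {
    beta <- pmin(pmax(beta, -max_coef), max_coef)
    warning("apparent complete separation: coefficients capped at +/-",
            max_coef, "; fit flagged as not converged")
  }
  list(
    beta = matrix(beta, nrow = K - 1, ncol = ncol(X)),
    log_lik = -mlr_nll(beta, X, yidx, K),
    converged = !separated && max(abs(grad)) < 1e-4 * max(1, length(yidx) / 100),
    grad_norm = max(abs(grad))
  )
}

#' Fit a multinomial logistic regression pigmentation model
#'
#' Fits category log-odds as linear functions of effect-allele dosages,
#' maximising the multinomial log-likelihood (quasi-Newton from a zero
#' start; the problem is convex so the fit is deterministic).  Samples with
#' a missing predictor dosage or an `"unknown"` phenotype are dropped and
#' counted.  Complete separation is handled by capping coefficients at
#' `max_coef` and flagging the fit unconverged.
#'
#' @param genotypes Genotype tibble (`sample_id` + dosage columns).
#' @param phenotypes Phenotype tibble (`sample_id` + trait columns), or a
#'   character vector aligned with `genotypes` rows.
#' @param trait `"eye"`, `"hair"` or `"skin"`.
#' @param predictors Character vector of rsIDs to use as predictors.
#' @param ref Reference category (default: first observed category in
#'   vocabulary order).
#' @param exclude Categories to drop entirely before fitting (e.g. red hair
#'   when its representation is too small to model).
#' @param max_coef Coefficient cap used to detect complete separation.
#' @return An object of class `mlr_fit`: coefficient matrix
#'   (`(K-1) x (1 + P)`, rows are non-reference categories), log-likelihood,
#'   parameter count, AIC, convergence flag, category levels and drop
#'   accounting.  Supports [predict()][predict.mlr_fit], `logLik()`,
#'   `AIC()`, [tidy()] and [glance()].
#' @export
#' @examples
#' spec <- cohort_spec(n = 300, seed = 7)
#' cohort <- generate_cohort(spec)
#' fit <- fit_mlr(cohort$genotypes, cohort$phenotypes, "eye",
#'                predictors = pigment_panel("eye")$rsid)
#' glance(fit)
fit_mlr <- function(genotypes, phenotypes, trait, predictors,
                    ref = NULL, exclude = NULL, max_coef = 15) {
  trait <- match.arg(trait, c("eye", "hair", "skin"))
  y <- align_phenotype(genotypes, phenotypes, trait)
  missing_pred <- setdiff(predictors, names(genotypes))
  if (length(missing_pred)) {
    stop("predictor(s) not in genotype table: ", paste(missing_pred, collapse = ", "))
  }
  Xd <- as.matrix(genotypes[, predictors, drop = FALSE])
  ok <- !is.na(y) & y != "unknown" & !y %in% exclude & stats::complete.cases(Xd)
  n_dropped <- sum(!ok)
  y <- y[ok]
  Xd <- Xd[ok, , drop = FALSE]
  levels <- intersect(trait_levels(trait), unique(y))
  if (length(levels) < 2) stop("need at least 2 observed categories, got ", length(levels))
  if (is.null(ref)) ref <- levels[1]
  if (!ref %in% levels) stop("reference category ", shQuote(ref), " not observed")
  levels <- c(ref, setdiff(levels, ref))
  if (any(table(factor(y, levels)) == 0)) stop("category with 0 observations")
  yidx <- match(y, levels)
  X <- cbind(`(Intercept)` = 1, Xd)
  opt <- mlr_optimize(X, yidx, length(levels), max_coef = max_coef)
  dimnames(opt$beta) <- list(levels[-1], colnames(X))
  structure(
    list(
      trait = trait,
      coefficients = opt$beta,
      levels = levels,
      ref = ref,
      predictors = predictors,
      log_lik = opt$log_lik,
      n_params = (length(levels) - 1) * (1 + length(predictors)),
      converged = opt$converged,
      grad_norm = opt$grad_norm,
      n = length(y),
      n_dropped = n_dropped,
      dosage_means = colMeans(Xd)
    ),
    class = "mlr_fit"
  )
}

align_phenotype <- function(genotypes, phenotypes, trait) {
  if (is.data.frame(phenotypes)) {
    idx <- match(genotypes$sample_id, phenotypes$sample_id)
    phenotypes[[trait]][idx]
  } else {
    stopifnot(length(phenotypes) == nrow(genotypes))
    phenotypes
  }
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat("Multinomial logistic model for", x$trait, "colour\n")
  cat("  categories:", paste(x$levels, collapse = ", "),
      sprintf("(reference: %s)\n", x$ref))
  cat(sprintf("  n = %d (dropped %d), predictors = %d, logLik = %.2f, AIC = %.2f\n",
              x$n, x$n_dropped, length(x$predictors), x$log_lik, AIC(x)))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
logLik.mlr_fit <- function(object, ...) {
  structure(object$log_lik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
coef.mlr_fit <- function(object, ...) object$coefficients

#' Predicted category probabilities
#'
#' Softmax over the fitted linear scores for each sample.  Samples missing
#' a required marker (eye colour: rs12913832) always get `NA` probabilities;
#' other missing dosages are either propagated as `NA` (`impute = "none"`)
#' or replaced by the training-set mean dosage (`impute = "mean"`), flagged
#' per sample in `.imputed`.
#'
#' @param object A fitted [fit_mlr()] model.
#' @param genotypes Genotype tibble with the model's predictor columns.
#' @param impute `"none"` or `"mean"`.
#' @param required rsIDs that may never be imputed (default: the trait's
#'   required markers).
#' @param ... Unused.
#' @return Tibble: `sample_id`, one probability column per category
#'   (vocabulary order), and a logical `.imputed` column.  Probabilities in
#'   each row sum to 1.
#' @export
predict.mlr_fit <- function(object, genotypes, impute = c("none", "mean"),
                            required = NULL, ...) {
  impute <- match.arg(impute)
  required <- required %||% intersect(required_markers(object$trait), object$predictors)
  Xd <- as.matrix(genotypes[, object$predictors, drop = FALSE])
  imputed <- rep(FALSE, nrow(Xd))
  if (impute == "mean") {
    for (j in seq_len(ncol(Xd))) {
      if (colnames(Xd)[j] %in% required) next
      miss <- is.na(Xd[, j])
      if (any(miss)) {
        Xd[miss, j] <- object$dosage_means[[colnames(Xd)[j]]]
        imputed <- imputed | miss
      }
    }
  }
  ok <- stats::complete.cases(Xd)
  K <- length(object$levels)
  pr <- matrix(NA_real_, nrow(Xd), K, dimnames = list(NULL, object$levels))
  if (any(ok)) {
    eta <- cbind(0, cbind(1, Xd[ok, , drop = FALSE]) %*% t(object$coefficients))
    m <- rowmax(eta)
    pr[ok, ] <- exp(eta - m) / rowSums(exp(eta - m))
  }
  lv <- intersect(trait_levels(object$trait), object$levels)
  out <- tibble::as_tibble(pr[, lv, drop = FALSE])
  dplyr::bind_cols(tibble::tibble(sample_id = genotypes$sample_id), out,
                   tibble::tibble(.imputed = imputed))
}

#' Akaike information criterion of a fitted model
#'
#' `AIC = 2k - 2 logLik` with `k = (K-1)(1+P)`.  Emits a warning when the
#' fit did not converge (the value is still returned).
#'
#' @param object A fitted [fit_mlr()] model.
#' @param ... Unused.
#' @param k Penalty per parameter (default 2).
#' @return A number.
#' @export
AIC.mlr_fit <- function(object, ..., k = 2) {
  if (!object$converged) warning("AIC from an unconverged fit")
  k * object$n_params - 2 * object$log_lik
}

#' @rdname pigmentr-tidiers
#' @export
tidy.mlr_fit <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    y.level = rep(rownames(co), times = ncol(co)),
    term = rep(colnames(co), each = nrow(co)),
    estimate = as.vector(co)
  )
}

#' Broom-style tidiers for pigmentr model objects
#'
#' `tidy()` returns per-term (or per-step / per-category) rows;
#' `glance()` returns a one-row model summary.
#'
#' @param x A `mlr_fit`, `mlr_selection` or `mlr_cv` object.
#' @param ... Unused.
#' @name pigmentr-tidiers
#' @return A tibble.
NULL

#' @rdname pigmentr-tidiers
#' @export
glance.mlr_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_lik,
    AIC = 2 * x$n_params - 2 * x$log_lik,
    df = x$n_params,
    nobs = x$n,
    n_dropped = x$n_dropped,
    converged = x$converged
  )
}
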