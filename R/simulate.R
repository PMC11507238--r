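# Synthetic genotype-phenotype cohort generator.
#
# Genotypes are drawn marker-by-marker under Hardy-Weinberg equilibrium at
# configured effect-allele frequencies (markers independent); phenotypes
# are sampled from a ground-truth multinomial logistic model whose
# intercepts are calibrated so the expected category marginals hit the
# configured targets.  Default parameters emulate the composition of a
# 412-individual Spanish study cohort: its printed category marginals, its
# per-trait usable counts (378 eye / 380 hair / 408 skin), its four fully
# failed assay markers, and its two isolated missing rs12913832 calls.

#' Ground-truth model coefficients for the cohort simulator
#'
#' Synthetic per-trait coefficient matrices (rows: non-reference
#' categories; columns: intercept + effect-allele dosage slopes for the
#' trait's active markers).  Slopes are chosen so that rs12913832 carries
#' the dominant effect for eye and hair (as expected for the strongest
#' pigmentation locus), MC1R variants drive red hair, and skin colour is
#' driven by the major skin loci.  Intercepts here are placeholders;
#' [calibrate_intercepts()] adjusts them to hit the target marginals.
#' Effect sizes are synthetic: no published per-population values exist
#' for this panel, so recovery of whatever truth is configured — not any
#' specific value — is the testable property.
#'
#' @param trait `"eye"`, `"hair"` or `"skin"`.
#' @return A list with `ref` (reference category) and `beta` (coefficient
#'   matrix with an `(Intercept)` column and one column per active rsID).
#' @export
default_truth <- function(trait = c("eye", "hair", "skin")) {
  trait <- match.arg(trait)
  if (trait == "eye") {
    beta <- rbind(
      intermediate = c(0, 1.5, 0.5, -0.4, 0.3),
      brown        = c(0, 3.0, 1.0, -0.8, -0.5)
    )
    colnames(beta) <- c("(Intercept)", "rs12913832", "rs16891982",
                        "rs1800407", "rs12203592")
    list(ref = "blue", beta = beta)
  } else if (trait == "hair") {
    beta <- rbind(
      red   = c(0, 0, 0, 0, 2.5, 1.5),
      brown = c(0, 1.6, 0.7, 0.5, -0.5, 0),
      black = c(0, 2.4, 1.1, 0.8, -1.0, -0.5)
    )
    colnames(beta) <- c("(Intercept)", "rs12913832", "rs16891982",
                        "rs683", "rs1805007", "rs1805008")
    list(ref = "blond", beta = beta)
  } else {
    beta <- rbind(
      very_pale    = c(0, 0, 0, 0, 0),
      intermediate = c(0, 0.8, 0.7, 1.0, 0.6),
      dark         = c(0, 1.6, 1.2, 2.0, 1.5),
      dark_black   = c(0, 0, 0, 0, 0)
    )
    colnames(beta) <- c("(Intercept)", "rs16891982", "rs12913832",
                        "rs1426654", "rs6119471")
    list(ref = "pale", beta = beta)
  }
}

default_marginals <- function(trait) {
  switch(trait,
    eye  = c(blue = 0.0847, intermediate = 0.2275, brown = 0.6878),
    hair = c(blond = 0.0974, red = 0.0026, brown = 0.6447, black = 0.2553),
    skin = c(very_pale = 0, pale = 0.5343, intermediate = 0.3971,
             dark = 0.0686, dark_black = 0)
  )
}

#' Specification of a synthetic cohort
#'
#' Collects every parameter of the cohort generator.  Defaults reproduce
#' the composition of the emulated 412-individual study population:
#' category marginals per trait, per-trait unknown-phenotype counts
#' (34 eye / 32 hair / 4 skin, leaving 378/380/408 usable), the four
#' fully failed markers, and two targeted missing rs12913832 calls.
#'
#' @param n Number of individuals (default 412).
#' @param allele_freqs Tibble `rsid`/`frequency`; default
#'   [synthetic_allele_freqs()].
#' @param truth Named list of per-trait truth models (see
#'   [default_truth()]).
#' @param target_marginals Named list of per-trait category proportions
#'   (must each sum to 1).
#' @param missing_phenotypes Named integer vector: individuals per trait
#'   whose phenotype is unknown.
#' @param failed_markers rsIDs typed as all-missing (assay failures).
#' @param missing_marker_rate Independent per-cell genotype missingness
#'   rate on non-failed markers.
#' @param required_marker_holes Number of additional targeted missing
#'   rs12913832 calls.
#' @param seed Integer seed; every random draw flows from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 412,
                        allele_freqs = synthetic_allele_freqs(),
                        truth = list(eye = default_truth("eye"),
                                     hair = default_truth("hair"),
                                     skin = default_truth("skin")),
                        target_marginals = list(eye = default_marginals("eye"),
                                                hair = default_marginals("hair"),
                                                skin = default_marginals("skin")),
                        missing_phenotypes = c(eye = 34L, hair = 32L, skin = 4L),
                        failed_markers = c("rs1800414", "rs2228479",
                                           "rs312262906", "rs6497292"),
                        missing_marker_rate = 0,
                        required_marker_holes = 2L,
                        seed = 1L) {
  stopifnot(n >= 1, all(allele_freqs$frequency > 0 & allele_freqs$frequency < 1))
  for (trait in names(target_marginals)) {
    m <- target_marginals[[trait]]
    if (abs(sum(m) - 1) > 1e-6) stop("marginals for ", trait, " must sum to 1")
    if (!identical(names(m), trait_levels(trait))) {
      stop("marginals for ", trait, " must be named by trait_levels()")
    }
  }
  structure(
    list(n = as.integer(n), allele_freqs = allele_freqs, truth = truth,
         target_marginals = target_marginals,
         missing_phenotypes = missing_phenotypes,
         failed_markers = failed_markers,
         missing_marker_rate = missing_marker_rate,
         required_marker_holes = as.integer(required_marker_holes),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Exact expected category marginals of a truth model under HWE genotype
# frequencies, by enumerating the joint dosage distribution of the active
# (nonzero-slope) markers.
expected_marginals <- function(truth, allele_freqs) {
  beta <- truth$beta
  markers <- setdiff(colnames(beta), "(Intercept)")
  active <- markers[colSums(abs(beta[, markers, drop = FALSE])) > 0]
  K <- nrow(beta) + 1
  freqs <- setNames(allele_freqs$frequency, allele_freqs$rsid)[active]
  if (anyNA(freqs)) stop("allele frequency missing for: ",
                         paste(active[is.na(freqs)], collapse = ", "))
  grids <- as.matrix(expand.grid(rep(list(0:2), length(active))))
  if (length(active) == 0) grids <- matrix(0, nrow = 1, ncol = 0)
  colnames(grids) <- active
  gp <- rep(1, nrow(grids))
  for (m in active) {
    p <- freqs[[m]]
    hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    gp <- gp * hw[grids[, m] + 1]
  }
  eta <- cbind(0, cbind(1, grids) %*%
                 t(beta[, c("(Intercept)", active), drop = FALSE]))
  pr <- exp(eta - rowmax(eta))
  pr <- pr / rowSums(pr)
  marg <- colSums(pr * gp)
  names(marg) <- c(truth$ref, rownames(beta))
  marg
}

#' Calibrate truth-model intercepts to target category marginals
#'
#' Holds the configured slopes fixed and iteratively adjusts the
#' non-reference intercepts until the model's expected category marginals
#' (computed exactly by enumerating the Hardy-Weinberg dosage distribution
#' of the active markers) match the targets.  Categories with a zero
#' target get a large negative intercept cap and are never sampled.
#'
#' @param spec A [cohort_spec()].
#' @param trait Trait to calibrate.
#' @param tol Max absolute marginal error accepted (default 1e-4).
#' @param max_iter Iteration cap.
#' @return The trait's truth list with calibrated intercepts, carrying the
#'   achieved marginals as attribute `"marginals"`.
#' @export
calibrate_intercepts <- function(spec, trait, tol = 1e-4, max_iter = 200) {
  truth <- spec$truth[[trait]]
  target <- spec$target_marginals[[trait]]
  beta <- truth$beta
  cats <- rownames(beta)
  neg_cap <- -30
  zero_cats <- cats[target[cats] == 0]
  beta[zero_cats, "(Intercept)"] <- neg_cap
  live <- setdiff(cats, zero_cats)
  # renormalised targets over reachable categories
  reach <- c(truth$ref, live)
  t_live <- target[reach] / sum(target[reach])
  for (it in seq_len(max_iter)) {
    truth$beta <- beta
    m <- expected_marginals(truth, spec$allele_freqs)
    err <- max(abs(m[reach] - t_live))
    if (err < tol) {
      out <- truth
      attr(out, "marginals") <- m
      return(out)
    }
    beta[live, "(Intercept)"] <- beta[live, "(Intercept)"] +
      log(t_live[live] / m[live]) - log(t_live[[truth$ref]] / m[[truth$ref]])
  }
  stop("intercept calibration did not converge for ", trait,
       "; best marginals: ", paste(sprintf("%s=%.4f", names(m), m), collapse = ", "))
}

#' Generate a synthetic genotype-phenotype cohort
#'
#' Draws HWE genotypes for all 41 panel markers at the configured allele
#' frequencies, samples each trait's phenotype from its calibrated truth
#' model, marks the failed markers all-missing, injects genotype
#' missingness, and blanks the configured number of phenotypes per trait
#' to `"unknown"`.  Bit-identical output for the same spec (all randomness
#' flows from `spec$seed`).
#'
#' @param spec A [cohort_spec()].
#' @return A list: `genotypes` tibble, `phenotypes` tibble, and `truth` —
#'   the calibrated per-trait models actually used for sampling.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 100, seed = 42))
#' dplyr::count(cohort$phenotypes, eye)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- lapply(setNames(names(spec$truth), names(spec$truth)),
                  function(trait) calibrate_intercepts(spec, trait))
  withr::with_seed(spec$seed, {
    n <- spec$n
    freqs <- spec$allele_freqs
    geno <- tibble::tibble(sample_id = sprintf("S%05d", seq_len(n)))
    for (i in seq_len(nrow(freqs))) {
      geno[[freqs$rsid[i]]] <- rbinom(n, 2L, freqs$frequency[i])
    }
    pheno <- tibble::tibble(sample_id = geno$sample_id)
    for (trait in names(truth)) {
      beta <- truth[[trait]]$beta
      markers <- setdiff(colnames(beta), "(Intercept)")
      X <- cbind(1, as.matrix(geno[, markers, drop = FALSE]))
      eta <- cbind(0, X %*% t(beta))
      pr <- exp(eta - rowmax(eta))
      pr <- pr / rowSums(pr)
      cats <- c(truth[[trait]]$ref, rownames(beta))
      u <- runif(n)
      idx <- max.col(u < t(apply(pr, 1, cumsum)), ties.method = "first")
      y <- cats[idx]
      n_unknown <- spec$missing_phenotypes[[trait]] %||% 0L
      if (n_unknown > 0) {
        if (n_unknown > n) stop("more unknown phenotypes than samples")
        y[sample(n, n_unknown)] <- "unknown"
      }
      pheno[[trait]] <- y
    }
    for (m in intersect(spec$failed_markers, names(geno))) {
      geno[[m]] <- NA_integer_
    }
    geno <- inject_missingness(
      geno, rate = spec$missing_marker_rate,
      holes = spec$required_marker_holes, hole_marker = "rs12913832",
      skip = spec$failed_markers)
    list(genotypes = geno, phenotypes = pheno, truth = truth)
  })
}

#' Inject genotype missingness
#'
#' Adds independent Bernoulli per-cell missingness at `rate` to every
#' non-skipped marker, plus `holes` targeted missing calls in
#' `hole_marker` (emulating isolated assay dropouts of the key marker).
#' Draws from the current RNG state; seed it (or call from
#' [generate_cohort()]) for reproducibility.
#'
#' @param genotypes Genotype tibble.
#' @param rate Per-cell missingness probability in `[0, 1)`.
#' @param holes Number of targeted missing calls.
#' @param hole_marker Marker receiving the targeted holes.
#' @param skip Markers exempt from random missingness (e.g. already
#'   all-missing failed assays).
#' @return The genotype tibble with `NA`s injected.
#' @export
inject_missingness <- function(genotypes, rate = 0, holes = 0L,
                               hole_marker = "rs12913832",
                               skip = character(0)) {
  stopifnot(rate >= 0, rate < 1)
  n <- nrow(genotypes)
  if (holes > n) stop("more targeted holes (", holes, ") than samples (", n, ")")
  markers <- setdiff(names(genotypes), c("sample_id", skip))
  if (rate > 0) {
    for (m in markers) {
      genotypes[[m]][runif(n) < rate] <- NA_integer_
    }
  }
  if (holes > 0 && hole_marker %in% names(genotypes)) {
    genotypes[[hole_marker]][sample(n, holes)] <- NA_integer_
  }
  genotypes
}
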