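#' Per-marker allele and genotype frequencies
#'
#' Counts genotypes per marker (excluding missing calls) and computes the
#' effect-allele frequency \eqn{(n_1 + 2 n_2) / (2n)}.  Markers with no
#' non-missing genotype get an `NA` frequency (undefined, never zero).
#'
#' @param genotypes Genotype tibble from [read_genotypes()] or
#'   [generate_cohort()].
#' @param panel Optional panel tibble; defaults to every rsID column present.
#' @return A tibble with one row per marker: `rsid`, genotype counts
#'   `n0`, `n1`, `n2`, non-missing total `n`, and `frequency`.
#' @export
#' @examples
#' g <- tibble::tibble(sample_id = letters[1:4],
#'                     rs12913832 = c(0L, 1L, 2L, 1L))
#' allele_frequencies(g)
allele_frequencies <- function(genotypes, panel = NULL) {
  rsids <- if (is.null(panel)) setdiff(names(genotypes), "sample_id") else panel$rsid
  counts <- purrr::map_dfr(rsids, function(m) {
    v <- genotypes[[m]]
    tibble::tibble(
      rsid = m,
      n0 = sum(v == 0L, na.rm = TRUE),
      n1 = sum(v == 1L, na.rm = TRUE),
      n2 = sum(v == 2L, na.rm = TRUE)
    )
  })
  counts |>
    dplyr::mutate(
      n = .data$n0 + .data$n1 + .data$n2,
      frequency = ifelse(.data$n > 0, (.data$n1 + 2 * .data$n2) / (2 * .data$n), NA_real_)
    )
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Tests observed genotype counts against the Hardy-Weinberg expectation
#' \eqn{(n(1-\hat p)^2, 2n\hat p(1-\hat p), n\hat p^2)} with
#' \eqn{\hat p = (n_1 + 2n_2)/(2n)}, using a Pearson chi-square statistic
#' with 1 degree of freedom.  Monomorphic markers (\eqn{\hat p \in \{0,1\}})
#' are flagged and return `NA` rather than erroring.
#'
#' All three arguments are vectorised.
#'
#' @param n0,n1,n2 Counts of samples carrying 0, 1 and 2 effect alleles.
#' @return A tibble with columns `chisq`, `p_value`, `monomorphic`.
#' @export
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions: chisq 0, p 1
#' hwe_test(50, 0, 50)    # total heterozygote deficit
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  stopifnot(all(n >= 1))
  p <- (n1 + 2 * n2) / (2 * n)
  mono <- p == 0 | p == 1
  e0 <- n * (1 - p)^2
  e1 <- 2 * n * p * (1 - p)
  e2 <- n * p^2
  chisq <- ifelse(mono, NA_real_,
                  (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
  tibble::tibble(
    chisq = chisq,
    p_value = ifelse(mono, NA_real_, pchisq(chisq, df = 1, lower.tail = FALSE)),
    monomorphic = mono
  )
}

#' Compare allele frequencies against a reference population
#'
#' Pearson chi-square test (2 x 2 allele-count table, 1 df, no continuity
#' correction) of each marker's effect-allele frequency against a reference
#' population, with Bonferroni correction over the number of markers
#' actually tested.  The corrected threshold is computed as the exact
#' quotient `alpha / n_tested`.
#'
#' @param freqs Frequency tibble from [allele_frequencies()].
#' @param reference Tibble with columns `rsid`, `frequency`, `n` (reference
#'   sample count; allele counts are `2 n frequency`).
#' @param alpha Family-wise significance level before correction.
#' @return `freqs` joined with `ref_frequency`, `chisq`, `p_value`,
#'   `alpha_corrected` and `significant` (Bonferroni-corrected flag).
#'   Markers with zero total allele count in either population get `NA`.
#' @export
compare_frequencies <- function(freqs, reference, alpha = 0.05) {
  ref <- dplyr::select(reference, "rsid", ref_frequency = "frequency", ref_n = "n")
  joined <- dplyr::inner_join(freqs, ref, by = "rsid")
  a1 <- joined$n1 + 2 * joined$n2
  a0 <- 2 * joined$n - a1
  b1 <- 2 * joined$ref_n * joined$ref_frequency
  b0 <- 2 * joined$ref_n - b1
  stat <- purrr::map_dbl(seq_len(nrow(joined)), function(i) {
    tab <- matrix(c(a1[i], a0[i], b1[i], b0[i]), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  })
  n_tested <- sum(!is.na(stat))
  alpha_corrected <- if (n_tested > 0) alpha / n_tested else NA_real_
  joined |>
    dplyr::mutate(
      chisq = stat,
      p_value = pchisq(stat, df = 1, lower.tail = FALSE),
      alpha_corrected = alpha_corrected,
      significant = !is.na(.data$p_value) & .data$p_value < alpha_corrected
    ) |>
    dplyr::select(-"ref_n")
}

#' Full population-genetic QC report
#'
#' Convenience wrapper: allele/genotype frequencies, Hardy-Weinberg test per
#' marker, and (optionally) a frequency comparison against a reference
#' population with Bonferroni correction.
#'
#' @inheritParams allele_frequencies
#' @inheritParams compare_frequencies
#' @param reference Optional reference frequency tibble (see
#'   [compare_frequencies()]).
#' @return One tibble with a row per marker combining all QC columns.
#' @export
qc_report <- function(genotypes, panel = NULL, reference = NULL, alpha = 0.05) {
  freqs <- allele_frequencies(genotypes, panel)
  usable <- freqs$n > 0
  hwe <- tibble::tibble(hwe_chisq = NA_real_, hwe_p = NA_real_, monomorphic = NA)[rep(1, nrow(freqs)), ]
  if (any(usable)) {
    h <- hwe_test(freqs$n0[usable], freqs$n1[usable], freqs$n2[usable])
    hwe$hwe_chisq[usable] <- h$chisq
    hwe$hwe_p[usable] <- h$p_value
    hwe$monomorphic[usable] <- h$monomorphic
  }
  out <- dplyr::bind_cols(freqs, hwe)
  if (!is.null(reference)) {
    cmp <- compare_frequencies(freqs, reference, alpha = alpha) |>
      dplyr::select("rsid", "ref_frequency", cmp_chisq = "chisq",
                    cmp_p = "p_value", "alpha_corrected", "significant")
    out <- dplyr::left_join(out, cmp, by = "rsid")
  }
  out
}
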