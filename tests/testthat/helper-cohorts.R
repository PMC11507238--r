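# Small in-code fixtures shared across tests.

# A tiny eye-panel genotype/phenotype pair with a deterministic layout.
tiny_eye_data <- function() {
  panel <- pigment_panel("eye")
  genotypes <- tibble::tibble(
    sample_id = sprintf("T%02d", 1:6),
    rs12913832 = c(0L, 1L, 2L, 2L, 1L, 0L),
    rs1800407  = c(0L, 0L, 1L, 0L, 2L, 1L),
    rs12896399 = c(1L, 1L, 0L, 2L, 1L, 0L),
    rs16891982 = c(2L, 2L, 2L, 1L, 2L, 2L),
    rs1393350  = c(0L, 1L, 0L, 0L, 1L, 2L),
    rs12203592 = c(0L, 0L, 1L, 0L, 0L, 1L)
  )
  phenotypes <- tibble::tibble(
    sample_id = genotypes$sample_id,
    eye = c("blue", "intermediate", "brown", "brown", "intermediate", "blue"),
    hair = "unknown", skin = "unknown"
  )
  list(genotypes = genotypes, phenotypes = phenotypes, panel = panel)
}

# Quick spec for small simulated cohorts with no missingness.
clean_spec <- function(n, seed, ...) {
  cohort_spec(n = n, seed = seed,
              missing_phenotypes = c(eye = 0L, hair = 0L, skin = 0L),
              missing_marker_rate = 0, required_marker_holes = 0L,
              failed_markers = character(0), ...)
}

# Brute-force AUC oracle: count concordant pairs, half credit for ties.
pair_count_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
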