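#' Probability thresholds for phenotype calling
#'
#' Default thresholds of the calling rules: a probability above
#' `definitive` (0.7) is a positive single-category call; eye probabilities
#' in the `(undefined_low, definitive]` band (0.5-0.7) are undefined under
#' the strict approach and compound intermediate-X under the flexible one;
#' skin calls require the top category to exceed `skin_primary` (0.5) and,
#' in flexible mode, attach a secondary tone when the runner-up is within
#' `skin_secondary_gap`; hair compounds form when the runner-up is within
#' `hair_compound_band` of the top category.
#'
#' All thresholds are strict inequalities: a probability exactly at a
#' threshold falls to the lower branch.
#'
#' @param definitive Positive-prediction threshold (eye), default 0.7.
#' @param undefined_low Lower edge of the eye undefined band, default 0.5.
#' @param skin_primary Skin top-category threshold, default 0.5.
#' @param skin_secondary_gap Max gap for a secondary skin tone, default 0.2.
#' @param hair_compound_band Max gap for a hair compound call, default 0.1.
#' @return A named list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(definitive = 0.7, undefined_low = 0.5,
                               skin_primary = 0.5, skin_secondary_gap = 0.2,
                               hair_compound_band = 0.1) {
  stopifnot(0 < undefined_low, undefined_low < definitive, definitive <= 1)
  structure(
    list(definitive = definitive, undefined_low = undefined_low,
         skin_primary = skin_primary, skin_secondary_gap = skin_secondary_gap,
         hair_compound_band = hair_compound_band),
    class = "calling_thresholds"
  )
}

# Validate a probability vector against a trait vocabulary.  Categories
# absent from the vector (e.g. a skin model fitted without the unobserved
# extremes) are treated as probability zero.  Any NA component signals a
# sample that cannot be called.
check_proba <- function(p, trait) {
  levels <- trait_levels(trait)
  if (is.data.frame(p)) p <- unlist(p[1, intersect(names(p), levels)])
  if (is.null(names(p)) && length(p) == length(levels)) names(p) <- levels
  if (!all(names(p) %in% levels)) {
    stop("probability names must be among: ", paste(levels, collapse = ", "))
  }
  full <- setNames(numeric(length(levels)), levels)
  full[names(p)] <- as.numeric(p)
  if (anyNA(full)) return(NULL)
  if (any(full < -1e-9) || abs(sum(full) - 1) > 1e-6) {
    stop("malformed probability vector: components must be >= 0 and sum to 1")
  }
  full
}

call_tibble <- function(trait, labels, status) {
  tibble::tibble(
    trait = trait,
    labels = if (length(labels)) paste(labels, collapse = "/") else NA_character_,
    status = status
  )
}

#' Call eye colour from category probabilities
#'
#' Applies the threshold rules for eye colour: blue or brown above 0.7 is a
#' definitive single call; a blue/brown maximum in the 0.5-0.7 band is a
#' compound intermediate-blue or intermediate-brown call (status
#' `"undefined"` under the strict approach, a definitive compound under the
#' flexible one); when neither blue nor brown exceeds 0.5 the call is
#' intermediate (status `"intermediate_rule"`).  An intermediate
#' probability above 0.7 is called intermediate definitively.  Any `NA`
#' probability (e.g. missing rs12913832) yields an `NA` call.
#'
#' @param p Named probabilities for `blue`, `intermediate`, `brown`
#'   (vector or one-row data frame), summing to 1.
#' @param mode `"strict"` or `"flexible"`.
#' @param thresholds A [calling_thresholds()] object.
#' @return One-row tibble: `trait`, `labels` (categories joined by `/`),
#'   `status` (`definitive`, `undefined`, `intermediate_rule` or `NA`).
#' @export
#' @examples
#' call_eye(c(blue = 0.85, intermediate = 0.05, brown = 0.10))
#' call_eye(c(blue = 0.60, intermediate = 0.15, brown = 0.25), mode = "flexible")
call_eye <- function(p, mode = c("strict", "flexible"),
                     thresholds = calling_thresholds()) {
  mode <- match.arg(mode)
  p <- check_proba(p, "eye")
  if (is.null(p)) return(call_tibble("eye", character(0), "NA"))
  t_hi <- thresholds$definitive
  t_lo <- thresholds$undefined_low
  if (p["blue"] > t_hi) return(call_tibble("eye", "blue", "definitive"))
  if (p["brown"] > t_hi) return(call_tibble("eye", "brown", "definitive"))
  if (p["intermediate"] > t_hi) return(call_tibble("eye", "intermediate", "definitive"))
  lead <- if (p["blue"] >= p["brown"]) "blue" else "brown"
  if (p[lead] > t_lo) {
    status <- if (mode == "strict") "undefined" else "definitive"
    return(call_tibble("eye", c("intermediate", lead), status))
  }
  call_tibble("eye", "intermediate", "intermediate_rule")
}

#' Call hair colour from category probabilities
#'
#' Calls the highest-probability hair category, attaching the runner-up as
#' a compound call (e.g. black/brown) when it lies within
#' `hair_compound_band` of the leader.  Exact ties are broken in
#' vocabulary order (blond, red, brown, black).
#'
#' @param p Named probabilities for `blond`, `red`, `brown`, `black`.
#' @param thresholds A [calling_thresholds()] object.
#' @inherit call_eye return
#' @export
#' @examples
#' call_hair(c(blond = 0.05, red = 0, brown = 0.46, black = 0.49))
call_hair <- function(p, thresholds = calling_thresholds()) {
  p <- check_proba(p, "hair")
  if (is.null(p)) return(call_tibble("hair", character(0), "NA"))
  ord <- order(-p, match(names(p), trait_levels("hair")))
  top <- names(p)[ord[1]]
  second <- names(p)[ord[2]]
  labels <- if (p[top] - p[second] <= thresholds$hair_compound_band) {
    c(top, second)
  } else {
    top
  }
  call_tibble("hair", labels, "definitive")
}

#' Call skin colour from category probabilities
#'
#' Strict approach: the highest-probability category is called when it
#' exceeds `skin_primary` (0.5); otherwise the prediction is undefined (no
#' dominant tone).  Flexible approach: as strict, but a secondary tone is
#' attached when the runner-up lies within `skin_secondary_gap` of the
#' leader (e.g. intermediate/pale); all-below-threshold stays undefined in
#' both modes.
#'
#' @param p Named probabilities over the skin vocabulary (categories absent
#'   from a reduced model count as zero).
#' @inheritParams call_eye
#' @inherit call_eye return
#' @export
#' @examples
#' call_skin(c(very_pale = 0.01, pale = 0.10, intermediate = 0.70,
#'             dark = 0.18, dark_black = 0.01))
call_skin <- function(p, mode = c("strict", "flexible"),
                      thresholds = calling_thresholds()) {
  mode <- match.arg(mode)
  p <- check_proba(p, "skin")
  if (is.null(p)) return(call_tibble("skin", character(0), "NA"))
  ord <- order(-p, match(names(p), trait_levels("skin")))
  top <- names(p)[ord[1]]
  second <- names(p)[ord[2]]
  if (p[top] <= thresholds$skin_primary) {
    return(call_tibble("skin", character(0), "undefined"))
  }
  labels <- top
  if (mode == "flexible" && p[top] - p[second] <= thresholds$skin_secondary_gap) {
    labels <- c(top, second)
  }
  call_tibble("skin", labels, "definitive")
}

#' Batch phenotype calling from a probability table
#'
#' Applies the per-trait calling rules to every row of a probability table
#' (as produced by [predict.mlr_fit()]).
#'
#' @param probs Tibble with `sample_id` and one probability column per
#'   category.  Rows with `NA` probabilities become `NA` calls.
#' @param trait `"eye"`, `"hair"` or `"skin"`.
#' @inheritParams call_eye
#' @return Tibble: `sample_id`, `trait`, `labels`, `status`.
#' @export
call_phenotypes <- function(probs, trait, mode = c("strict", "flexible"),
                            thresholds = calling_thresholds()) {
  trait <- match.arg(trait, c("eye", "hair", "skin"))
  mode <- match.arg(mode)
  cats <- intersect(names(probs), trait_levels(trait))
  stopifnot(length(cats) >= 2)
  calls <- purrr::map_dfr(seq_len(nrow(probs)), function(i) {
    p <- unlist(probs[i, cats])
    switch(trait,
      eye = call_eye(p, mode, thresholds),
      hair = call_hair(p, thresholds),
      skin = call_skin(p, mode, thresholds)
    )
  })
  dplyr::bind_cols(tibble::tibble(sample_id = probs$sample_id), calls)
}
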