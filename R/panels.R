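#' Category vocabulary for a pigmentation trait
#'
#' Eye colour uses three categories (blue, intermediate, brown), hair four
#' (blond, red, brown, black) and skin five (very pale through dark-black),
#' matching the category system of the HIrisPlex-S prediction tool.
#'
#' @param trait One of `"eye"`, `"hair"`, `"skin"`.
#' @return Character vector of category labels, in conventional light-to-dark
#'   order. This order is also the tie-break order used by the calling rules.
#' @export
#' @examples
#' trait_levels("eye")
trait_levels <- function(trait) {
  trait <- match.arg(trait, c("eye", "hair", "skin"))
  switch(trait,
    eye  = c("blue", "intermediate", "brown"),
    hair = c("blond", "red", "brown", "black"),
    skin = c("very_pale", "pale", "intermediate", "dark", "dark_black")
  )
}

# Master marker table: the 41 pigmentation SNPs, their genes, the counted
# (effect) allele of the web-tool input dialect, and panel membership.
# eye panel: 6 markers; hair: 22; skin: 36.
marker_table <- function() {
  tibble::tribble(
    ~rsid,          ~gene,           ~allele, ~eye,  ~hair, ~skin,
    "rs12913832",   "HERC2",         "T",     TRUE,  TRUE,  TRUE,
    "rs1800407",    "OCA2",          "A",     TRUE,  TRUE,  TRUE,
    "rs12896399",   "SLC24A4",       "T",     TRUE,  FALSE, TRUE,
    "rs16891982",   "SLC45A2",       "C",     TRUE,  TRUE,  TRUE,
    "rs1393350",    "TYR",           "A",     TRUE,  FALSE, TRUE,
    "rs12203592",   "IRF4",          "T",     TRUE,  TRUE,  TRUE,
    "rs201326893",  "MC1R",          "A",     FALSE, TRUE,  FALSE,
    "rs312262906",  "MC1R",          "A",     FALSE, TRUE,  FALSE,
    "rs1805006",    "MC1R",          "A",     FALSE, TRUE,  TRUE,
    "rs11547464",   "MC1R",          "A",     FALSE, TRUE,  TRUE,
    "rs1805007",    "MC1R",          "T",     FALSE, TRUE,  TRUE,
    "rs1805008",    "MC1R",          "T",     FALSE, TRUE,  TRUE,
    "rs1805009",    "MC1R",          "C",     FALSE, TRUE,  FALSE,
    "rs1805005",    "MC1R",          "T",     FALSE, TRUE,  FALSE,
    "rs2228479",    "MC1R",          "A",     FALSE, TRUE,  TRUE,
    "rs1110400",    "MC1R",          "C",     FALSE, TRUE,  TRUE,
    "rs885479",     "MC1R",          "T",     FALSE, TRUE,  TRUE,
    "rs28777",      "SLC45A2",       "C",     FALSE, TRUE,  TRUE,
    "rs12821256",   "KITLG",         "G",     FALSE, TRUE,  TRUE,
    "rs4959270",    "EXOC2",         "A",     FALSE, TRUE,  FALSE,
    "rs1042602",    "TYR",           "A",     FALSE, TRUE,  TRUE,
    "rs2402130",    "SLC24A4",       "G",     FALSE, TRUE,  TRUE,
    "rs2378249",    "ASIP/PIGU",     "G",     FALSE, TRUE,  TRUE,
    "rs683",        "TYRP1",         "G",     FALSE, TRUE,  TRUE,
    "rs3114908",    "ANKRD11",       "T",     FALSE, FALSE, TRUE,
    "rs1800414",    "OCA2",          "G",     FALSE, FALSE, TRUE,
    "rs10756819",   "BNC2",          "A",     FALSE, FALSE, TRUE,
    "rs2238289",    "HERC2",         "G",     FALSE, FALSE, TRUE,
    "rs17128291",   "SLC24A4",       "G",     FALSE, FALSE, TRUE,
    "rs6497292",    "HERC2",         "G",     FALSE, FALSE, TRUE,
    "rs1129038",    "HERC2",         "T",     FALSE, FALSE, TRUE,
    "rs1667394",    "HERC2",         "C",     FALSE, FALSE, TRUE,
    "rs1126809",    "TYR",           "A",     FALSE, FALSE, TRUE,
    "rs1470608",    "OCA2",          "T",     FALSE, FALSE, TRUE,
    "rs1426654",    "SLC24A5",       "G",     FALSE, FALSE, TRUE,
    "rs6119471",    "ASIP",          "C",     FALSE, FALSE, TRUE,
    "rs1545397",    "OCA2",          "T",     FALSE, FALSE, TRUE,
    "rs6059655",    "RALY",          "A",     FALSE, FALSE, TRUE,
    "rs12441727",   "OCA2",          "A",     FALSE, FALSE, TRUE,
    "rs3212355",    "MC1R",          "A",     FALSE, FALSE, TRUE,
    "rs8051733",    "DEF8",          "C",     FALSE, FALSE, TRUE
  )
}

#' SNP panel for a pigmentation trait
#'
#' Returns the marker panel used for predicting one pigmentation trait:
#' 6 SNPs for eye colour, 22 for hair and 36 for skin.  The `allele` column
#' is the counted (effect) allele, i.e. dosages in genotype files are the
#' number of copies of this allele.  `required` flags markers whose absence
#' makes a prediction impossible for a sample (eye colour cannot be called
#' without the HERC2 rs12913832 genotype).
#'
#' @param trait One of `"eye"`, `"hair"`, `"skin"`, or `"all"` for the union
#'   panel of all 41 pigmentation markers.
#' @return A tibble with columns `rsid`, `gene`, `allele`, `required`.
#' @export
#' @examples
#' pigment_panel("eye")
#' nrow(pigment_panel("skin"))
pigment_panel <- function(trait = c("eye", "hair", "skin", "all")) {
  trait <- match.arg(trait)
  mt <- marker_table()
  tbl <- if (trait == "all") mt else mt[mt[[trait]], , drop = FALSE]
  out <- tibble::tibble(
    rsid = tbl$rsid,
    gene = tbl$gene,
    allele = tbl$allele,
    required = tbl$rsid %in% required_markers(trait)
  )
  attr(out, "trait") <- trait
  out
}

required_markers <- function(trait) {
  if (trait %in% c("eye", "all")) "rs12913832" else character(0)
}

#' Synthetic default allele frequencies for the pigmentation panel
#'
#' A configurable table of effect-allele frequencies covering all 41 panel
#' markers, used as the default by the cohort simulator and shipped as
#' `inst/extdata/synthetic_allele_freqs.csv`.  The values are synthetic:
#' plausible European-range frequencies chosen for realism, not estimates
#' from any genotyped cohort.  Supply your own table wherever a
#' `allele_freqs` argument is accepted.
#'
#' @return A tibble with columns `rsid` and `frequency`.
#' @export
synthetic_allele_freqs <- function() {
  panel <- pigment_panel("all")
  freqs <- c(
    rs12913832 = 0.62, rs1800407 = 0.07, rs12896399 = 0.42,
    rs16891982 = 0.88, rs1393350 = 0.22, rs12203592 = 0.14,
    rs201326893 = 0.02, rs312262906 = 0.01, rs1805006 = 0.02,
    rs11547464 = 0.03, rs1805007 = 0.06, rs1805008 = 0.07,
    rs1805009 = 0.02, rs1805005 = 0.12, rs2228479 = 0.08,
    rs1110400 = 0.02, rs885479 = 0.06, rs28777 = 0.92,
    rs12821256 = 0.12, rs4959270 = 0.45, rs1042602 = 0.35,
    rs2402130 = 0.78, rs2378249 = 0.12, rs683 = 0.35,
    rs3114908 = 0.35, rs1800414 = 0.01, rs10756819 = 0.30,
    rs2238289 = 0.20, rs17128291 = 0.18, rs6497292 = 0.08,
    rs1129038 = 0.62, rs1667394 = 0.75, rs1126809 = 0.25,
    rs1470608 = 0.22, rs1426654 = 0.97, rs6119471 = 0.05,
    rs1545397 = 0.10, rs6059655 = 0.08, rs12441727 = 0.15,
    rs3212355 = 0.04, rs8051733 = 0.30
  )
  tibble::tibble(rsid = panel$rsid, frequency = unname(freqs[panel$rsid]))
}
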