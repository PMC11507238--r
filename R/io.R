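#' Read a genotype matrix in the web-tool column dialect
#'
#' Parses a delimited text file whose first column is the sample identifier
#' and whose remaining columns are named `rsID_allele` (e.g. `rs12913832_T`),
#' each holding the dosage (0, 1 or 2 copies) of the counted allele, with
#' `NA` or an empty cell for a missing call.  Comma and tab delimiters are
#' both accepted.
#'
#' Columns whose rsID is not in `panel` are dropped with a warning; panel
#' markers absent from the file are added as all-missing columns with a
#' warning, so the returned tibble always has one column per panel marker.
#'
#' @param path Path to the genotype file.
#' @param panel A panel tibble from [pigment_panel()].
#' @return A tibble with `sample_id` followed by one integer column per
#'   panel rsID.
#' @seealso [write_genotypes()], [read_phenotypes()]
#' @export
read_genotypes <- function(path, panel = pigment_panel("all")) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE)
  if (ncol(raw) < 1L) stop("empty genotype file: ", path)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cols <- names(raw)[-1]
  rsids <- sub("_[ACGTacgt]+$", "", cols)
  keep <- rsids %in% panel$rsid
  if (any(!keep)) {
    warning("ignoring ", sum(!keep), " column(s) not in panel: ",
            paste(utils::head(cols[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ..." else "")
  }
  out <- tibble::tibble(sample_id = ids)
  for (j in which(keep)) {
    v <- trimws(raw[[j + 1L]])
    v[v %in% c("", "NA", "na", ".")] <- NA_character_
    bad <- !is.na(v) & !v %in% c("0", "1", "2")
    if (any(bad)) {
      i <- which(bad)[1]
      stop("invalid dosage ", shQuote(v[i]), " at row ", i,
           " (sample ", ids[i], "), column ", cols[j])
    }
    out[[rsids[j]]] <- as.integer(v)
  }
  absent <- setdiff(panel$rsid, rsids[keep])
  if (length(absent)) {
    warning("panel marker(s) absent from file, recorded as all-missing: ",
            paste(absent, collapse = ", "))
    for (m in absent) out[[m]] <- NA_integer_
  }
  out[, c("sample_id", panel$rsid)]
}

#' Write a genotype matrix in the web-tool column dialect
#'
#' Inverse of [read_genotypes()]: columns are written as `rsID_allele` using
#' the panel's counted alleles.
#'
#' @param genotypes Genotype tibble (`sample_id` + one column per rsID).
#' @param path Output path.
#' @param panel Panel tibble supplying the allele suffix for each marker.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, panel = pigment_panel("all"),
                            delim = ",") {
  rsids <- intersect(names(genotypes)[-1], panel$rsid)
  out <- genotypes[, c("sample_id", rsids)]
  suffix <- setNames(panel$allele, panel$rsid)
  names(out) <- c("sampleid", paste0(rsids, "_", suffix[rsids]))
  readr::write_delim(out, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read observed phenotypes
#'
#' Reads a delimited file with columns `sampleid` (or `sample_id`), `eye`,
#' `hair`, `skin`.  Empty cells and `NA` become `"unknown"`.  Any value
#' outside the trait vocabulary (see [trait_levels()]) is an error.
#'
#' @param path Path to the phenotype file.
#' @return Tibble with `sample_id`, `eye`, `hair`, `skin` character columns.
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE)
  names(raw)[1] <- "sample_id"
  if (anyDuplicated(raw$sample_id)) stop("duplicate sample ids in ", path)
  for (trait in c("eye", "hair", "skin")) {
    if (!trait %in% names(raw)) {
      raw[[trait]] <- "unknown"
      next
    }
    v <- trimws(raw[[trait]])
    v[v %in% c("", "NA", "na")] <- "unknown"
    bad <- !v %in% c(trait_levels(trait), "unknown")
    if (any(bad)) {
      stop("unknown ", trait, " category ", shQuote(v[which(bad)[1]]),
           " at row ", which(bad)[1])
    }
    raw[[trait]] <- v
  }
  tibble::as_tibble(raw[, c("sample_id", "eye", "hair", "skin")])
}

#' Write observed phenotypes
#'
#' @param phenotypes Tibble with `sample_id`, `eye`, `hair`, `skin`.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path, delim = ",") {
  out <- phenotypes[, c("sample_id", "eye", "hair", "skin")]
  names(out)[1] <- "sampleid"
  readr::write_delim(out, path, delim = delim, na = "unknown")
  invisible(path)
}
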