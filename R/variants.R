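## protein-level change notation: R277L, Y233*, R388Ter, M387delM
PROTEIN_CHANGE_RE <- "^[A-Z][0-9]+([A-Z]\\*?|\\*|Ter|del[A-Z]+)$"

#' Classify a SIFT score
#'
#' Standard SIFT convention: scores at or below 0.05 are \code{"damaging"},
#' above are \code{"tolerated"}; missing scores (e.g. termination variants
#' without a prediction) are \code{"unknown"}. Severity is non-increasing in
#' the score.
#'
#' @param score numeric vector of SIFT scores in [0, 1] (NA allowed).
#' @return character vector: \code{"damaging"}, \code{"tolerated"} or
#'   \code{"unknown"}.
#' @examples
#' classifySift(c(0.03, 0.65, 0.05))
#' @export
classifySift <- function(score) {
  bad <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad)) stopf("SIFT score out of [0, 1]: %g", score[bad][1L])
  ifelse(is.na(score), "unknown",
         ifelse(score <= 0.05, "damaging", "tolerated"))
}

#' Classify a PolyPhen-2 score
#'
#' HumDiv-style bins: scores at or above 0.957 are
#' \code{"probably_damaging"}, at or above 0.453 \code{"possibly_damaging"},
#' below \code{"benign"}; missing scores are \code{"unknown"}. Severity is
#' non-decreasing in the score.
#'
#' @param score numeric vector of PolyPhen-2 scores in [0, 1] (NA allowed).
#' @return character vector of bin labels.
#' @examples
#' classifyPolyphen(c(0.993, 0.262, 0.497))
#' @export
classifyPolyphen <- function(score) {
  bad <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad)) stopf("PolyPhen-2 score out of [0, 1]: %g", score[bad][1L])
  ifelse(is.na(score), "unknown",
         ifelse(score >= 0.957, "probably_damaging",
                ifelse(score >= 0.453, "possibly_damaging", "benign")))
}

## printed label vocabulary -> threshold-class vocabulary
normalizeSiftLabel <- function(label) {
  l <- tolower(trimws(label))
  ifelse(is.na(label), "unknown",
         ifelse(l == "damaging", "damaging",
                ifelse(l == "tolerated", "tolerated", "unknown")))
}

normalizePolyphenLabel <- function(label) {
  l <- tolower(trimws(label))
  ifelse(is.na(label), "unknown",
         ifelse(l == "probably damaging", "probably_damaging",
                ifelse(l == "possibly damaging", "possibly_damaging",
                       ifelse(l == "benign", "benign", "unknown"))))
}

#' Load a variant table from TSV
#'
#' Reads a tab-separated variant table into a \code{data.frame} of records.
#' Required columns: \code{snp_id}, \code{protein_change}, \code{region};
#' recognised optional columns: \code{sift_score},
#' \code{sift_label_printed}, \code{polyphen_score},
#' \code{polyphen_label_printed}. \code{"/"} and blank cells map to
#' \code{NA} (absent). Protein changes must match
#' \code{<ref aa><position><alt aa|*|Ter|delX>}; a malformed change raises a
#' parse error carrying the data-row number. Printed predictor labels are
#' stored verbatim and never overwritten; threshold classes are computed on
#' demand by [classifySift] / [classifyPolyphen].
#'
#' @param path path to the TSV file.
#' @return \code{data.frame} of variant records.
#' @seealso [variantFixturePath] for the packaged tables.
#' @export
loadVariantTable <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  need <- c("snp_id", "protein_change", "region")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("variant table %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  toNA <- function(x) ifelse(is.na(x) | x == "/" | !nzchar(trimws(x)),
                             NA_character_, trimws(x))
  for (cl in names(df)) df[[cl]] <- toNA(df[[cl]])
  badRow <- which(is.na(df$protein_change) |
                  !grepl(PROTEIN_CHANGE_RE, df$protein_change))
  if (length(badRow))
    stopf("parse error: malformed protein_change '%s' at data row %d",
          df$protein_change[badRow[1L]], badRow[1L])
  for (cl in c("sift_score", "polyphen_score")) {
    if (!cl %in% names(df)) { df[[cl]] <- NA_real_; next }
    v <- suppressWarnings(as.numeric(df[[cl]]))
    badNum <- which(!is.na(df[[cl]]) & is.na(v))
    if (length(badNum))
      stopf("parse error: non-numeric %s at data row %d", cl, badNum[1L])
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stopf("%s outside [0, 1] in %s", cl, path)
    df[[cl]] <- v
  }
  for (cl in c("sift_label_printed", "polyphen_label_printed"))
    if (!cl %in% names(df)) df[[cl]] <- NA_character_
  df
}

#' Is a variant a termination or deletion variant?
#'
#' @param protein_change character vector of protein changes.
#' @return logical vector: TRUE for \code{*}, \code{Ter} and \code{delX}
#'   variants.
#' @export
isTruncatingChange <- function(protein_change) {
  grepl("(\\*|Ter|del[A-Z]+)$", protein_change)
}

#' Filter variants predicted damaging by both predictors
#'
#' Retains records whose computed SIFT class is \code{"damaging"} and whose
#' computed PolyPhen-2 class is \code{"probably_damaging"} or
#' \code{"possibly_damaging"}; records lacking either score are excluded.
#'
#' @param records variant \code{data.frame} from [loadVariantTable].
#' @return the filtered subset.
#' @export
filterDamagingBoth <- function(records) {
  if (nrow(records) == 0L) return(records)
  keep <- !is.na(records$sift_score) & !is.na(records$polyphen_score) &
    classifySift(records$sift_score) == "damaging" &
    classifyPolyphen(records$polyphen_score) %in%
      c("probably_damaging", "possibly_damaging")
  records[keep, , drop = FALSE]
}

#' Count variants per annotated region
#'
#' Exact multiset count of the \code{region} field (records without a region
#' are skipped); counts sum to the number of region-annotated records.
#'
#' @param records variant \code{data.frame}.
#' @return named integer vector, region -> count.
#' @export
countByRegion <- function(records) {
  r <- records$region[!is.na(records$region)]
  if (length(r) == 0L) return(integer(0))
  tab <- table(r)
  stats::setNames(as.integer(tab), names(tab))
}

#' QC: printed predictor labels versus threshold classes
#'
#' For every record carrying both a score and a printed label for a
#' predictor, compares the printed label with the class the thresholds
#' assign to the printed score, and reports disagreements. Variant tables
#' assembled from multiple sources can carry internally inconsistent labels
#' (the same numeric score printed as different bins); this check surfaces
#' them without altering the stored labels.
#'
#' @param records variant \code{data.frame}.
#' @return \code{data.frame} of mismatches with columns \code{snp_id},
#'   \code{protein_change}, \code{tool}, \code{score},
#'   \code{printed_label}, \code{computed_class}; zero rows when all labels
#'   agree.
#' @export
consistencyCheck <- function(records) {
  out <- list()
  mk <- function(i, tool, score, printed, computed)
    data.frame(snp_id = records$snp_id[i],
               protein_change = records$protein_change[i], tool = tool,
               score = score, printed_label = printed,
               computed_class = computed, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    s <- records$sift_score[i]
    sl <- records$sift_label_printed[i]
    if (!is.na(s) && !is.na(sl)) {
      printed <- normalizeSiftLabel(sl)
      computed <- classifySift(s)
      if (printed != "unknown" && printed != computed)
        out[[length(out) + 1L]] <- mk(i, "SIFT", s, sl, computed)
    }
    p <- records$polyphen_score[i]
    pl <- records$polyphen_label_printed[i]
    if (!is.na(p) && !is.na(pl)) {
      printed <- normalizePolyphenLabel(pl)
      computed <- classifyPolyphen(p)
      if (printed != "unknown" && printed != computed)
        out[[length(out) + 1L]] <- mk(i, "PolyPhen-2", p, pl, computed)
    }
  }
  if (length(out) == 0L)
    return(data.frame(snp_id = character(0), protein_change = character(0),
                      tool = character(0), score = numeric(0),
                      printed_label = character(0),
                      computed_class = character(0)))
  do.call(rbind, out)
}
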