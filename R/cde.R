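#' Catalogue of common data elements (CDEs)
#'
#' The catalogue organizes annotation vocabulary as data elements
#' (concepts, e.g. Thermostat) holding attributes (properties, e.g. its
#' implementation name), grouped into the seven survey groups (authorship,
#' platform, molecular system, methods, molecules, molecular dynamics,
#' quantum mechanics). Attributes carry flags: recommended (community mean
#' importance score above 4.0 on the 1-5 Likert scale), derived (inferable
#' through a dictionary from a stored attribute) and has-unit. A data
#' element is recommended if at least one of its attributes is.
#'
#' The packaged catalogue (\code{inst/extdata/cde_catalog.csv}) is a
#' synthetic transcription assembled from the published element and
#' attribute descriptions; it reproduces the published totals of 32
#' elements and 72 attributes, 30 of them recommended.
#'
#' @name cde-catalog
NULL

#' Load a CDE catalogue
#'
#' @param path catalogue CSV with columns \code{CATEGORY}, \code{ELEMENT},
#'   \code{ATTRIBUTE}, \code{RECOMMENDED}, \code{DERIVED}, \code{HAS_UNIT}
#'   and optional \code{MEAN_SCORE}; defaults to the packaged catalogue.
#' @return a \code{simdex_cde_catalog} with the attribute table, the
#'   element summary and category listing.
#' @export
load_cde_catalog <- function(path = system.file("extdata", "cde_catalog.csv",
                                                package = "simdex", mustWork = TRUE)) {
  df <- read_simdex_csv(path)
  need <- c("CATEGORY", "ELEMENT", "ATTRIBUTE", "RECOMMENDED", "DERIVED", "HAS_UNIT")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stopf("simdex_schema_error", "catalogue is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (any(!nzchar(trimws(df$ELEMENT)))) {
    stopf("simdex_schema_error", "catalogue attribute '%s' belongs to no element",
          df$ATTRIBUTE[!nzchar(trimws(df$ELEMENT))][1])
  }
  df$RECOMMENDED <- is_flag_true(df$RECOMMENDED)
  df$DERIVED <- is_flag_true(df$DERIVED)
  df$HAS_UNIT <- is_flag_true(df$HAS_UNIT)
  df$MEAN_SCORE <- if ("MEAN_SCORE" %in% names(df)) {
    suppressWarnings(as.numeric(df$MEAN_SCORE))
  } else NA_real_
  key <- paste(df$CATEGORY, df$ELEMENT, df$ATTRIBUTE, sep = "\x1f")
  if (anyDuplicated(key)) {
    stopf("simdex_schema_error", "duplicate attribute row(s) in catalogue")
  }
  # recommended flag must agree with the scoring rule where a score exists
  scored <- !is.na(df$MEAN_SCORE)
  bad <- scored & (df$RECOMMENDED != (df$MEAN_SCORE > 4.0))
  if (any(bad)) {
    stopf("simdex_schema_error",
          "attribute '%s' has RECOMMENDED inconsistent with its mean score",
          df$ATTRIBUTE[bad][1])
  }
  elements <- stats::aggregate(RECOMMENDED ~ CATEGORY + ELEMENT, data = df, FUN = any)
  structure(list(table = df, elements = elements,
                 categories = unique(df$CATEGORY)),
            class = "simdex_cde_catalog")
}

#' Catalogue summary counts
#' @param catalog a \code{simdex_cde_catalog}.
#' @return named list: elements, attributes, recommended attributes,
#'   recommended elements, categories.
#' @export
cde_stats <- function(catalog) {
  list(n_elements = nrow(catalog$elements),
       n_attributes = nrow(catalog$table),
       n_recommended_attributes = sum(catalog$table$RECOMMENDED),
       n_recommended_elements = sum(catalog$elements$RECOMMENDED),
       n_categories = length(catalog$categories))
}

#' Classify survey importance from Likert responses
#'
#' An attribute is recommended when the mean of its non-N/A responses on
#' the 1-5 Likert scale is strictly greater than 4.0 ("Important");
#' otherwise it is optional. N/A responses do not enter the mean.
#'
#' @param scores vector of responses: numbers in 1..5, with N/A allowed as
#'   \code{NA} or the string \code{"N/A"}.
#' @return \code{"recommended"} or \code{"optional"}.
#' @export
classify_importance <- function(scores) {
  vals <- suppressWarnings(as.numeric(ifelse(scores %in% c("N/A", "NA"), NA, scores)))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stopf("simdex_undefined_score_error", "all responses are N/A; score undefined")
  }
  if (any(vals < 1 | vals > 5)) {
    stopf("simdex_usage_error", "Likert responses must lie in 1..5")
  }
  if (mean(vals) > 4.0) "recommended" else "optional"
}

#' Check annotation completeness against the catalogue
#'
#' @param triplets triplet data.frame (or a \code{simdex_triplet_store}).
#' @param catalog a \code{simdex_cde_catalog}.
#' @return a \code{simdex_completeness_report}: the fraction of recommended
#'   catalogue attributes present among the triplets, the missing
#'   recommended attributes, and attributes unknown to the catalogue
#'   (user-specific extensions, not errors).
#' @export
validate_annotations <- function(triplets, catalog) {
  if (inherits(triplets, "simdex_triplet_store")) triplets <- triplets$triplets
  present <- unique(tolower(triplets$attribute))
  rec <- catalog$table$ATTRIBUTE[catalog$table$RECOMMENDED]
  known <- tolower(catalog$table$ATTRIBUTE)
  hit <- tolower(rec) %in% present
  structure(list(
    completeness = if (length(rec) == 0) 1 else sum(hit) / length(rec),
    present_recommended = rec[hit],
    missing_recommended = rec[!hit],
    unknown_attributes = sort(unique(triplets$attribute[!tolower(triplets$attribute) %in% known]))),
    class = "simdex_completeness_report")
}

#' @export
print.simdex_completeness_report <- function(x, ...) {
  cat(sprintf("Annotation completeness: %.1f%% of recommended attributes present\n",
              100 * x$completeness))
  if (length(x$missing_recommended) > 0) {
    cat("Missing recommended:", paste(x$missing_recommended, collapse = ", "), "\n")
  }
  if (length(x$unknown_attributes) > 0) {
    cat("User-specific extensions:", paste(x$unknown_attributes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.simdex_cde_catalog <- function(x, ...) {
  s <- cde_stats(x)
  cat(sprintf("<CDE catalogue: %d elements, %d attributes (%d recommended), %d groups>\n",
              s$n_elements, s$n_attributes, s$n_recommended_attributes, s$n_categories))
  invisible(x)
}
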