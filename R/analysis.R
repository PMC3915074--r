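#' Descriptors for derived analysis data
#'
#' Analysis outputs (RMSD series, covariance matrices, averaged values)
#' are described the way self-describing array formats do it: named
#' dimensions with sizes, and variables referencing zero or more
#' dimensions -- zero dimensions for a scalar (an average RMSD), one for an
#' array (an RMSD time series), two for a matrix (a coordinate
#' covariance). A provenance record states how the data was derived: the
#' analysis method, the program and version, the exact command, the
#' execution timestamp and the optional reference system. Optional filters
#' (file dependencies, time window, atom selection) support currency
#' checking and detailed searches; atom selections are kept as opaque
#' program-tagged strings, never translated to a common syntax.
#'
#' Descriptors persist as JSON sidecar documents next to the analysis file.
#'
#' @name analysis-descriptors
NULL

#' Describe value collections as dimensioned variables
#'
#' @param datasets named list; each element a scalar, vector, matrix or
#'   array of values (or a data.frame, taken as a matrix). Ragged lists are
#'   rejected.
#' @param value_type reported value type for all datasets (e.g. "float").
#' @return list with \code{dimensions} (named sizes) and \code{variables}
#'   (name, value type, units placeholder, dimension references); variable
#'   dimensionality equals the dataset's shape rank.
#' @export
describe_variables <- function(datasets, value_type = "float") {
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    stopf("simdex_usage_error", "datasets must be a named list")
  }
  dims <- list()
  vars <- list()
  for (nm in names(datasets)) {
    x <- datasets[[nm]]
    if (is.data.frame(x)) x <- as.matrix(x)
    if (is.list(x)) {
      lens <- lengths(x)
      if (length(unique(lens)) > 1) {
        stopf("simdex_shape_error", "dataset '%s' is ragged (row lengths %s)",
              nm, paste(unique(lens), collapse = ", "))
      }
      x <- if (length(x) == 0) numeric() else do.call(rbind, x)
    }
    shape <- if (!is.null(dim(x))) dim(x) else if (length(x) == 1) integer() else length(x)
    dim_refs <- character()
    for (k in seq_along(shape)) {
      dname <- sprintf("%s_dim%d", nm, k)
      dims[[dname]] <- as.integer(shape[k])
      dim_refs <- c(dim_refs, dname)
    }
    vars[[length(vars) + 1L]] <- list(
      name = nm, type = value_type, labels = NULL, units = NULL,
      dimensions = dim_refs)
  }
  list(dimensions = dims, variables = vars)
}

#' Build an analysis provenance record
#'
#' @param method analysis method name (e.g. "RMSD"); see the packaged
#'   \code{md_analysis_method} dictionary for standard entries.
#' @param description method description (e.g. "Root mean square deviation
#'   calculation").
#' @param program program name, non-empty.
#' @param version program version.
#' @param command the actual command executed.
#' @param inputs optional input file path(s) describing the task.
#' @param timestamp execution timestamp (ISO string).
#' @param reference optional reference system: \code{"self"},
#'   \code{"experimental"} or \code{"other simulated structure"}.
#' @return a \code{simdex_provenance} record.
#' @export
build_provenance <- function(method, description = NULL, program,
                             version = NULL, command = NULL, inputs = NULL,
                             timestamp = NULL, reference = NULL) {
  assert_string(method, "method")
  assert_string(program, "program")
  if (!is.null(reference)) {
    reference <- match.arg(reference,
                           c("self", "experimental", "other simulated structure"))
  }
  structure(list(method_name = method, method_description = description,
                 program = program, program_version = version,
                 command = command, input_path = inputs,
                 timestamp = timestamp, reference_system = reference),
            class = "simdex_provenance")
}

#' Assemble a full analysis-data descriptor
#'
#' @param variables result of \code{\link{describe_variables}}.
#' @param provenance a \code{simdex_provenance}.
#' @param file_dependencies optional character vector of files the analysis
#'   derives from (e.g. the trajectory used).
#' @param time_filter optional time window / frame subset description.
#' @param space_filter optional opaque atom-selection string.
#' @param space_filter_program program whose selection syntax
#'   \code{space_filter} uses.
#' @return a \code{simdex_analysis_descriptor}.
#' @export
analysis_descriptor <- function(variables, provenance,
                                file_dependencies = NULL, time_filter = NULL,
                                space_filter = NULL,
                                space_filter_program = NULL) {
  structure(list(dimensions = variables$dimensions,
                 variables = variables$variables,
                 provenance = provenance,
                 filters = list(file_dependencies = file_dependencies,
                                time_filter = time_filter,
                                space_filter = space_filter,
                                space_filter_program = space_filter_program)),
            class = "simdex_analysis_descriptor")
}

#' Check whether analysis data is current with respect to its inputs
#'
#' An analysis is stale when any file it depends on is newer than the
#' analysis artifact itself. Comparison uses whole-second resolution; ties
#' count as current. A dependency with no available timestamp makes the
#' answer unknown.
#'
#' @param descriptor a \code{simdex_analysis_descriptor} listing file
#'   dependencies.
#' @param analysis_mtime modification time of the analysis artifact
#'   (POSIXct or epoch seconds).
#' @param timestamps named vector/list mapping dependency paths to
#'   modification times; missing or NA entries are unavailable.
#' @return \code{"current"}, \code{"needs_update"} or \code{"unknown"}.
#' @export
check_currency <- function(descriptor, analysis_mtime, timestamps) {
  deps <- descriptor$filters$file_dependencies
  if (is.null(deps) || length(deps) == 0) return("unknown")
  secs <- function(x) floor(as.numeric(x))
  a <- secs(analysis_mtime)
  status <- "current"
  for (d in deps) {
    t <- timestamps[[d]]
    if (is.null(t) || is.na(t)) return("unknown")
    if (secs(t) > a) status <- "needs_update"
  }
  status
}

#' Write / read descriptor sidecar documents
#'
#' The sidecar is a JSON document stored next to the analysis file
#' (\code{<file>.simdex.json}); writing then reading restores the
#' descriptor losslessly.
#'
#' @param descriptor a \code{simdex_analysis_descriptor}.
#' @param path sidecar path.
#' @export
write_descriptor <- function(descriptor, path) {
  jsonlite::write_json(unclass_deep(descriptor), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_descriptor
#' @export
read_descriptor <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  vars <- lapply(x$variables, function(v) {
    list(name = v$name, type = v$type, labels = v$labels,
         units = v$units,
         dimensions = as.character(unlist(v$dimensions)))
  })
  dims <- lapply(x$dimensions, as.integer)
  prov <- structure(lapply(x$provenance, function(f) {
    if (is.list(f)) as.character(unlist(f)) else f
  }), class = "simdex_provenance")
  filters <- x$filters
  structure(list(
    dimensions = dims, variables = vars, provenance = prov,
    filters = list(
      file_dependencies = if (!is.null(filters$file_dependencies)) {
        as.character(unlist(filters$file_dependencies))
      },
      time_filter = filters$time_filter,
      space_filter = filters$space_filter,
      space_filter_program = filters$space_filter_program)),
    class = "simdex_analysis_descriptor")
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
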