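#' Attribute-value-unit triplet store
#'
#' Experiments, their entities and their files are indexed as
#' attribute-value-unit (AVU) triplets, the flat annotation form used to
#' tag files and directories in annotation-based repositories. A store
#' holds one data.frame of triplets plus an optional CDE catalogue used to
#' flag attributes as standard (catalogue) or user-specific.
#'
#' @param triplets data.frame with columns \code{subject},
#'   \code{subject_type}, \code{attribute}, \code{value}, \code{unit},
#'   \code{standard}.
#' @param catalog optional \code{simdex_cde_catalog}.
#' @export
triplet_store <- function(triplets = empty_triplets(), catalog = NULL) {
  structure(list(triplets = triplets, catalog = catalog),
            class = "simdex_triplet_store")
}

empty_triplets <- function() {
  data.frame(subject = character(), subject_type = character(),
             attribute = character(), value = character(),
             unit = character(), standard = logical(),
             stringsAsFactors = FALSE)
}

avu_row <- function(subject, subject_type, attribute, value, unit = NA_character_) {
  data.frame(subject = subject, subject_type = subject_type,
             attribute = attribute, value = canonical_value(value),
             unit = unit %||% NA_character_, standard = NA,
             stringsAsFactors = FALSE)
}

# numbers without exponent padding, strings trimmed; units copied verbatim
canonical_value <- function(x) {
  if (is.numeric(x)) return(format(x, scientific = FALSE, trim = TRUE))
  if (is.logical(x)) return(tolower(as.character(x)))
  trimws(as.character(x))
}

#' Field-to-attribute flattening map
#'
#' The versioned table mapping model entity fields to AVU attribute names;
#' attribute names coincide with the CDE catalogue's attribute column so
#' flattened experiments can be checked for completeness. Attributes marked
#' derived are not stored on entities but computed through the dictionaries
#' at flattening time (force-field type from the force-field name, QM
#' method class/family from the method name, basis-set type from the
#' basis-set name).
#'
#' @return data.frame with columns \code{entity}, \code{field},
#'   \code{attribute}, \code{derived}.
#' @export
avu_attribute_map <- function() {
  m <- rbind(
    c("experiment", "id", "experiment_id", FALSE),
    c("experiment", "name", "experiment_name", FALSE),
    c("experiment", "role", "experiment_role", FALSE),
    c("author", "name", "author_name", FALSE),
    c("citation", "text", "citation_identifier", FALSE),
    c("grant", "agency", "funding_agency", FALSE),
    c("grant", "number", "grant_number", FALSE),
    c("system", "name", "system_name", FALSE),
    c("molecule", "name", "molecule_name", FALSE),
    c("molecule", "count", "molecule_count", FALSE),
    c("molecule", "normalized_chain", "normalized_chain", FALSE),
    c("molecule", "chain", "specific_chain", FALSE),
    c("task", "method_name", "method_name", FALSE),
    c("task", "boundary_conditions", "boundary_conditions", FALSE),
    c("task", "solvent_type", "solvent_type", FALSE),
    c("task", "conditions.reference_temperature", "reference_temperature", FALSE),
    c("task", "conditions.reference_pressure", "reference_pressure", FALSE),
    c("task", "software.name", "software_name", FALSE),
    c("task", "software.version", "software_version", FALSE),
    c("task", "software.executable", "executable_name", FALSE),
    c("task", "environment.os", "operating_system", FALSE),
    c("task", "environment.cpu_architecture", "cpu_architecture", FALSE),
    c("task", "environment.gpu_architecture", "gpu_architecture", FALSE),
    c("task", "environment.machine_architecture", "machine_architecture", FALSE),
    c("task", "environment.machine_name", "machine_name", FALSE),
    c("task", "execution.start", "start_time", FALSE),
    c("task", "execution.end", "end_time", FALSE),
    c("task", "execution.elapsed", "elapsed_time", FALSE),
    c("task", "execution.termination_status", "termination_status", FALSE),
    c("md_parameter_set", "force_fields.name", "force_field_name", FALSE),
    c("md_parameter_set", "force_fields.name->force_field.TYPE_ID", "force_field_type", TRUE),
    c("md_parameter_set", "barostat.implementation", "barostat_implementation", FALSE),
    c("md_parameter_set", "thermostat.implementation", "thermostat_implementation", FALSE),
    c("md_parameter_set", "ensemble", "ensemble_type", FALSE),
    c("md_parameter_set", "constraints.algorithm", "constraint_algorithm", FALSE),
    c("md_parameter_set", "constraints.target", "constraint_target", FALSE),
    c("md_parameter_set", "restraints.property", "restrained_property", FALSE),
    c("md_parameter_set", "restraints.target", "restraint_target", FALSE),
    c("md_parameter_set", "electrostatics_model", "electrostatics_model", FALSE),
    c("md_parameter_set", "collision_frequency", "collision_frequency", FALSE),
    c("md_parameter_set", "n_steps", "number_of_steps", FALSE),
    c("md_parameter_set", "step_length", "step_length", FALSE),
    c("qm_parameter_set", "method", "qm_method_name", FALSE),
    c("qm_parameter_set", "method->qm_method.CLASS_ID", "qm_method_class", TRUE),
    c("qm_parameter_set", "method->qm_method_class.FAMILY_ID", "qm_method_family", TRUE),
    c("qm_parameter_set", "basis_set", "basis_set_name", FALSE),
    c("qm_parameter_set", "basis_set->basis_set.BASIS_TYPE", "basis_set_type", TRUE),
    c("qm_parameter_set", "frozen_core", "frozen_core_flag", FALSE),
    c("qm_parameter_set", "pseudopotentials", "pseudopotentials_flag", FALSE),
    c("qm_parameter_set", "plane_wave_cutoff", "plane_wave_cutoff", FALSE),
    c("qm_parameter_set", "convergence_flag", "convergence_flag", FALSE),
    c("qm_parameter_set", "convergence_criteria", "convergence_criteria", FALSE),
    c("file", "format", "file_format", FALSE),
    c("file", "role", "file_role", FALSE),
    c("file", "size", "file_size", FALSE))
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- c("entity", "field", "attribute", "derived")
  out$derived <- as.logical(out$derived)
  out
}

#' Flatten an experiment into AVU triplets
#'
#' Emits one triplet per mapped attribute with a value, on subjects of type
#' experiment, system, task or file; derived attributes (force-field type,
#' QM method class and family, basis-set type) are materialized when the
#' dictionaries resolve the specific names. Flattening is deterministic and
#' idempotent.
#'
#' @param exp a valid \code{experiment}.
#' @param dictionaries optional dictionary set for derived attributes.
#' @return triplet data.frame (see \code{\link{triplet_store}}).
#' @export
flatten_to_triplets <- function(exp, dictionaries = NULL) {
  rows <- list()
  put <- function(...) rows[[length(rows) + 1L]] <<- avu_row(...)
  eid <- exp$id

  put(eid, "experiment", "experiment_id", exp$id)
  put(eid, "experiment", "experiment_name", exp$name)
  if (!is.null(exp$role)) put(eid, "experiment", "experiment_role", exp$role)
  if (!is.null(exp$author)) put(eid, "experiment", "author_name", exp$author$name)
  for (ct in exp$citations) put(eid, "experiment", "citation_identifier", ct$text)
  for (g in exp$grants) {
    put(eid, "experiment", "funding_agency", g$agency)
    if (!is.null(g$number)) put(eid, "experiment", "grant_number", g$number)
  }
  emit_extended <- function(subject, type, entity) {
    for (t in entity$extended %||% list()) {
      put(subject, type, t$attribute, t$value, t$unit)
    }
  }
  emit_extended(eid, "experiment", exp)

  for (s in exp$systems) {
    if (!is.null(s$name)) put(s$id, "system", "system_name", s$name)
    for (m in s$molecules) {
      put(s$id, "system", "molecule_name", m$name)
      put(s$id, "system", "molecule_count", m$count)
      if (!is.null(m$chain)) put(s$id, "system", "specific_chain", paste(m$chain, collapse = " "))
      if (!is.null(m$normalized_chain)) put(s$id, "system", "normalized_chain", m$normalized_chain)
    }
    emit_extended(s$id, "system", s)
  }

  for (fs in exp$file_collections) {
    for (f in fs$files) {
      if (!is.null(f$format)) put(f$uid, "file", "file_format", f$format)
      if (!is.null(f$role)) put(f$uid, "file", "file_role", f$role)
      if (!is.null(f$size)) put(f$uid, "file", "file_size", f$size, "bytes")
    }
  }

  scalar <- function(subject, type, attr, val, unit = NA_character_) {
    if (!is.null(val)) put(subject, type, attr, val, unit)
  }
  for (pg in exp$process_groups) {
    for (pr in pg$processes) {
      for (tk in pr$tasks) {
        tid <- tk$id
        scalar(tid, "task", "method_name", tk$method_name)
        scalar(tid, "task", "boundary_conditions", tk$boundary_conditions)
        scalar(tid, "task", "solvent_type", tk$solvent_type)
        if (!is.null(tk$conditions)) {
          scalar(tid, "task", "reference_temperature", tk$conditions$reference_temperature)
          scalar(tid, "task", "reference_pressure", tk$conditions$reference_pressure)
        }
        if (!is.null(tk$software)) {
          scalar(tid, "task", "software_name", tk$software$name)
          scalar(tid, "task", "software_version", tk$software$version)
          scalar(tid, "task", "executable_name", tk$software$executable)
        }
        if (!is.null(tk$environment)) {
          env <- tk$environment
          scalar(tid, "task", "operating_system", env$os)
          scalar(tid, "task", "cpu_architecture", env$cpu_architecture)
          scalar(tid, "task", "gpu_architecture", env$gpu_architecture)
          scalar(tid, "task", "machine_architecture", env$machine_architecture)
          scalar(tid, "task", "machine_name", env$machine_name)
        }
        if (!is.null(tk$execution)) {
          scalar(tid, "task", "start_time", tk$execution$start)
          scalar(tid, "task", "end_time", tk$execution$end)
          scalar(tid, "task", "elapsed_time", tk$execution$elapsed, "s")
          scalar(tid, "task", "termination_status", tk$execution$termination_status)
        }
        for (ps_id in tk$parameter_set_ids) {
          ps <- exp$parameter_sets[[ps_id]]
          if (is.null(ps)) next
          flatten_parameter_set(ps, tid, dictionaries, put, scalar)
        }
        emit_extended(tid, "task", tk)
      }
    }
  }

  if (length(rows) == 0) return(empty_triplets())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  unique(out)
}

flatten_parameter_set <- function(ps, tid, dictionaries, put, scalar) {
  kind <- class(ps)[1]
  if (kind == "simdex_md_parameter_set") {
    for (ff in ps$force_fields) {
      put(tid, "task", "force_field_name", ff$name)
      if (!is.null(dictionaries) && !is.null(dictionaries[["force_field"]])) {
        e <- lookup_term(dictionaries[["force_field"]], ff$name)
        if (!is.null(e) && "TYPE_ID" %in% names(e$links)) {
          put(tid, "task", "force_field_type",
              resolve_link(e, "TYPE_ID", dictionaries)$term)
        }
      }
    }
    if (!is.null(ps$barostat)) scalar(tid, "task", "barostat_implementation", ps$barostat$implementation)
    if (!is.null(ps$thermostat)) scalar(tid, "task", "thermostat_implementation", ps$thermostat$implementation)
    scalar(tid, "task", "ensemble_type", ps$ensemble)
    for (cn in ps$constraints) {
      put(tid, "task", "constraint_algorithm", cn$algorithm)
      put(tid, "task", "constraint_target", cn$target)
    }
    for (rs in ps$restraints) {
      put(tid, "task", "restrained_property", rs$property)
      put(tid, "task", "restraint_target", rs$target)
    }
    scalar(tid, "task", "electrostatics_model", ps$electrostatics_model)
    scalar(tid, "task", "collision_frequency", ps$collision_frequency)
    scalar(tid, "task", "number_of_steps", ps$n_steps)
    scalar(tid, "task", "step_length", ps$step_length)
  } else if (kind == "simdex_qm_parameter_set") {
    put(tid, "task", "qm_method_name", ps$method)
    if (!is.null(dictionaries)) {
      cls <- classify_method(ps$method, dictionaries)
      if (!is.null(cls$method_class)) put(tid, "task", "qm_method_class", cls$method_class)
      if (!is.null(cls$method_family)) put(tid, "task", "qm_method_family", cls$method_family)
    }
    if (!is.null(ps$basis_set)) {
      put(tid, "task", "basis_set_name", ps$basis_set)
      if (!is.null(dictionaries) && !is.null(dictionaries[["basis_set"]])) {
        e <- lookup_term(dictionaries[["basis_set"]], ps$basis_set)
        if (!is.null(e) && !is.null(e$extras[["BASIS_TYPE"]])) {
          put(tid, "task", "basis_set_type", e$extras[["BASIS_TYPE"]])
        }
      }
    }
    scalar(tid, "task", "frozen_core_flag", ps$frozen_core)
    scalar(tid, "task", "pseudopotentials_flag", ps$pseudopotentials)
    scalar(tid, "task", "plane_wave_cutoff", ps$plane_wave_cutoff)
    scalar(tid, "task", "convergence_flag", ps$convergence_flag)
    scalar(tid, "task", "convergence_criteria", ps$convergence_criteria)
  } else if (kind == "simdex_qmmm_parameter_set") {
    scalar(tid, "task", "boundary_treatment", ps$boundary_treatment)
  }
  for (t in ps$extended %||% list()) put(tid, "task", t$attribute, t$value, t$unit)
  invisible(NULL)
}

#' Tag a subject with an annotation triplet
#'
#' Attributes recognized by the store's catalogue are flagged standard;
#' anything else is accepted and flagged user-specific (lab-specific
#' attributes are data, not errors).
#'
#' @param store a \code{simdex_triplet_store}.
#' @param subject subject identifier (file uid, directory, entity id).
#' @param attribute non-empty attribute name.
#' @param value value (serialized to string).
#' @param unit optional unit string.
#' @param subject_type optional subject type label.
#' @return the updated store.
#' @export
tag_subject <- function(store, subject, attribute, value, unit = NULL,
                        subject_type = "user") {
  assert_string(attribute, "attribute")
  row <- avu_row(subject, subject_type, attribute, value, unit)
  row$standard <- is_standard_attribute(attribute, store$catalog)
  store$triplets <- rbind(store$triplets, row)
  store
}

is_standard_attribute <- function(attribute, catalog) {
  if (is.null(catalog)) return(NA)
  tolower(attribute) %in% tolower(catalog$table$ATTRIBUTE)
}

#' Query a triplet store
#'
#' Returns the subjects satisfying the conjunction of all predicates. Each
#' predicate is \code{list(attribute, comparator, value)} with comparator
#' \code{"=="} (case-sensitive equality) or \code{"contains"}
#' (case-insensitive substring). Results equal a linear scan of the store
#' with the same predicates.
#'
#' @param store a \code{simdex_triplet_store}.
#' @param predicates non-empty list of predicates.
#' @return sorted character vector of matching subjects.
#' @export
query_index <- function(store, predicates) {
  if (length(predicates) == 0) stopf("simdex_usage_error", "predicates must be non-empty")
  if (!is.list(predicates[[1]]) && !is.character(predicates[[1]])) {
    predicates <- list(predicates)
  }
  tt <- store$triplets
  result <- NULL
  for (p in predicates) {
    p <- as.list(p)
    if (length(p) != 3) stopf("simdex_usage_error", "predicate must be (attribute, comparator, value)")
    attr_ <- p[[1]]; cmp <- p[[2]]; val <- canonical_value(p[[3]])
    hit <- tt$attribute == attr_
    matched <- switch(cmp,
      "==" = hit & tt$value == val,
      "contains" = hit & grepl(tolower(val), tolower(tt$value), fixed = TRUE),
      stopf("simdex_usage_error", "unknown comparator '%s'", cmp))
    subjects <- unique(tt$subject[matched])
    result <- if (is.null(result)) subjects else intersect(result, subjects)
    if (length(result) == 0) break
  }
  sort(result)
}
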