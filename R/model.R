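#' Logical model of virtual experiments
#'
#' A virtual experiment is the full set of dependent computational tasks and
#' files constituting one simulation study. It decomposes into process
#' groups (all tasks target the same molecular system; one group per
#' simulated copy or subsystem), processes (series of similar tasks, e.g.
#' minimization, heating, production MD) and tasks (single computational
#' runs). Tasks reference reusable method parameter sets (MD, QM, QM/MM)
#' kept in a per-experiment registry, and raw files hosted on file systems.
#' Every entity can carry extended attributes: attribute-value-unit triplets
#' with an optional concept identifier, for properties the model does not
#' represent natively.
#'
#' Constructors are plain functions returning classed lists; fields left
#' \code{NULL} mean "not recorded" and are never invented downstream.
#'
#' @name experiment-model
NULL

new_entity <- function(class, fields) {
  fields$extended <- fields$extended %||% list()
  structure(fields, class = c(class, "simdex_entity"))
}

#' @rdname experiment-model
#' @param id,name,role experiment identity; \code{role} is the general
#'   rationale (e.g. "simulation", "geometry optimization", "docking").
#' @param author,citations,grants authorship context.
#' @param systems named list of molecular systems.
#' @param parameter_sets named registry of parameter sets referenced by id
#'   from tasks.
#' @param process_groups list of process groups.
#' @param file_collections list of file system references.
#' @param extended list of extended attributes.
#' @export
experiment <- function(id, name, role = "simulation", author = NULL,
                       citations = list(), grants = list(),
                       systems = list(), parameter_sets = list(),
                       process_groups = list(), file_collections = list(),
                       extended = list()) {
  assert_string(id, "id"); assert_string(name, "name")
  new_entity("simdex_experiment", list(
    id = id, name = name, role = role, author = author,
    citations = citations, grants = grants,
    systems = systems, parameter_sets = parameter_sets,
    process_groups = process_groups, file_collections = file_collections,
    extended = extended))
}

#' @rdname experiment-model
#' @param members list of experiments (or experiment ids).
#' @export
experiment_set <- function(name, members = list()) {
  ids <- vapply(members, function(m) if (is.character(m)) m else m$id, character(1))
  if (anyDuplicated(ids)) stopf("simdex_usage_error", "duplicate experiment in set '%s'", name)
  structure(list(name = name, members = members), class = "simdex_experiment_set")
}

#' @rdname experiment-model
#' @param system_id id of the molecular system all processes in the group target.
#' @param processes list of processes.
#' @param depends_on character vector of ids of prerequisite entities of the
#'   same kind.
#' @export
process_group <- function(id, system_id, processes = list(), depends_on = character()) {
  new_entity("simdex_process_group", list(
    id = id, system_id = system_id, processes = processes,
    depends_on = depends_on))
}

#' @rdname experiment-model
#' @param tasks list of experiment tasks (similar kind).
#' @export
process <- function(id, tasks = list(), depends_on = character()) {
  new_entity("simdex_process", list(id = id, tasks = tasks, depends_on = depends_on))
}

#' @rdname experiment-model
#' @param kind task kind: \code{"minimization"}, \code{"md"}, \code{"qm"} or
#'   \code{"qmmm"}.
#' @param method_name,description method identification.
#' @param boundary_conditions \code{"periodic"} or \code{"non-periodic"}.
#' @param solvent_type \code{"vacuum"}, \code{"implicit"} or \code{"explicit"}.
#' @param calculation calculation-type term(s).
#' @param conditions a \code{simulated_conditions}.
#' @param environment a \code{computing_environment}.
#' @param execution a \code{task_execution}.
#' @param software a \code{software} record.
#' @param parameter_set_ids ids into the experiment's parameter-set registry.
#' @param file_uids uids of the task's input/output files.
#' @export
experiment_task <- function(id, kind, method_name = NULL, description = NULL,
                            boundary_conditions = NULL, solvent_type = NULL,
                            calculation = NULL, conditions = NULL,
                            environment = NULL, execution = NULL,
                            software = NULL, parameter_set_ids = character(),
                            file_uids = character(), depends_on = character(),
                            extended = list()) {
  kind <- match.arg(kind, c("minimization", "md", "qm", "qmmm"))
  new_entity("simdex_task", list(
    id = id, kind = kind, method_name = method_name, description = description,
    boundary_conditions = boundary_conditions, solvent_type = solvent_type,
    calculation = calculation, conditions = conditions,
    environment = environment, execution = execution, software = software,
    parameter_set_ids = parameter_set_ids, file_uids = file_uids,
    depends_on = depends_on, extended = extended))
}

#' @rdname experiment-model
#' @param reference_temperature,reference_pressure simulated conditions;
#'   non-negative when present (units are carried alongside the values
#'   elsewhere and never converted).
#' @export
simulated_conditions <- function(reference_temperature = NULL,
                                 reference_pressure = NULL) {
  structure(list(reference_temperature = reference_temperature,
                 reference_pressure = reference_pressure),
            class = "simdex_conditions")
}

#' @rdname experiment-model
#' @param os,cpu_architecture,gpu_architecture,machine_architecture,machine_name
#'   computing environment description.
#' @export
computing_environment <- function(os = NULL, cpu_architecture = NULL,
                                  gpu_architecture = NULL,
                                  machine_architecture = NULL,
                                  machine_name = NULL) {
  structure(list(os = os, cpu_architecture = cpu_architecture,
                 gpu_architecture = gpu_architecture,
                 machine_architecture = machine_architecture,
                 machine_name = machine_name),
            class = "simdex_environment")
}

#' @rdname experiment-model
#' @param start,end timestamps (ISO strings); \code{elapsed} seconds;
#'   \code{termination_status} e.g. "normal", "error", "incomplete".
#' @export
task_execution <- function(start = NULL, end = NULL, elapsed = NULL,
                           termination_status = NULL) {
  structure(list(start = start, end = end, elapsed = elapsed,
                 termination_status = termination_status),
            class = "simdex_execution")
}

#' @rdname experiment-model
#' @param version,executable software identification; the executable name can
#'   carry build information (see \code{\link{parse_executable_name}}).
#' @export
software <- function(name, version = NULL, executable = NULL) {
  structure(list(name = name, version = version, executable = executable),
            class = "simdex_software")
}

#' Method parameter sets
#'
#' Parameter sets bundle the method settings a task was run with; they are
#' registered on the experiment and referenced by id so several tasks (e.g.
#' REMD replicas) can share one set. MD sets describe the classical force
#' field(s), pressure/temperature coupling, ensemble, constraints and
#' restraints, electrostatics model and integration steps; the collision
#' frequency is only meaningful for stochastic (Langevin/Brownian) dynamics.
#' QM sets retain the specific method and basis-set names verbatim plus the
#' standard approximations (frozen core, pseudopotentials, plane-wave
#' cutoff); QM/MM sets describe the boundary treatment between the regions.
#'
#' @param id registry id.
#' @param force_fields list of \code{force_field}; an MD task needs at least one.
#' @param barostat,thermostat optional coupling records.
#' @param ensemble ensemble term (microcanonical, canonical,
#'   isothermal-isobaric, generalized).
#' @param constraints,restraints lists of \code{constraint}/\code{restraint}.
#' @param electrostatics_model e.g. "PME".
#' @param collision_frequency optional rate (stochastic dynamics only).
#' @param n_steps,step_length integration steps and step length.
#' @param extended extended attributes.
#' @export
md_parameter_set <- function(id, force_fields = list(), barostat = NULL,
                             thermostat = NULL, ensemble = NULL,
                             constraints = list(), restraints = list(),
                             electrostatics_model = NULL,
                             collision_frequency = NULL, n_steps = NULL,
                             step_length = NULL, extended = list()) {
  new_entity("simdex_md_parameter_set", list(
    id = id, force_fields = force_fields, barostat = barostat,
    thermostat = thermostat, ensemble = ensemble, constraints = constraints,
    restraints = restraints, electrostatics_model = electrostatics_model,
    collision_frequency = collision_frequency, n_steps = n_steps,
    step_length = step_length, extended = extended))
}

#' @rdname md_parameter_set
#' @param method specific method name (always retained).
#' @param basis_set specific basis-set name.
#' @param frozen_core,pseudopotentials approximation flags.
#' @param plane_wave_cutoff optional energy cutoff.
#' @param convergence_flag,convergence_criteria optional convergence record.
#' @export
qm_parameter_set <- function(id, method, basis_set = NULL, frozen_core = NULL,
                             pseudopotentials = NULL, plane_wave_cutoff = NULL,
                             convergence_flag = NULL,
                             convergence_criteria = NULL, extended = list()) {
  assert_string(method, "method")
  new_entity("simdex_qm_parameter_set", list(
    id = id, method = method, basis_set = basis_set,
    frozen_core = frozen_core, pseudopotentials = pseudopotentials,
    plane_wave_cutoff = plane_wave_cutoff,
    convergence_flag = convergence_flag,
    convergence_criteria = convergence_criteria, extended = extended))
}

#' @rdname md_parameter_set
#' @param boundary_treatment description of the QM/MM boundary treatment.
#' @export
qmmm_parameter_set <- function(id, boundary_treatment, extended = list()) {
  new_entity("simdex_qmmm_parameter_set", list(
    id = id, boundary_treatment = boundary_treatment, extended = extended))
}

#' @rdname md_parameter_set
#' @param name specific force-field name as referenced by the run (kept even
#'   when no dictionary entry matches).
#' @export
force_field <- function(name) {
  assert_string(name, "name")
  structure(list(name = name), class = "simdex_force_field")
}

#' @rdname md_parameter_set
#' @param implementation barostat/thermostat implementation name.
#' @param time_constant,chain_length optional coupling extras.
#' @export
barostat <- function(implementation, time_constant = NULL, chain_length = NULL) {
  structure(list(implementation = implementation, time_constant = time_constant,
                 chain_length = chain_length), class = "simdex_barostat")
}

#' @rdname md_parameter_set
#' @export
thermostat <- function(implementation, time_constant = NULL, chain_length = NULL) {
  structure(list(implementation = implementation, time_constant = time_constant,
                 chain_length = chain_length), class = "simdex_thermostat")
}

#' @rdname md_parameter_set
#' @param algorithm constraint algorithm (e.g. SHAKE, LINCS).
#' @param target the atoms it applies to: an atom mask or textual
#'   description (e.g. ":WAT", "bonds involving hydrogen"); non-empty.
#' @export
constraint <- function(algorithm, target) {
  assert_string(target, "target")
  structure(list(algorithm = algorithm, target = target),
            class = "simdex_constraint")
}

#' @rdname md_parameter_set
#' @param property restrained property (e.g. "bond", "angle", "position").
#' @export
restraint <- function(property, target) {
  assert_string(target, "target")
  structure(list(property = property, target = target),
            class = "simdex_restraint")
}

#' Authorship records
#' @param name,institution,contact author fields.
#' @export
author <- function(name, institution = NULL, contact = NULL) {
  structure(list(name = name, institution = institution, contact = contact),
            class = "simdex_author")
}

#' @rdname author
#' @param text free text or identifier (e.g. a DOI).
#' @export
citation_ref <- function(text) structure(list(text = text), class = "simdex_citation")

#' @rdname author
#' @param agency,number grant fields.
#' @export
grant <- function(agency, number = NULL) {
  structure(list(agency = agency, number = number), class = "simdex_grant")
}

#' Molecular system composition
#'
#' Structural data is minimized to occurrence counts: each molecule records
#' how many times each residue and each atomic element occurs (water is one
#' H entry with count 2 and one O entry with count 1), plus the molecule
#' count in the system (e.g. the number of explicit water molecules).
#' Biomolecules additionally carry the ordered residue chain as found in the
#' topology (specific chain) and its one-letter normalized form.
#'
#' @param id,name system identity.
#' @param molecules list of \code{molecule}.
#' @param topology_file_uid uid of the topology file, which belongs to the
#'   system rather than to any task.
#' @param extended extended attributes.
#' @export
molecular_system <- function(id, name = NULL, molecules = list(),
                             topology_file_uid = NULL, extended = list()) {
  new_entity("simdex_system", list(
    id = id, name = name, molecules = molecules,
    topology_file_uid = topology_file_uid, extended = extended))
}

#' @rdname molecular_system
#' @param count number of copies of this molecule in the system.
#' @param kind "biomolecule", "small molecule", "solvent" or "ion".
#' @param residues data.frame with columns \code{name}, \code{count}.
#' @param atoms data.frame with columns \code{element}, \code{count}.
#' @param chain ordered character vector of specific residue symbols
#'   (biomolecules only).
#' @param normalized_chain one-letter normalized sequence string.
#' @export
molecule <- function(name, count = 1L, kind = "biomolecule",
                     residues = NULL, atoms = NULL, chain = NULL,
                     normalized_chain = NULL) {
  structure(list(name = name, count = as.integer(count), kind = kind,
                 residues = residues, atoms = atoms, chain = chain,
                 normalized_chain = normalized_chain),
            class = "simdex_molecule")
}

#' File system references
#' @param type file-system type (e.g. "NFS", "object store", "local").
#' @param host,protocol access route.
#' @param files list of \code{file_reference}.
#' @export
file_system_ref <- function(type = "local", host = NULL, protocol = NULL,
                            files = list()) {
  uids <- vapply(files, function(f) f$uid, character(1))
  if (anyDuplicated(uids)) {
    stopf("simdex_usage_error", "duplicate file uid within a file system: %s",
          paste(unique(uids[duplicated(uids)]), collapse = ", "))
  }
  structure(list(type = type, host = host, protocol = protocol, files = files),
            class = "simdex_file_system")
}

#' @rdname file_system_ref
#' @param uid unique identifier within the host file system.
#' @param path,format,role,size file description; role is "input", "output"
#'   or "topology".
#' @export
file_reference <- function(uid, path, format = NULL, role = NULL, size = NULL) {
  if (!is.null(role)) role <- match.arg(role, c("input", "output", "topology"))
  structure(list(uid = uid, path = path, format = format, role = role,
                 size = size), class = "simdex_file")
}

# ---- extended attributes -------------------------------------------------

#' Attach an extended attribute (attribute-value-unit triplet) to an entity
#'
#' Extended attributes are multi-valued: attaching the same attribute twice
#' records two coexisting triplets.
#'
#' @param entity any model entity created by the constructors in this
#'   package.
#' @param attribute non-empty attribute name.
#' @param value value, serialized as a string.
#' @param unit optional unit string (copied verbatim, never converted).
#' @param concept_id optional reference into an external terminology.
#' @return the entity with one more triplet in its \code{extended} list.
#' @export
attach_extended_attribute <- function(entity, attribute, value,
                                      unit = NULL, concept_id = NULL) {
  if (!inherits(entity, "simdex_entity")) {
    stopf("simdex_usage_error", "entity does not support extended attributes")
  }
  assert_string(attribute, "attribute")
  entity$extended[[length(entity$extended) + 1L]] <-
    list(attribute = attribute, value = as.character(value),
         unit = unit, concept_id = concept_id)
  entity
}

#' @rdname attach_extended_attribute
#' @description \code{remove_extended_attribute} removes the most recently
#'   attached triplet with the given attribute name (and value, when given),
#'   restoring the entity to its prior structure.
#' @export
remove_extended_attribute <- function(entity, attribute, value = NULL) {
  hits <- which(vapply(entity$extended, function(t) {
    t$attribute == attribute && (is.null(value) || t$value == value)
  }, logical(1)))
  if (length(hits) > 0) entity$extended[[hits[length(hits)]]] <- NULL
  entity
}

# ---- dependencies --------------------------------------------------------

entity_kind <- function(entity) class(entity)[1]

#' Dependency graphs between tasks, processes, or process groups
#'
#' Dependencies record the workflow between entities of one kind; the graph
#' must stay acyclic. \code{add_dependency} refuses edges between different
#' entity kinds and edges that would create a cycle (including self-edges).
#'
#' @param kind entity kind label the graph is restricted to (set on first
#'   edge when \code{NULL}).
#' @export
dependency_graph <- function(kind = NULL) {
  structure(list(kind = kind,
                 edges = data.frame(from = character(), to = character(),
                                    stringsAsFactors = FALSE)),
            class = "simdex_depgraph")
}

#' @rdname dependency_graph
#' @param from,to model entities of the same kind (\code{to} is a
#'   prerequisite of \code{from} is \emph{not} implied: the edge reads
#'   "\code{to} depends on nothing new; \code{from -> to} means \code{to}
#'   runs after \code{from}").
#' @param graph a \code{simdex_depgraph}.
#' @export
add_dependency <- function(from, to, graph) {
  if (entity_kind(from) != entity_kind(to)) {
    stopf("simdex_usage_error", "dependency endpoints must be the same entity kind (%s vs %s)",
          entity_kind(from), entity_kind(to))
  }
  if (is.null(graph$kind)) graph$kind <- entity_kind(from)
  if (graph$kind != entity_kind(from)) {
    stopf("simdex_usage_error", "graph holds %s dependencies, not %s",
          graph$kind, entity_kind(from))
  }
  edges <- rbind(graph$edges, data.frame(from = from$id, to = to$id,
                                         stringsAsFactors = FALSE))
  if (is.null(topological_order(edges))) {
    stopf("simdex_cycle_error", "edge %s -> %s would create a cycle",
          from$id, to$id)
  }
  graph$edges <- edges
  graph
}

# Kahn topological sort over an edge data.frame(from, to); NULL on cycle.
# Node order is stabilized lexicographically so the result is deterministic.
topological_order <- function(edges, nodes = NULL) {
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  if (length(nodes) == 0) return(character())
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (t in edges$to) indeg[t] <- indeg[t] + 1L
  out <- character()
  ready <- sort(names(indeg)[indeg == 0L])
  while (length(ready) > 0) {
    n <- ready[1]; ready <- ready[-1]
    out <- c(out, n)
    succ <- edges$to[edges$from == n]
    for (s in succ) {
      indeg[s] <- indeg[s] - 1L
      if (indeg[s] == 0L) ready <- sort(c(ready, s))
    }
  }
  if (length(out) != length(nodes)) return(NULL)
  out
}

# ---- validation ----------------------------------------------------------

violation <- function(path, rule, detail) {
  data.frame(path = path, rule = rule, detail = detail, stringsAsFactors = FALSE)
}

#' Validate an experiment against the model invariants
#'
#' Violations are data, not exceptions: the report lists every breached
#' invariant with the path of the offending entity. An empty report means
#' the experiment is valid. Checked invariants include: tasks belong to
#' exactly one process and processes to exactly one group; dependency
#' graphs at all three levels are acyclic and same-kind; task files resolve
#' to the experiment's file collections and topology files hang off the
#' molecular system, not a task; MD tasks reference exactly one MD set with
#' at least one force field, QM tasks one QM set, QM/MM tasks MD+QM+QM/MM
#' sets; simulated conditions are non-negative; execution end >= start.
#'
#' @param exp an \code{experiment}.
#' @return data.frame with columns \code{path}, \code{rule}, \code{detail};
#'   zero rows iff valid.
#' @export
validate_experiment <- function(exp) {
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x

  file_uids <- unlist(lapply(exp$file_collections, function(fs) {
    vapply(fs$files, function(f) f$uid, character(1))
  }))
  file_roles <- stats::setNames(
    unlist(lapply(exp$file_collections, function(fs) {
      vapply(fs$files, function(f) f$role %||% NA_character_, character(1))
    })), file_uids)

  seen_process <- character(); seen_task <- character()
  for (pg in exp$process_groups) {
    pg_path <- sprintf("experiment/%s", pg$id)
    if (!pg$system_id %in% names(exp$systems)) {
      add(violation(pg_path, "system", sprintf("unknown system '%s'", pg$system_id)))
    }
    for (pr in pg$processes) {
      pr_path <- sprintf("%s/%s", pg_path, pr$id)
      if (pr$id %in% seen_process) {
        add(violation(pr_path, "containment", "process appears in more than one group"))
      }
      seen_process <- c(seen_process, pr$id)
      kinds <- unique(vapply(pr$tasks, function(t) t$kind, character(1)))
      if (length(kinds) > 1) {
        add(violation(pr_path, "similar-tasks",
                      sprintf("process mixes task kinds: %s", paste(kinds, collapse = ", "))))
      }
      for (tk in pr$tasks) {
        tk_path <- sprintf("%s/%s", pr_path, tk$id)
        if (tk$id %in% seen_task) {
          add(violation(tk_path, "containment", "task appears in more than one process"))
        }
        seen_task <- c(seen_task, tk$id)
        for (uid in tk$file_uids) {
          if (!uid %in% file_uids) {
            add(violation(tk_path, "file", sprintf("file '%s' not in any collection", uid)))
          } else if (identical(file_roles[[uid]], "topology")) {
            add(violation(tk_path, "topology-file",
                          sprintf("topology file '%s' must attach to the molecular system", uid)))
          }
        }
        check_task_parameter_sets(tk, tk_path, exp, add)
        if (!is.null(tk$conditions)) {
          for (fld in c("reference_temperature", "reference_pressure")) {
            val <- tk$conditions[[fld]]
            if (!is.null(val) && is.finite(suppressWarnings(as.numeric(val))) &&
                as.numeric(val) < 0) {
              add(violation(tk_path, "conditions", sprintf("%s is negative", fld)))
            }
          }
        }
        ex <- tk$execution
        if (!is.null(ex) && !is.null(ex$start) && !is.null(ex$end) &&
            as.POSIXct(ex$end, tz = "UTC") < as.POSIXct(ex$start, tz = "UTC")) {
          add(violation(tk_path, "execution", "end timestamp precedes start"))
        }
      }
      check_dependency_edges(pr$tasks, pr_path, "task", add)
    }
    check_dependency_edges(pg$processes, pg_path, "process", add)
  }
  check_dependency_edges(exp$process_groups, sprintf("experiment/%s", exp$id),
                         "process group", add)

  if (length(v) == 0) {
    return(data.frame(path = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

check_task_parameter_sets <- function(tk, tk_path, exp, add) {
  sets <- exp$parameter_sets[tk$parameter_set_ids]
  for (i in seq_along(tk$parameter_set_ids)) {
    if (is.null(sets[[i]])) {
      add(violation(tk_path, "parameter-set",
                    sprintf("unknown parameter set '%s'", tk$parameter_set_ids[i])))
    }
  }
  sets <- Filter(Negate(is.null), sets)
  kinds <- vapply(sets, entity_kind, character(1))
  n_md <- sum(kinds == "simdex_md_parameter_set")
  n_qm <- sum(kinds == "simdex_qm_parameter_set")
  n_qmmm <- sum(kinds == "simdex_qmmm_parameter_set")
  need <- switch(tk$kind,
    md = n_md == 1,
    minimization = n_md <= 1,
    qm = n_qm == 1,
    qmmm = n_md == 1 && n_qm == 1 && n_qmmm == 1)
  if (!isTRUE(need)) {
    add(violation(tk_path, "parameter-set",
                  sprintf("%s task references %d MD / %d QM / %d QM/MM sets",
                          tk$kind, n_md, n_qm, n_qmmm)))
  }
  if (tk$kind %in% c("md", "qmmm")) {
    for (s in sets[kinds == "simdex_md_parameter_set"]) {
      if (length(s$force_fields) < 1) {
        add(violation(tk_path, "force-field",
                      sprintf("MD parameter set '%s' declares no force field", s$id)))
      }
    }
  }
  if (tk$kind == "qmmm") {
    for (s in sets[kinds == "simdex_qmmm_parameter_set"]) {
      if (is.null(s$boundary_treatment) || !nzchar(s$boundary_treatment)) {
        add(violation(tk_path, "qmmm-boundary",
                      sprintf("QM/MM parameter set '%s' has empty boundary treatment", s$id)))
      }
    }
  }
  invisible(NULL)
}

check_dependency_edges <- function(entities, path, level, add) {
  ids <- vapply(entities, function(e) e$id, character(1))
  edges <- do.call(rbind, lapply(entities, function(e) {
    if (length(e$depends_on) == 0) return(NULL)
    data.frame(from = e$depends_on, to = e$id, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) return(invisible(NULL))
  unknown <- setdiff(edges$from, ids)
  for (u in unknown) {
    add(violation(path, "dependency", sprintf("%s dependency on unknown id '%s'", level, u)))
  }
  edges <- edges[edges$from %in% ids, , drop = FALSE]
  if (is.null(topological_order(edges, nodes = ids))) {
    add(violation(path, "cycle", sprintf("%s dependencies contain a cycle", level)))
  }
  invisible(NULL)
}
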