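#' XML experiment documents
#'
#' Experiments serialize to an XML tree mirroring the model: entities are
#' elements, scalar fields are attributes, extended attributes are
#' dedicated \code{extendedAttribute} elements, and dependencies and
#' parameter-set usage serialize as id references (\code{dependsOn},
#' \code{parameterSetRef}) so the tree stays acyclic. \code{from_xml} is
#' the exact inverse on valid documents; unknown elements are rejected
#' with their path.
#'
#' @name experiment-xml
NULL

set_attrs <- function(node, ...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.null(v)) xml2::xml_set_attr(node, nm, canonical_value(v))
  }
  node
}

add_extended_nodes <- function(node, entity) {
  for (t in entity$extended %||% list()) {
    ch <- xml2::xml_add_child(node, "extendedAttribute")
    set_attrs(ch, attribute = t$attribute, value = t$value,
              unit = t$unit, conceptId = t$concept_id)
  }
}

add_depends_nodes <- function(node, entity) {
  for (d in entity$depends_on %||% character()) {
    set_attrs(xml2::xml_add_child(node, "dependsOn"), ref = d)
  }
}

#' Serialize an experiment to XML
#'
#' @param exp a valid \code{experiment}; invalid experiments are refused
#'   with the validation report in the error condition.
#' @return an \code{xml_document}.
#' @export
to_xml <- function(exp) {
  report <- validate_experiment(exp)
  if (nrow(report) > 0) {
    cond <- structure(
      class = c("simdex_invalid_experiment", "simdex_error", "error", "condition"),
      list(message = sprintf("experiment '%s' fails validation (%d violation(s))",
                             exp$id, nrow(report)),
           call = sys.call(-1), report = report))
    stop(cond)
  }
  doc <- xml2::xml_new_root("experiment")
  set_attrs(doc, id = exp$id, name = exp$name, role = exp$role)
  root <- xml2::xml_root(doc)
  if (!is.null(exp$author)) {
    set_attrs(xml2::xml_add_child(root, "author"), name = exp$author$name,
              institution = exp$author$institution, contact = exp$author$contact)
  }
  for (ct in exp$citations) {
    xml2::xml_set_text(xml2::xml_add_child(root, "citation"), ct$text)
  }
  for (g in exp$grants) {
    set_attrs(xml2::xml_add_child(root, "grant"), agency = g$agency, number = g$number)
  }
  add_extended_nodes(root, exp)

  for (s in exp$systems) {
    sn <- xml2::xml_add_child(root, "molecularSystem")
    set_attrs(sn, id = s$id, name = s$name, topologyFileUid = s$topology_file_uid)
    for (m in s$molecules) {
      mn <- xml2::xml_add_child(sn, "molecule")
      set_attrs(mn, name = m$name, count = m$count, kind = m$kind,
                normalizedChain = m$normalized_chain)
      if (!is.null(m$chain)) {
        xml2::xml_set_text(xml2::xml_add_child(mn, "chain"),
                           paste(m$chain, collapse = " "))
      }
      for (i in seq_len(NROW(m$residues))) {
        set_attrs(xml2::xml_add_child(mn, "residueOccurrence"),
                  name = m$residues$name[i], count = m$residues$count[i])
      }
      for (i in seq_len(NROW(m$atoms))) {
        set_attrs(xml2::xml_add_child(mn, "atomOccurrence"),
                  element = m$atoms$element[i], count = m$atoms$count[i])
      }
    }
    add_extended_nodes(sn, s)
  }

  if (length(exp$parameter_sets) > 0) {
    psn <- xml2::xml_add_child(root, "parameterSets")
    for (ps in exp$parameter_sets) add_parameter_set_node(psn, ps)
  }

  for (fs in exp$file_collections) {
    fn <- xml2::xml_add_child(root, "fileCollection")
    set_attrs(fn, type = fs$type, host = fs$host, protocol = fs$protocol)
    for (f in fs$files) {
      set_attrs(xml2::xml_add_child(fn, "file"), uid = f$uid, path = f$path,
                format = f$format, role = f$role, size = f$size)
    }
  }

  for (pg in exp$process_groups) {
    pgn <- xml2::xml_add_child(root, "processGroup")
    set_attrs(pgn, id = pg$id, systemRef = pg$system_id)
    add_depends_nodes(pgn, pg)
    for (pr in pg$processes) {
      prn <- xml2::xml_add_child(pgn, "process")
      set_attrs(prn, id = pr$id)
      add_depends_nodes(prn, pr)
      for (tk in pr$tasks) add_task_node(prn, tk)
    }
    add_extended_nodes(pgn, pg)
  }
  doc
}

add_parameter_set_node <- function(parent, ps) {
  kind <- class(ps)[1]
  if (kind == "simdex_md_parameter_set") {
    n <- xml2::xml_add_child(parent, "mdParameterSet")
    set_attrs(n, id = ps$id, ensemble = ps$ensemble,
              electrostaticsModel = ps$electrostatics_model,
              collisionFrequency = ps$collision_frequency,
              nSteps = ps$n_steps, stepLength = ps$step_length)
    for (ff in ps$force_fields) {
      set_attrs(xml2::xml_add_child(n, "forceField"), name = ff$name)
    }
    for (nm in c("barostat", "thermostat")) {
      b <- ps[[nm]]
      if (!is.null(b)) {
        set_attrs(xml2::xml_add_child(n, nm), implementation = b$implementation,
                  timeConstant = b$time_constant, chainLength = b$chain_length)
      }
    }
    for (cn in ps$constraints) {
      set_attrs(xml2::xml_add_child(n, "constraint"),
                algorithm = cn$algorithm, target = cn$target)
    }
    for (rs in ps$restraints) {
      set_attrs(xml2::xml_add_child(n, "restraint"),
                property = rs$property, target = rs$target)
    }
  } else if (kind == "simdex_qm_parameter_set") {
    n <- xml2::xml_add_child(parent, "qmParameterSet")
    set_attrs(n, id = ps$id, method = ps$method, basisSet = ps$basis_set,
              frozenCore = ps$frozen_core, pseudopotentials = ps$pseudopotentials,
              planeWaveCutoff = ps$plane_wave_cutoff,
              convergenceFlag = ps$convergence_flag,
              convergenceCriteria = ps$convergence_criteria)
  } else {
    n <- xml2::xml_add_child(parent, "qmmmParameterSet")
    set_attrs(n, id = ps$id, boundaryTreatment = ps$boundary_treatment)
  }
  add_extended_nodes(n, ps)
  n
}

add_task_node <- function(parent, tk) {
  n <- xml2::xml_add_child(parent, "task")
  set_attrs(n, id = tk$id, kind = tk$kind, methodName = tk$method_name,
            description = tk$description,
            boundaryConditions = tk$boundary_conditions,
            solventType = tk$solvent_type, calculation = tk$calculation)
  add_depends_nodes(n, tk)
  for (ref in tk$parameter_set_ids) {
    set_attrs(xml2::xml_add_child(n, "parameterSetRef"), ref = ref)
  }
  for (uid in tk$file_uids) {
    set_attrs(xml2::xml_add_child(n, "fileRef"), uid = uid)
  }
  if (!is.null(tk$conditions)) {
    set_attrs(xml2::xml_add_child(n, "simulatedConditions"),
              referenceTemperature = tk$conditions$reference_temperature,
              referencePressure = tk$conditions$reference_pressure)
  }
  if (!is.null(tk$environment)) {
    e <- tk$environment
    set_attrs(xml2::xml_add_child(n, "computingEnvironment"),
              os = e$os, cpuArchitecture = e$cpu_architecture,
              gpuArchitecture = e$gpu_architecture,
              machineArchitecture = e$machine_architecture,
              machineName = e$machine_name)
  }
  if (!is.null(tk$execution)) {
    x <- tk$execution
    set_attrs(xml2::xml_add_child(n, "taskExecution"), start = x$start,
              end = x$end, elapsed = x$elapsed,
              terminationStatus = x$termination_status)
  }
  if (!is.null(tk$software)) {
    set_attrs(xml2::xml_add_child(n, "software"), name = tk$software$name,
              version = tk$software$version, executable = tk$software$executable)
  }
  add_extended_nodes(n, tk)
  n
}

# ---- reading -------------------------------------------------------------

a_chr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}
a_num <- function(node, name) {
  v <- a_chr(node, name)
  if (is.null(v)) NULL else as.numeric(v)
}
a_int <- function(node, name) {
  v <- a_chr(node, name)
  if (is.null(v)) NULL else as.integer(v)
}
a_lgl <- function(node, name) {
  v <- a_chr(node, name)
  if (is.null(v)) NULL else is_flag_true(v)
}

reject_unknown <- function(node, known) {
  for (ch in xml2::xml_children(node)) {
    nm <- xml2::xml_name(ch)
    if (!nm %in% known) {
      stopf("simdex_parse_error", "unknown element <%s> at %s",
            nm, xml2::xml_path(ch))
    }
  }
}

read_extended <- function(node) {
  lapply(xml2::xml_find_all(node, "./extendedAttribute"), function(ch) {
    list(attribute = a_chr(ch, "attribute"), value = a_chr(ch, "value"),
         unit = a_chr(ch, "unit"), concept_id = a_chr(ch, "conceptId"))
  })
}

read_depends <- function(node) {
  refs <- vapply(xml2::xml_find_all(node, "./dependsOn"),
                 function(ch) a_chr(ch, "ref"), character(1))
  if (length(refs) == 0) character() else refs
}

#' Read an experiment back from its XML document
#'
#' @param doc an \code{xml_document} or path to an XML file.
#' @return an \code{experiment} that passes \code{validate_experiment};
#'   documents with elements outside the schema are rejected with the
#'   element path.
#' @export
from_xml <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "experiment") {
    stopf("simdex_parse_error", "root element must be <experiment>, not <%s>",
          xml2::xml_name(root))
  }
  reject_unknown(root, c("author", "citation", "grant", "extendedAttribute",
                         "molecularSystem", "parameterSets", "fileCollection",
                         "processGroup"))

  author_node <- xml2::xml_find_first(root, "./author")
  systems <- lapply(xml2::xml_find_all(root, "./molecularSystem"), read_system_node)
  systems <- named_by_id(systems)

  ps_nodes <- xml2::xml_find_all(root, "./parameterSets/*")
  psets <- named_by_id(lapply(ps_nodes, read_parameter_set_node))

  fcols <- lapply(xml2::xml_find_all(root, "./fileCollection"), function(fn) {
    reject_unknown(fn, "file")
    file_system_ref(
      type = a_chr(fn, "type") %||% "local", host = a_chr(fn, "host"),
      protocol = a_chr(fn, "protocol"),
      files = lapply(xml2::xml_find_all(fn, "./file"), function(f) {
        file_reference(uid = a_chr(f, "uid"), path = a_chr(f, "path"),
                       format = a_chr(f, "format"), role = a_chr(f, "role"),
                       size = a_num(f, "size"))
      }))
  })

  pgs <- lapply(xml2::xml_find_all(root, "./processGroup"), read_process_group_node)

  experiment(
    id = a_chr(root, "id"), name = a_chr(root, "name"),
    role = a_chr(root, "role"),
    author = if (!inherits(author_node, "xml_missing")) {
      author(a_chr(author_node, "name"),
             institution = a_chr(author_node, "institution"),
             contact = a_chr(author_node, "contact"))
    },
    citations = lapply(xml2::xml_find_all(root, "./citation"),
                       function(ch) citation_ref(xml2::xml_text(ch))),
    grants = lapply(xml2::xml_find_all(root, "./grant"), function(ch) {
      grant(a_chr(ch, "agency"), number = a_chr(ch, "number"))
    }),
    systems = systems, parameter_sets = psets,
    process_groups = pgs, file_collections = fcols,
    extended = read_extended(root))
}

named_by_id <- function(entities) {
  if (length(entities) == 0) return(list())
  stats::setNames(entities, vapply(entities, function(e) e$id, character(1)))
}

read_system_node <- function(sn) {
  reject_unknown(sn, c("molecule", "extendedAttribute"))
  mols <- lapply(xml2::xml_find_all(sn, "./molecule"), function(mn) {
    reject_unknown(mn, c("chain", "residueOccurrence", "atomOccurrence"))
    res_nodes <- xml2::xml_find_all(mn, "./residueOccurrence")
    atom_nodes <- xml2::xml_find_all(mn, "./atomOccurrence")
    chain_node <- xml2::xml_find_first(mn, "./chain")
    molecule(
      name = a_chr(mn, "name"), count = a_int(mn, "count") %||% 1L,
      kind = a_chr(mn, "kind") %||% "biomolecule",
      residues = if (length(res_nodes) > 0) {
        data.frame(name = vapply(res_nodes, a_chr, character(1), name = "name"),
                   count = vapply(res_nodes, a_int, integer(1), name = "count"),
                   stringsAsFactors = FALSE)
      },
      atoms = if (length(atom_nodes) > 0) {
        data.frame(element = vapply(atom_nodes, a_chr, character(1), name = "element"),
                   count = vapply(atom_nodes, a_int, integer(1), name = "count"),
                   stringsAsFactors = FALSE)
      },
      chain = if (!inherits(chain_node, "xml_missing")) {
        strsplit(xml2::xml_text(chain_node), "[[:space:]]+")[[1]]
      },
      normalized_chain = a_chr(mn, "normalizedChain"))
  })
  molecular_system(id = a_chr(sn, "id"), name = a_chr(sn, "name"),
                   molecules = mols,
                   topology_file_uid = a_chr(sn, "topologyFileUid"),
                   extended = read_extended(sn))
}

read_parameter_set_node <- function(n) {
  nm <- xml2::xml_name(n)
  if (nm == "mdParameterSet") {
    reject_unknown(n, c("forceField", "barostat", "thermostat", "constraint",
                        "restraint", "extendedAttribute"))
    coupling <- function(tag, ctor) {
      b <- xml2::xml_find_first(n, paste0("./", tag))
      if (inherits(b, "xml_missing")) return(NULL)
      ctor(a_chr(b, "implementation"), time_constant = a_num(b, "timeConstant"),
           chain_length = a_num(b, "chainLength"))
    }
    md_parameter_set(
      id = a_chr(n, "id"),
      force_fields = lapply(xml2::xml_find_all(n, "./forceField"),
                            function(f) force_field(a_chr(f, "name"))),
      barostat = coupling("barostat", barostat),
      thermostat = coupling("thermostat", thermostat),
      ensemble = a_chr(n, "ensemble"),
      constraints = lapply(xml2::xml_find_all(n, "./constraint"), function(c_) {
        constraint(a_chr(c_, "algorithm"), a_chr(c_, "target"))
      }),
      restraints = lapply(xml2::xml_find_all(n, "./restraint"), function(r) {
        restraint(a_chr(r, "property"), a_chr(r, "target"))
      }),
      electrostatics_model = a_chr(n, "electrostaticsModel"),
      collision_frequency = a_num(n, "collisionFrequency"),
      n_steps = a_num(n, "nSteps"), step_length = a_num(n, "stepLength"),
      extended = read_extended(n))
  } else if (nm == "qmParameterSet") {
    reject_unknown(n, "extendedAttribute")
    qm_parameter_set(
      id = a_chr(n, "id"), method = a_chr(n, "method"),
      basis_set = a_chr(n, "basisSet"), frozen_core = a_lgl(n, "frozenCore"),
      pseudopotentials = a_lgl(n, "pseudopotentials"),
      plane_wave_cutoff = a_num(n, "planeWaveCutoff"),
      convergence_flag = a_lgl(n, "convergenceFlag"),
      convergence_criteria = a_chr(n, "convergenceCriteria"),
      extended = read_extended(n))
  } else if (nm == "qmmmParameterSet") {
    reject_unknown(n, "extendedAttribute")
    qmmm_parameter_set(id = a_chr(n, "id"),
                       boundary_treatment = a_chr(n, "boundaryTreatment"),
                       extended = read_extended(n))
  } else {
    stopf("simdex_parse_error", "unknown element <%s> at %s", nm, xml2::xml_path(n))
  }
}

read_process_group_node <- function(pgn) {
  reject_unknown(pgn, c("dependsOn", "process", "extendedAttribute"))
  procs <- lapply(xml2::xml_find_all(pgn, "./process"), function(prn) {
    reject_unknown(prn, c("dependsOn", "task"))
    process(id = a_chr(prn, "id"),
            tasks = lapply(xml2::xml_find_all(prn, "./task"), read_task_node),
            depends_on = read_depends(prn))
  })
  process_group(id = a_chr(pgn, "id"), system_id = a_chr(pgn, "systemRef"),
                processes = procs, depends_on = read_depends(pgn))
}

read_task_node <- function(n) {
  reject_unknown(n, c("dependsOn", "parameterSetRef", "fileRef",
                      "simulatedConditions", "computingEnvironment",
                      "taskExecution", "software", "extendedAttribute"))
  get1 <- function(tag) {
    x <- xml2::xml_find_first(n, paste0("./", tag))
    if (inherits(x, "xml_missing")) NULL else x
  }
  cond_n <- get1("simulatedConditions")
  env_n <- get1("computingEnvironment")
  exe_n <- get1("taskExecution")
  sw_n <- get1("software")
  refs <- function(tag, attrib) {
    v <- vapply(xml2::xml_find_all(n, paste0("./", tag)),
                function(ch) a_chr(ch, attrib), character(1))
    if (length(v) == 0) character() else v
  }
  experiment_task(
    id = a_chr(n, "id"), kind = a_chr(n, "kind"),
    method_name = a_chr(n, "methodName"), description = a_chr(n, "description"),
    boundary_conditions = a_chr(n, "boundaryConditions"),
    solvent_type = a_chr(n, "solventType"), calculation = a_chr(n, "calculation"),
    conditions = if (!is.null(cond_n)) {
      simulated_conditions(
        reference_temperature = a_num(cond_n, "referenceTemperature"),
        reference_pressure = a_num(cond_n, "referencePressure"))
    },
    environment = if (!is.null(env_n)) {
      computing_environment(
        os = a_chr(env_n, "os"), cpu_architecture = a_chr(env_n, "cpuArchitecture"),
        gpu_architecture = a_chr(env_n, "gpuArchitecture"),
        machine_architecture = a_chr(env_n, "machineArchitecture"),
        machine_name = a_chr(env_n, "machineName"))
    },
    execution = if (!is.null(exe_n)) {
      task_execution(start = a_chr(exe_n, "start"), end = a_chr(exe_n, "end"),
                     elapsed = a_num(exe_n, "elapsed"),
                     termination_status = a_chr(exe_n, "terminationStatus"))
    },
    software = if (!is.null(sw_n)) {
      software(a_chr(sw_n, "name"), version = a_chr(sw_n, "version"),
               executable = a_chr(sw_n, "executable"))
    },
    parameter_set_ids = refs("parameterSetRef", "ref"),
    file_uids = refs("fileRef", "uid"),
    depends_on = read_depends(n),
    extended = read_extended(n))
}

# ---- HTML ----------------------------------------------------------------

#' Render an experiment document as an HTML tree view
#'
#' Transforms the XML document into a collapsible tree: one node per model
#' entity (every XML element becomes a \code{details}/\code{summary} block
#' with class \code{entity} and \code{data-kind} set to the entity name).
#'
#' @param doc an \code{xml_document} (from \code{\link{to_xml}}), an
#'   \code{experiment}, or a path to an XML file.
#' @return single HTML page as a character scalar; parses as well-formed
#'   markup.
#' @export
render_html <- function(doc) {
  if (inherits(doc, "simdex_experiment")) doc <- to_xml(doc)
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  root <- xml2::xml_root(doc)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  render_node <- function(node) {
    nm <- xml2::xml_name(node)
    ats <- xml2::xml_attrs(node)
    label <- if (length(ats) > 0) {
      paste0(nm, " [", paste(sprintf("%s=%s", names(ats), ats), collapse = ", "), "]")
    } else nm
    txt <- xml2::xml_text(node, trim = TRUE)
    kids <- xml2::xml_children(node)
    if (length(kids) == 0) {
      body <- if (nzchar(txt)) paste0(": ", esc(txt)) else ""
      sprintf("<div class=\"entity leaf\" data-kind=\"%s\">%s%s</div>",
              nm, esc(label), body)
    } else {
      sprintf("<details class=\"entity\" data-kind=\"%s\" open><summary>%s</summary>\n%s\n</details>",
              nm, esc(label),
              paste(vapply(kids, render_node, character(1)), collapse = "\n"))
    }
  }
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
    "<title>", esc(xml2::xml_attr(root, "name") %||% "experiment"), "</title>",
    "<style>.entity{margin-left:1em;font-family:monospace}summary{cursor:pointer}</style>",
    "</head><body>\n", render_node(root), "\n</body></html>\n")
}

# ---- relational DDL ------------------------------------------------------

#' Default relational descriptor of the experiment model
#'
#' Enumerates the model entities, their scalar fields and their links, as
#' input to \code{\link{generate_ddl}}.
#'
#' @return a list of entity descriptors (name, fields, links, extension).
#' @export
model_descriptor <- function() {
  ent <- function(name, fields, links = list(), extension = TRUE) {
    list(name = name, fields = fields, links = links, extension = extension)
  }
  list(
    ent("experiment", c(id = "TEXT", name = "TEXT", role = "TEXT")),
    ent("molecular_system", c(id = "TEXT", name = "TEXT", topology_file_uid = "TEXT"),
        list(experiment_id = "experiment")),
    ent("molecule", c(id = "TEXT", name = "TEXT", count = "INTEGER", kind = "TEXT",
                      specific_chain = "TEXT", normalized_chain = "TEXT"),
        list(system_id = "molecular_system")),
    ent("process_group", c(id = "TEXT"),
        list(experiment_id = "experiment", system_id = "molecular_system")),
    ent("process", c(id = "TEXT"), list(process_group_id = "process_group")),
    ent("experiment_task",
        c(id = "TEXT", kind = "TEXT", method_name = "TEXT",
          boundary_conditions = "TEXT", solvent_type = "TEXT",
          reference_temperature = "REAL", reference_pressure = "REAL",
          termination_status = "TEXT", software_name = "TEXT",
          software_version = "TEXT", executable = "TEXT"),
        list(process_id = "process")),
    ent("md_parameter_set",
        c(id = "TEXT", ensemble = "TEXT", electrostatics_model = "TEXT",
          collision_frequency = "REAL", n_steps = "REAL", step_length = "REAL")),
    ent("qm_parameter_set",
        c(id = "TEXT", method = "TEXT", basis_set = "TEXT",
          frozen_core = "INTEGER", pseudopotentials = "INTEGER",
          plane_wave_cutoff = "REAL")),
    ent("qmmm_parameter_set", c(id = "TEXT", boundary_treatment = "TEXT")),
    ent("task_parameter_set", c(id = "TEXT"),
        list(task_id = "experiment_task"), extension = FALSE),
    ent("file_system", c(id = "TEXT", type = "TEXT", host = "TEXT", protocol = "TEXT"),
        list(experiment_id = "experiment"), extension = FALSE),
    ent("file", c(uid = "TEXT", path = "TEXT", format = "TEXT", role = "TEXT",
                  size = "REAL"),
        list(file_system_id = "file_system"), extension = FALSE))
}

#' Generate relational DDL for the model and dictionaries
#'
#' Emits one table per entity and per dictionary, foreign-key constraints
#' for every link column, and a companion \code{<table>_extended_attribute}
#' table per extension-enabled entity (extended attributes require one
#' extra table per extended table to stay queryable without table-name
#' injection). Tables are ordered so referenced tables are created first,
#' and \code{DROP TABLE IF EXISTS} statements (reverse order) make the
#' script idempotent under drop-and-recreate.
#'
#' @param descriptor entity list from \code{\link{model_descriptor}}.
#' @param dictionaries optional \code{simdex_dictionary_set} to generate
#'   dictionary tables for.
#' @return character vector of SQL statements (portable baseline dialect).
#' @export
generate_ddl <- function(descriptor = model_descriptor(), dictionaries = NULL) {
  tables <- list()  # name -> list(cols = c(sql...), pk, fks)

  for (d in dictionaries %||% list()) {
    cols <- c("id TEXT PRIMARY KEY", "term TEXT NOT NULL", "description TEXT")
    fks <- character()
    for (i in seq_len(nrow(d$schema))) {
      col <- tolower(d$schema$COLUMN[i])
      kind <- d$schema$KIND[i]
      if (kind == "link") {
        target <- d$schema$TARGET[i]
        if (is.null(dictionaries[[target]])) {
          stopf("simdex_generation_error",
                "dictionary '%s' links to undeclared dictionary '%s'", d$name, target)
        }
        cols <- c(cols, sprintf("%s TEXT REFERENCES %s(id)", col, target))
      } else if (kind == "boolean") {
        cols <- c(cols, sprintf("%s INTEGER", col))
      } else {
        cols <- c(cols, sprintf("%s TEXT", col))
      }
    }
    tables[[d$name]] <- list(cols = cols,
                             deps = d$schema$TARGET[d$schema$KIND == "link"])
  }

  known_entities <- vapply(descriptor, function(e) e$name, character(1))
  for (e in descriptor) {
    pk <- names(e$fields)[1]
    cols <- sprintf("%s %s%s", names(e$fields), e$fields,
                    ifelse(names(e$fields) == pk, " PRIMARY KEY", ""))
    for (ln in names(e$links)) {
      target <- e$links[[ln]]
      if (!target %in% known_entities) {
        stopf("simdex_generation_error",
              "entity '%s' links to undeclared entity '%s'", e$name, target)
      }
      tcol <- if (target == "file") "uid" else "id"
      cols <- c(cols, sprintf("%s TEXT REFERENCES %s(%s)", ln, target, tcol))
    }
    tables[[e$name]] <- list(cols = cols, deps = unlist(e$links, use.names = FALSE))
    if (isTRUE(e$extension)) {
      ext <- sprintf("%s_extended_attribute", e$name)
      tables[[ext]] <- list(
        cols = c("id INTEGER PRIMARY KEY",
                 sprintf("owner_id TEXT NOT NULL REFERENCES %s(%s)", e$name, pk),
                 "attribute TEXT NOT NULL", "value TEXT", "unit TEXT",
                 "concept_id TEXT"),
        deps = e$name)
    }
  }

  edges <- do.call(rbind, lapply(names(tables), function(nm) {
    deps <- setdiff(tables[[nm]]$deps, "")
    deps <- deps[deps %in% names(tables)]
    if (length(deps) == 0) return(NULL)
    data.frame(from = deps, to = nm, stringsAsFactors = FALSE)
  }))
  order_ <- topological_order(edges %||% data.frame(from = character(), to = character()),
                              nodes = names(tables))
  if (is.null(order_)) {
    stopf("simdex_generation_error", "cyclic table references in descriptor")
  }

  drops <- sprintf("DROP TABLE IF EXISTS %s;", rev(order_))
  creates <- vapply(order_, function(nm) {
    sprintf("CREATE TABLE %s (\n  %s\n);", nm,
            paste(tables[[nm]]$cols, collapse = ",\n  "))
  }, character(1))
  c("PRAGMA foreign_keys=ON;", drops, creates)
}

sql_quote <- function(x) {
  if (is.null(x) || (length(x) == 1 && is.na(x))) return("NULL")
  if (is.logical(x)) return(if (x) "1" else "0")
  if (is.numeric(x)) return(canonical_value(x))
  sprintf("'%s'", gsub("'", "''", as.character(x)))
}

#' Generate INSERT statements loading a dictionary set
#'
#' @param dictionaries a \code{simdex_dictionary_set}.
#' @return character vector of SQL INSERT statements, ordered so link
#'   targets load before the dictionaries referencing them.
#' @export
generate_dictionary_inserts <- function(dictionaries) {
  deps <- do.call(rbind, lapply(dictionaries, function(d) {
    targets <- d$schema$TARGET[d$schema$KIND == "link"]
    if (length(targets) == 0) return(NULL)
    data.frame(from = targets, to = d$name, stringsAsFactors = FALSE)
  }))
  order_ <- topological_order(deps %||% data.frame(from = character(), to = character()),
                              nodes = names(dictionaries))
  stmts <- character()
  for (nm in order_) {
    d <- dictionaries[[nm]]
    if (is.null(d)) next
    extra_cols <- d$schema$COLUMN
    for (e in d$entries) {
      cols <- c("id", "term", "description", tolower(extra_cols))
      vals <- c(sql_quote(e$id), sql_quote(e$term), sql_quote(e$description))
      for (i in seq_along(extra_cols)) {
        col <- extra_cols[i]
        v <- if (d$schema$KIND[i] == "link") {
          if (col %in% names(e$links)) e$links[[col]]$id else NA
        } else if (col == "CITATION") {
          e$citation %||% NA
        } else {
          e$extras[[col]] %||% NA
        }
        vals <- c(vals, sql_quote(v))
      }
      stmts <- c(stmts, sprintf("INSERT INTO %s (%s) VALUES (%s);", nm,
                                paste(cols, collapse = ", "),
                                paste(vals, collapse = ", ")))
    }
  }
  stmts
}

#' Execute SQL statements on an embedded SQLite database
#'
#' Uses the RSQLite driver when installed, otherwise the system python's
#' sqlite3 module, so generated DDL can be smoke-tested without a database
#' server.
#'
#' @param statements character vector of SQL statements.
#' @param db path to the database file (created if absent).
#' @return \code{db}, invisibly; execution errors propagate.
#' @export
execute_sql <- function(statements, db = tempfile(fileext = ".sqlite")) {
  if (requireNamespace("RSQLite", quietly = TRUE)) {
    con <- DBI::dbConnect(RSQLite::SQLite(), db)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    for (s in statements) DBI::dbExecute(con, s)
  } else {
    sql_file <- tempfile(fileext = ".sql")
    writeLines(statements, sql_file)
    code <- sprintf(
      "import sqlite3,sys;con=sqlite3.connect(%s);con.executescript(open(%s).read());con.commit()",
      shQuote(db), shQuote(sql_file))
    out <- system2("python", c("-c", shQuote(code)), stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
      stopf("simdex_sql_error", "SQL execution failed: %s", paste(out, collapse = "\n"))
    }
  }
  invisible(db)
}

#' @rdname execute_sql
#' @param query a scalar-returning SQL query (e.g. a COUNT).
#' @export
query_scalar <- function(db, query) {
  if (requireNamespace("RSQLite", quietly = TRUE)) {
    con <- DBI::dbConnect(RSQLite::SQLite(), db)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    as.numeric(DBI::dbGetQuery(con, query)[[1]][1])
  } else {
    code <- sprintf(
      "import sqlite3;con=sqlite3.connect(%s);print(con.execute(%s).fetchone()[0])",
      shQuote(db), shQuote(query))
    out <- system2("python", c("-c", shQuote(code)), stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
      stopf("simdex_sql_error", "SQL query failed: %s", paste(out, collapse = "\n"))
    }
    as.numeric(out[length(out)])
  }
}
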