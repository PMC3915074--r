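#' Fixture file dialects
#'
#' simdex extracts metadata from three documented line-oriented dialects
#' rather than from real engine grammars (the model, not the file formats,
#' is the point; real AMBER/Gaussian fidelity is out of scope):
#'
#' \describe{
#'   \item{topology (\code{SIMDEX_TOP})}{first line \code{\%SIMDEX_TOP 1.0};
#'     a \code{\%SECTION HEADER} block of \code{KEY = value} lines; then one
#'     \code{\%SECTION MOLECULE <name>} block per molecule with
#'     \code{KEY = value} lines (\code{KIND}, \code{COUNT},
#'     \code{N_RESIDUES}, \code{N_ATOMS}, optional \code{CHAIN} of
#'     space-separated residue symbols) plus \code{RESIDUE <name> <count>}
#'     and \code{ATOM <element> <count>} occurrence lines. Declared counts
#'     must equal the summed occurrence lines.}
#'   \item{MD output (\code{SIMDEX_MDOUT})}{first line
#'     \code{\%SIMDEX_MDOUT 1.0}; \code{KEY = value} lines
#'     (\code{FORCE_FIELD} may repeat); a final \code{FOOTER: <status>}
#'     line. A missing footer means the run ended without writing its
#'     summary and is recorded as termination status \code{"incomplete"}.}
#'   \item{QM output (\code{SIMDEX_QMOUT})}{same key/value + footer shape
#'     with QM keys (\code{METHOD}, \code{BASIS_SET}, ...).}
#' }
#'
#' Parsers never invent values: a key absent from the file is absent from
#' the record (\code{NULL}), never defaulted.
#'
#' @name fixture-dialects
NULL

TOP_MAGIC <- "%SIMDEX_TOP"
MDOUT_MAGIC <- "%SIMDEX_MDOUT"
QMOUT_MAGIC <- "%SIMDEX_QMOUT"

#' Detect the format of a file
#'
#' Returns a term of the packaged \code{file_format} dictionary
#' (\code{"PDB"}, \code{"SIMDEX_TOP"}, \code{"SIMDEX_MDOUT"},
#' \code{"SIMDEX_QMOUT"}, \code{"CSV"}, \code{"XML"}) or \code{"unknown"}.
#'
#' @param path file path.
#' @return format term string.
#' @export
detect_format <- function(path) {
  if (!file.exists(path)) stopf("simdex_io_error", "cannot read '%s'", path)
  lines <- tryCatch(readLines(path, n = 10L, warn = FALSE),
                    error = function(e) stopf("simdex_io_error", "cannot read '%s'", path))
  if (length(lines) == 0) return("unknown")
  first <- lines[1]
  if (startsWith(first, TOP_MAGIC)) return("SIMDEX_TOP")
  if (startsWith(first, MDOUT_MAGIC)) return("SIMDEX_MDOUT")
  if (startsWith(first, QMOUT_MAGIC)) return("SIMDEX_QMOUT")
  if (any(grepl("^(ATOM  |HETATM|HEADER|REMARK)", lines))) return("PDB")
  if (grepl("^<\\?xml", first)) return("XML")
  if (grepl(",", first, fixed = TRUE) && tolower(tools::file_ext(path)) == "csv") return("CSV")
  "unknown"
}

read_dialect_lines <- function(path, magic) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], magic)) {
    stopf("simdex_parse_error", "line 1: '%s' is not a %s file", path, magic)
  }
  lines
}

# parse "KEY = value" lines into a list of character vectors (repeats kept)
parse_kv_block <- function(lines, line_offset = 0L) {
  kv <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    m <- regmatches(ln, regexec("^\\s*([A-Z0-9_]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 0) {
      stopf("simdex_parse_error", "line %d: malformed key/value line: '%s'",
            i + line_offset, ln)
    }
    kv[[m[2]]] <- c(kv[[m[2]]], m[3])
  }
  kv
}

kv1 <- function(kv, key) if (is.null(kv[[key]])) NULL else kv[[key]][1]
kv_num <- function(kv, key) {
  v <- kv1(kv, key)
  if (is.null(v)) NULL else as.numeric(v)
}

#' Parse a fixture MD output file into a task record
#'
#' @param path path to a \code{SIMDEX_MDOUT} file.
#' @return a \code{simdex_md_task_record} with the task kind and stage, the
#'   MD parameter-set fragment, simulated conditions, software, computing
#'   environment and execution records, populated only with keys present in
#'   the file. A missing \code{FOOTER:} line yields termination status
#'   \code{"incomplete"}.
#' @export
parse_md_output <- function(path) {
  lines <- read_dialect_lines(path, MDOUT_MAGIC)
  body <- lines[-1]
  footer <- grep("^FOOTER:", body)
  status <- "incomplete"
  if (length(footer) > 0) {
    status <- trimws(sub("^FOOTER:", "", body[footer[1]]))
    body <- body[-footer]
  }
  kv <- parse_kv_block(body, line_offset = 1L)
  kind <- kv1(kv, "TASK_KIND")
  if (is.null(kind) || !kind %in% c("md", "minimization")) {
    stopf("simdex_parse_error", "line 1: '%s' must declare TASK_KIND md or minimization", path)
  }

  ffs <- lapply(kv[["FORCE_FIELD"]] %||% character(), force_field)
  bar <- if (!is.null(kv1(kv, "BAROSTAT"))) {
    barostat(kv1(kv, "BAROSTAT"), time_constant = kv_num(kv, "BAROSTAT_TIME_CONSTANT"))
  }
  thr <- if (!is.null(kv1(kv, "THERMOSTAT"))) {
    thermostat(kv1(kv, "THERMOSTAT"), time_constant = kv_num(kv, "THERMOSTAT_TIME_CONSTANT"))
  }
  cons <- if (!is.null(kv1(kv, "CONSTRAINT_ALGORITHM"))) {
    list(constraint(kv1(kv, "CONSTRAINT_ALGORITHM"),
                    kv1(kv, "CONSTRAINT_TARGET") %||% "all bonds"))
  } else list()
  rest <- if (!is.null(kv1(kv, "RESTRAINT_PROPERTY"))) {
    list(restraint(kv1(kv, "RESTRAINT_PROPERTY"),
                   kv1(kv, "RESTRAINT_TARGET") %||% "unspecified"))
  } else list()

  params <- md_parameter_set(
    id = content_id(basename(path), "mdparams", prefix = "ps"),
    force_fields = ffs, barostat = bar, thermostat = thr,
    ensemble = kv1(kv, "ENSEMBLE"), constraints = cons, restraints = rest,
    electrostatics_model = kv1(kv, "ELECTROSTATICS"),
    collision_frequency = kv_num(kv, "COLLISION_FREQUENCY"),
    n_steps = kv_num(kv, "N_STEPS"), step_length = kv_num(kv, "STEP_LENGTH"))

  structure(list(
    task_kind = kind,
    stage = kv1(kv, "STAGE"),
    system_name = kv1(kv, "SYSTEM_NAME"),
    copy = kv1(kv, "COPY"),
    replica = kv1(kv, "REPLICA"),
    method_name = kv1(kv, "METHOD_NAME"),
    solvent_type = kv1(kv, "SOLVENT_TYPE"),
    boundary_conditions = kv1(kv, "BOUNDARY_CONDITIONS"),
    parameters = params,
    conditions = simulated_conditions(
      reference_temperature = kv_num(kv, "REFERENCE_TEMPERATURE"),
      reference_pressure = kv_num(kv, "REFERENCE_PRESSURE")),
    software = if (!is.null(kv1(kv, "SOFTWARE_NAME"))) {
      software(kv1(kv, "SOFTWARE_NAME"), version = kv1(kv, "SOFTWARE_VERSION"),
               executable = kv1(kv, "EXECUTABLE"))
    },
    environment = computing_environment(
      os = kv1(kv, "OS"), cpu_architecture = kv1(kv, "CPU_ARCHITECTURE"),
      gpu_architecture = kv1(kv, "GPU_ARCHITECTURE"),
      machine_architecture = kv1(kv, "MACHINE_ARCHITECTURE"),
      machine_name = kv1(kv, "MACHINE_NAME")),
    execution = task_execution(
      start = kv1(kv, "START_TIME"), end = kv1(kv, "END_TIME"),
      elapsed = kv_num(kv, "ELAPSED_SECONDS"), termination_status = status),
    source_file = file_reference(uid = basename(path), path = path,
                                 format = "SIMDEX_MDOUT", role = "output")),
    class = "simdex_md_task_record")
}

#' Parse a fixture QM output file into a task record
#'
#' Method and basis-set names are captured verbatim; the executable string
#' is decomposed into build information via
#' \code{\link{parse_executable_name}}.
#'
#' @param path path to a \code{SIMDEX_QMOUT} file.
#' @return a \code{simdex_qm_task_record}.
#' @export
parse_qm_output <- function(path) {
  lines <- read_dialect_lines(path, QMOUT_MAGIC)
  body <- lines[-1]
  footer <- grep("^FOOTER:", body)
  status <- "incomplete"
  if (length(footer) > 0) {
    status <- trimws(sub("^FOOTER:", "", body[footer[1]]))
    body <- body[-footer]
  }
  kv <- parse_kv_block(body, line_offset = 1L)
  if (is.null(kv1(kv, "METHOD"))) {
    stopf("simdex_parse_error", "line 1: QM output '%s' declares no METHOD", path)
  }
  params <- qm_parameter_set(
    id = content_id(basename(path), "qmparams", prefix = "ps"),
    method = kv1(kv, "METHOD"), basis_set = kv1(kv, "BASIS_SET"),
    frozen_core = if (!is.null(kv1(kv, "FROZEN_CORE"))) is_flag_true(kv1(kv, "FROZEN_CORE")),
    pseudopotentials = if (!is.null(kv1(kv, "PSEUDOPOTENTIALS"))) is_flag_true(kv1(kv, "PSEUDOPOTENTIALS")),
    plane_wave_cutoff = kv_num(kv, "PLANE_WAVE_CUTOFF"),
    convergence_flag = if (!is.null(kv1(kv, "CONVERGED"))) is_flag_true(kv1(kv, "CONVERGED")),
    convergence_criteria = kv1(kv, "CONVERGENCE_CRITERIA"))
  exe <- kv1(kv, "EXECUTABLE")
  structure(list(
    task_kind = "qm",
    system_name = kv1(kv, "SYSTEM_NAME"),
    method_name = kv1(kv, "METHOD"),
    calculation = kv1(kv, "CALCULATION"),
    solvent_type = kv1(kv, "SOLVENT_TYPE"),
    boundary_conditions = kv1(kv, "BOUNDARY_CONDITIONS"),
    parameters = params,
    software = if (!is.null(kv1(kv, "SOFTWARE_NAME"))) {
      software(kv1(kv, "SOFTWARE_NAME"), version = kv1(kv, "SOFTWARE_VERSION"),
               executable = exe)
    },
    build_info = if (!is.null(exe)) parse_executable_name(exe),
    environment = computing_environment(
      os = kv1(kv, "OS"), cpu_architecture = kv1(kv, "CPU_ARCHITECTURE"),
      gpu_architecture = kv1(kv, "GPU_ARCHITECTURE"),
      machine_architecture = kv1(kv, "MACHINE_ARCHITECTURE"),
      machine_name = kv1(kv, "MACHINE_NAME")),
    execution = task_execution(
      start = kv1(kv, "START_TIME"), end = kv1(kv, "END_TIME"),
      elapsed = kv_num(kv, "ELAPSED_SECONDS"), termination_status = status),
    source_file = file_reference(uid = basename(path), path = path,
                                 format = "SIMDEX_QMOUT", role = "output")),
    class = "simdex_qm_task_record")
}

#' Parse a fixture topology file into a molecular system
#'
#' Composition is stored as occurrence counts (a water molecule is one H
#' entry with count 2 and one O entry with count 1), with the ordered
#' specific residue chain kept for biomolecules. Declared residue/atom
#' totals must match the listed occurrences.
#'
#' @param path path to a \code{SIMDEX_TOP} file.
#' @param dictionaries optional dictionary set; when given, biomolecule
#'   chains are normalized to one-letter codes via
#'   \code{\link{normalize_sequence}}.
#' @return a \code{molecular_system}.
#' @export
parse_topology <- function(path, dictionaries = NULL) {
  lines <- read_dialect_lines(path, TOP_MAGIC)
  sec_starts <- grep("^%SECTION ", lines)
  if (length(sec_starts) == 0) {
    stopf("simdex_parse_error", "line 1: topology '%s' has no sections", path)
  }
  header <- list()
  mols <- list()
  for (si in seq_along(sec_starts)) {
    from <- sec_starts[si]
    to <- if (si < length(sec_starts)) sec_starts[si + 1] - 1L else length(lines)
    title <- trimws(sub("^%SECTION ", "", lines[from]))
    body <- lines[(from + 1L):to]
    if (identical(title, "HEADER")) {
      header <- parse_kv_block(body, line_offset = from)
    } else if (startsWith(title, "MOLECULE ")) {
      mols[[length(mols) + 1L]] <-
        parse_molecule_block(sub("^MOLECULE ", "", title), body, from, path,
                             dictionaries)
    } else {
      stopf("simdex_parse_error", "line %d: unknown section '%s'", from, title)
    }
  }
  sys_name <- kv1(header, "SYSTEM_NAME")
  molecular_system(
    id = content_id(sys_name %||% basename(path),
                    vapply(mols, function(m) m$name, character(1)),
                    prefix = "sys"),
    name = sys_name, molecules = mols,
    topology_file_uid = basename(path))
}

parse_molecule_block <- function(name, body, offset, path, dictionaries) {
  kv_lines <- character(); res <- list(); atm <- list()
  for (i in seq_along(body)) {
    ln <- trimws(body[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^RESIDUE ", ln)) {
      parts <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(parts) != 3 || is.na(suppressWarnings(as.integer(parts[3])))) {
        stopf("simdex_parse_error", "line %d: malformed RESIDUE line", offset + i)
      }
      res[[length(res) + 1L]] <- data.frame(name = parts[2],
                                            count = as.integer(parts[3]),
                                            stringsAsFactors = FALSE)
    } else if (grepl("^ATOM ", ln)) {
      parts <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(parts) != 3 || is.na(suppressWarnings(as.integer(parts[3])))) {
        stopf("simdex_parse_error", "line %d: malformed ATOM line", offset + i)
      }
      atm[[length(atm) + 1L]] <- data.frame(element = parts[2],
                                            count = as.integer(parts[3]),
                                            stringsAsFactors = FALSE)
    } else {
      kv_lines <- c(kv_lines, body[i])
    }
  }
  kv <- parse_kv_block(kv_lines, line_offset = offset)
  residues <- if (length(res)) do.call(rbind, res)
  atoms <- if (length(atm)) do.call(rbind, atm)
  n_res <- kv_num(kv, "N_RESIDUES"); n_atm <- kv_num(kv, "N_ATOMS")
  if (!is.null(n_res) && !is.null(residues) && sum(residues$count) != n_res) {
    stopf("simdex_parse_error",
          "line %d: molecule '%s' declares %d residues but lists %d",
          offset, name, n_res, sum(residues$count))
  }
  if (!is.null(n_atm) && !is.null(atoms) && sum(atoms$count) != n_atm) {
    stopf("simdex_parse_error",
          "line %d: molecule '%s' declares %d atoms but lists %d",
          offset, name, n_atm, sum(atoms$count))
  }
  chain <- if (!is.null(kv1(kv, "CHAIN"))) strsplit(kv1(kv, "CHAIN"), "[[:space:]]+")[[1]]
  if (!is.null(chain) && !is.null(n_res) && length(chain) != n_res) {
    stopf("simdex_parse_error",
          "line %d: molecule '%s' chain length %d does not match N_RESIDUES %d",
          offset, name, length(chain), n_res)
  }
  molecule(
    name = name,
    count = as.integer(kv_num(kv, "COUNT") %||% 1),
    kind = kv1(kv, "KIND") %||% "biomolecule",
    residues = residues, atoms = atoms, chain = chain,
    normalized_chain = if (!is.null(chain) && !is.null(dictionaries)) {
      normalize_sequence(chain, dictionaries)
    })
}

#' Decompose an executable name into build information
#'
#' Gaussian-style executable strings of the form
#' \code{<ARCH>-<PRODUCT>Rev<REVISION>} (e.g. \code{"EM64L-G09RevC.01"})
#' yield the target architecture, product and revision; known MD engine
#' executables (\code{SANDER}, \code{PMEMD}) yield the product only. Any
#' other name degrades gracefully to the raw string.
#'
#' @param name executable name, non-empty.
#' @return a \code{simdex_build_info} with fields \code{raw} (always set),
#'   \code{product}, \code{revision}, \code{target_architecture}.
#' @export
parse_executable_name <- function(name) {
  assert_string(name, "name")
  out <- list(raw = name, product = NULL, revision = NULL,
              target_architecture = NULL)
  m <- regmatches(name, regexec("^([A-Za-z0-9]+)-(.+)Rev(.+)$", name))[[1]]
  if (length(m) == 4) {
    out$target_architecture <- m[2]
    out$product <- m[3]
    out$revision <- m[4]
  } else if (toupper(name) %in% c("SANDER", "PMEMD")) {
    out$product <- toupper(name)
  }
  structure(out, class = "simdex_build_info")
}

#' Normalize a specific residue chain to one-letter codes
#'
#' Each residue symbol is looked up in the \code{residue} dictionary and
#' replaced by its one-letter code (amino acids or nucleobases); symbols
#' with no mapping -- non-standard residues, ligands, solvent -- become the
#' placeholder \code{"X"}. The specific chain is kept separately on the
#' molecule; output length always equals input length.
#'
#' @param specific_residues ordered character vector of residue symbols as
#'   found in the topology (e.g. \code{c("ALA","GLY","SER")}).
#' @param dictionaries a dictionary set containing the \code{residue}
#'   dictionary.
#' @return single normalized string (e.g. \code{"AGS"}).
#' @export
normalize_sequence <- function(specific_residues, dictionaries) {
  if (length(specific_residues) == 0) {
    stopf("simdex_usage_error", "specific_residues must be non-empty")
  }
  rd <- dictionaries[["residue"]]
  codes <- vapply(specific_residues, function(r) {
    e <- if (!is.null(rd)) lookup_term(rd, r)
    code <- if (!is.null(e)) e$extras[["ONE_LETTER_CODE"]] else NULL
    if (is.null(code) || !nzchar(code)) "X" else code
  }, character(1))
  paste(codes, collapse = "")
}
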