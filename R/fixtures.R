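#' Deterministic synthetic study fixtures
#'
#' Generators write complete fixture study directories -- topology, per
#' stage input/output files, numbered trajectory files and a ground-truth
#' JSON manifest -- in the documented dialects, so parsing, assembly,
#' indexing and serialization are testable end to end without any real
#' simulation data. All randomness flows from the single seed; timestamps
#' are config-supplied, never wall clock, so regeneration at equal
#' (seed, config) is byte-identical. Trajectory names always include a
#' "2"/"10" pair that a naive string sort mis-orders. Payload files contain
#' placeholders only: no physics is simulated.
#'
#' @name synthetic-fixtures
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# nucleotide / amino-acid heavy+H atom compositions used to derive
# consistent occurrence counts for fixture chains (approximate residue
# compositions; fixtures need internal consistency, not chemistry)
RESIDUE_ATOMS <- list(
  A = c(C = 10, H = 12, N = 5, O = 6, P = 1),
  U = c(C = 9, H = 11, N = 2, O = 8, P = 1),
  G = c(C = 10, H = 12, N = 5, O = 7, P = 1),
  C = c(C = 9, H = 12, N = 3, O = 7, P = 1),
  ALA = c(C = 3, H = 5, N = 1, O = 1),
  GLY = c(C = 2, H = 3, N = 1, O = 1),
  SER = c(C = 3, H = 5, N = 1, O = 2),
  VAL = c(C = 5, H = 9, N = 1, O = 1),
  LEU = c(C = 6, H = 11, N = 1, O = 1))

chain_atoms <- function(chain) {
  tot <- c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  for (r in chain) {
    comp <- RESIDUE_ATOMS[[r]]
    for (el in names(comp)) tot[el] <- tot[el] + comp[el]
  }
  tot[tot > 0]
}

fmt_ts <- function(base, offset_s) {
  format(as.POSIXct(base, tz = "UTC") + offset_s, "%Y-%m-%dT%H:%M:%SZ")
}

write_topology_file <- function(path, system_name, mols) {
  lines <- c("%SIMDEX_TOP 1.0", "%SECTION HEADER",
             sprintf("SYSTEM_NAME = %s", system_name))
  for (m in mols) {
    lines <- c(lines, sprintf("%%SECTION MOLECULE %s", m$name),
               sprintf("KIND = %s", m$kind),
               sprintf("COUNT = %d", m$count),
               sprintf("N_RESIDUES = %d", sum(m$residues$count)),
               sprintf("N_ATOMS = %d", sum(m$atoms$count)))
    if (!is.null(m$chain)) {
      lines <- c(lines, sprintf("CHAIN = %s", paste(m$chain, collapse = " ")))
    }
    lines <- c(lines,
               sprintf("RESIDUE %s %d", m$residues$name, m$residues$count),
               sprintf("ATOM %s %d", m$atoms$element, m$atoms$count))
  }
  writeLines(lines, path)
}

mol_spec <- function(name, kind, count, chain = NULL, residues = NULL) {
  if (!is.null(chain)) {
    rt <- table(chain)
    residues <- data.frame(name = names(rt), count = as.integer(rt),
                           stringsAsFactors = FALSE)
    at <- chain_atoms(chain)
    atoms <- data.frame(element = names(at), count = as.integer(at),
                        stringsAsFactors = FALSE)
  } else if (identical(name, "WAT")) {
    residues <- data.frame(name = "WAT", count = 1L, stringsAsFactors = FALSE)
    atoms <- data.frame(element = c("H", "O"), count = c(2L, 1L),
                        stringsAsFactors = FALSE)
  } else {
    atoms <- data.frame(element = c("C", "H", "O"), count = c(6L, 8L, 2L),
                        stringsAsFactors = FALSE)
    residues <- data.frame(name = name, count = 1L, stringsAsFactors = FALSE)
  }
  list(name = name, kind = kind, count = count, chain = chain,
       residues = residues, atoms = atoms)
}

write_kv_file <- function(path, magic, kv, footer = "normal") {
  lines <- magic
  for (nm in names(kv)) {
    for (v in kv[[nm]]) lines <- c(lines, sprintf("%s = %s", nm, v))
  }
  if (!is.null(footer)) lines <- c(lines, sprintf("FOOTER: %s", footer))
  writeLines(lines, path)
}

#' Extract the comparable scalar fields of a parsed task record
#'
#' Used to compare parsed records against fixture manifests field by
#' field; covers every key the fixture dialects can carry.
#'
#' @param rec a \code{simdex_md_task_record} or \code{simdex_qm_task_record}.
#' @return named list of scalar fields (and the force-field name vector).
#' @export
record_fields <- function(rec) {
  ps <- rec$parameters
  base <- list(
    task_kind = rec$task_kind, stage = rec$stage, copy = rec$copy,
    replica = rec$replica, system_name = rec$system_name,
    method_name = rec$method_name, solvent_type = rec$solvent_type,
    boundary_conditions = rec$boundary_conditions,
    calculation = rec$calculation,
    reference_temperature = rec$conditions$reference_temperature,
    reference_pressure = rec$conditions$reference_pressure,
    software_name = if (!is.null(rec$software)) rec$software$name,
    software_version = if (!is.null(rec$software)) rec$software$version,
    executable = if (!is.null(rec$software)) rec$software$executable,
    os = rec$environment$os,
    cpu_architecture = rec$environment$cpu_architecture,
    machine_name = rec$environment$machine_name,
    start = rec$execution$start, end = rec$execution$end,
    elapsed = rec$execution$elapsed,
    termination_status = rec$execution$termination_status)
  extra <- if (inherits(rec, "simdex_md_task_record")) {
    list(force_fields = vapply(ps$force_fields, function(f) f$name, character(1)),
         thermostat = if (!is.null(ps$thermostat)) ps$thermostat$implementation,
         barostat = if (!is.null(ps$barostat)) ps$barostat$implementation,
         ensemble = ps$ensemble,
         constraint_algorithm = if (length(ps$constraints)) ps$constraints[[1]]$algorithm,
         electrostatics_model = ps$electrostatics_model,
         collision_frequency = ps$collision_frequency,
         n_steps = ps$n_steps, step_length = ps$step_length)
  } else {
    list(method = ps$method, basis_set = ps$basis_set,
         frozen_core = ps$frozen_core,
         revision = if (!is.null(rec$build_info)) rec$build_info$revision,
         target_architecture = if (!is.null(rec$build_info)) rec$build_info$target_architecture,
         product = if (!is.null(rec$build_info)) rec$build_info$product)
  }
  out <- c(base, extra)
  out[!vapply(out, is.null, logical(1))]
}

#' Generate a fixture MD study directory
#'
#' Emulates an MD study directory: one topology, one input and one output
#' file per stage and copy, and a numbered production trajectory series.
#' Multiple copies of the system (separate process groups) live in
#' \code{runN/} subdirectories.
#'
#' @param dir target directory (created; must not already contain a study).
#' @param seed integer seed driving every random draw.
#' @param stages subset of \code{c("minimization", "heating", "production")},
#'   at least one.
#' @param n_copies number of simulated copies of the system.
#' @param n_traj number of production trajectory files (>= 10 keeps the
#'   natural-ordering "2"/"10" collision in the tree).
#' @param explicit_water include an explicit water solvent molecule block.
#' @param base_time ISO timestamp seeding the (deterministic) execution
#'   timestamps.
#' @return the manifest, invisibly (also written to \code{manifest.json}).
#' @export
generate_md_study <- function(dir, seed = 1L,
                              stages = c("minimization", "heating", "production"),
                              n_copies = 1L, n_traj = 10L,
                              explicit_water = TRUE,
                              base_time = "2013-06-01T00:00:00Z") {
  if (length(stages) == 0) stopf("simdex_usage_error", "at least one stage is required")
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    n_res <- sample(6:12, 1)
    chain <- sample(c("A", "U", "G", "C"), n_res, replace = TRUE)
    system_name <- sprintf("RNA %dmer%s", n_res,
                           if (explicit_water) " in explicit water" else "")
    mols <- list(mol_spec("RNA1", "biomolecule", 1L, chain = chain))
    if (explicit_water) {
      mols <- c(mols, list(mol_spec("WAT", "solvent", sample(500:2000, 1))))
    }
    write_topology_file(file.path(dir, "system.top"), system_name, mols)

    thermo <- sample(c("Langevin", "Berendsen", "Nose-Hoover"), 1)
    ff <- c("AMBER FF99bsc0", if (explicit_water) "TIP3P")
    exe <- sample(c("SANDER", "PMEMD"), 1)
    machine <- sample(c("kraken.nics.utk.edu", "stampede.tacc.utexas.edu"), 1)
    collision <- if (thermo == "Langevin") round(stats::runif(1, 1, 5), 1)

    manifest_tasks <- list()
    for (copy in seq_len(n_copies)) {
      sub <- if (n_copies > 1) sprintf("run%d", copy) else "."
      if (sub != ".") dir.create(file.path(dir, sub), showWarnings = FALSE)
      rel <- function(f) if (sub == ".") f else file.path(sub, f)
      t0 <- 0
      for (stage in stages) {
        is_min <- stage == "minimization"
        n_steps <- if (is_min) sample(500:2000, 1) else sample(10:50, 1) * 10000
        elapsed <- round(stats::runif(1, 60, 4 * 3600))
        kv <- list(
          TASK_KIND = if (is_min) "minimization" else "md",
          STAGE = stage,
          METHOD_NAME = if (is_min) "Energy minimization" else "Molecular dynamics",
          SYSTEM_NAME = system_name)
        if (n_copies > 1) kv$COPY <- as.character(copy)
        kv <- c(kv, list(
          SOLVENT_TYPE = if (explicit_water) "explicit" else "implicit",
          BOUNDARY_CONDITIONS = if (explicit_water) "periodic" else "non-periodic",
          FORCE_FIELD = ff,
          N_STEPS = n_steps,
          SOFTWARE_NAME = "AMBER", SOFTWARE_VERSION = "12", EXECUTABLE = exe,
          OS = "Linux", CPU_ARCHITECTURE = "x86_64", MACHINE_NAME = machine,
          START_TIME = fmt_ts(base_time, t0),
          END_TIME = fmt_ts(base_time, t0 + elapsed),
          ELAPSED_SECONDS = elapsed))
        if (!is_min) {
          kv$STEP_LENGTH <- 0.002
          kv$THERMOSTAT <- thermo
          kv$REFERENCE_TEMPERATURE <- 300
          kv$ELECTROSTATICS <- if (explicit_water) "PME" else "Cutoff"
          kv$CONSTRAINT_ALGORITHM <- "SHAKE"
          kv$CONSTRAINT_TARGET <- "bonds involving hydrogen"
          if (!is.null(collision)) kv$COLLISION_FREQUENCY <- collision
          if (stage == "production" && explicit_water) {
            kv$ENSEMBLE <- "isothermal-isobaric"
            kv$BAROSTAT <- "Berendsen"
            kv$REFERENCE_PRESSURE <- 1
          } else {
            kv$ENSEMBLE <- "canonical"
          }
        }
        writeLines(c(sprintf("# input for %s", stage),
                     sprintf("STAGE = %s", stage)),
                   file.path(dir, sub, sprintf("%s.in", stage)))
        write_kv_file(file.path(dir, sub, sprintf("%s.out", stage)),
                      "%SIMDEX_MDOUT 1.0", kv)
        manifest_tasks[[rel(sprintf("%s.out", stage))]] <-
          record_fields(parse_md_output(file.path(dir, sub, sprintf("%s.out", stage))))
        t0 <- t0 + elapsed + 60
      }
      if ("production" %in% stages) {
        for (k in seq_len(n_traj)) {
          writeLines(c(sprintf("placeholder trajectory segment %d", k),
                       sprintf("frames: %d", 500)),
                     file.path(dir, sub, sprintf("production.%d.traj", k)))
        }
      }
    }

    traj_rel <- character()
    if ("production" %in% stages) {
      for (copy in seq_len(n_copies)) {
        sub <- if (n_copies > 1) sprintf("run%d", copy) else ""
        base <- sprintf("production.%d.traj", seq_len(n_traj))
        traj_rel <- c(traj_rel, if (nzchar(sub)) file.path(sub, base) else base)
      }
    }

    manifest <- list(
      kind = "md", seed = seed,
      config = list(stages = stages, n_copies = n_copies, n_traj = n_traj,
                    explicit_water = explicit_water, base_time = base_time),
      expected = list(
        system = list(
          name = system_name,
          molecules = lapply(mols, function(m) {
            list(name = m$name, kind = m$kind, count = m$count,
                 chain = m$chain,
                 residues = m$residues, atoms = m$atoms)
          })),
        tasks = manifest_tasks,
        n_process_groups = n_copies,
        n_processes_per_group = length(stages),
        trajectory_order = traj_rel))
    write_manifest(manifest, dir)
  })
}

#' Generate a fixture replica-exchange (REMD) study
#'
#' @param dir target directory.
#' @param seed integer seed.
#' @param n_replicas number of replicas (>= 1); each replica is one MD task
#'   record at its own rung of the temperature ladder.
#' @param base_time ISO timestamp base.
#' @return manifest, invisibly; it records the two legal process groupings
#'   (one process holding all replicas, or one process per replica).
#' @export
generate_remd_study <- function(dir, seed = 1L, n_replicas = 4L,
                                base_time = "2013-06-01T00:00:00Z") {
  if (!is.numeric(n_replicas) || n_replicas < 1) {
    stopf("simdex_usage_error", "n_replicas must be >= 1")
  }
  n_replicas <- as.integer(n_replicas)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed + 1000L, {
    n_res <- sample(4:8, 1)
    chain <- sample(c("ALA", "GLY", "SER", "VAL", "LEU"), n_res, replace = TRUE)
    system_name <- sprintf("peptide %dmer", n_res)
    mols <- list(mol_spec("PEP1", "biomolecule", 1L, chain = chain))
    write_topology_file(file.path(dir, "system.top"), system_name, mols)
    base_temp <- sample(c(280, 290, 300), 1)
    temps <- round(base_temp * 1.04^(seq_len(n_replicas) - 1), 1)
    manifest_tasks <- list()
    for (k in seq_len(n_replicas)) {
      elapsed <- round(stats::runif(1, 600, 7200))
      kv <- list(
        TASK_KIND = "md", STAGE = "remd", REPLICA = k,
        METHOD_NAME = "Molecular dynamics", SYSTEM_NAME = system_name,
        SOLVENT_TYPE = "implicit", BOUNDARY_CONDITIONS = "non-periodic",
        FORCE_FIELD = "AMBER FF99SB",
        THERMOSTAT = "Langevin", COLLISION_FREQUENCY = 2,
        ENSEMBLE = "canonical",
        N_STEPS = 200000, STEP_LENGTH = 0.002,
        REFERENCE_TEMPERATURE = temps[k],
        SOFTWARE_NAME = "AMBER", SOFTWARE_VERSION = "12", EXECUTABLE = "SANDER",
        OS = "Linux", CPU_ARCHITECTURE = "x86_64",
        START_TIME = fmt_ts(base_time, 0),
        END_TIME = fmt_ts(base_time, elapsed),
        ELAPSED_SECONDS = elapsed)
      out <- sprintf("remd.rep%d.out", k)
      writeLines(c("# REMD replica input", sprintf("REPLICA = %d", k)),
                 file.path(dir, sprintf("remd.rep%d.in", k)))
      write_kv_file(file.path(dir, out), "%SIMDEX_MDOUT 1.0", kv)
      manifest_tasks[[out]] <- record_fields(parse_md_output(file.path(dir, out)))
    }
    for (k in seq_len(10)) {
      writeLines(sprintf("placeholder exchange log segment %d", k),
                 file.path(dir, sprintf("exchange.%d.log", k)))
    }
    manifest <- list(
      kind = "remd", seed = seed,
      config = list(n_replicas = n_replicas, base_time = base_time),
      expected = list(
        system = list(name = system_name,
                      molecules = list(list(name = "PEP1", kind = "biomolecule",
                                            count = 1L, chain = chain,
                                            residues = mols[[1]]$residues,
                                            atoms = mols[[1]]$atoms))),
        tasks = manifest_tasks,
        temperatures = temps,
        groupings = list(single_process = list(n_processes = 1L,
                                               tasks_per_process = n_replicas),
                         per_replica = list(n_processes = n_replicas,
                                            tasks_per_process = 1L))))
    write_manifest(manifest, dir)
  })
}

#' Generate a fixture QM study
#'
#' @param dir target directory.
#' @param seed integer seed.
#' @param method,basis_set QM method and basis-set specific names; defaults
#'   drawn from the seed. Unmapped names (e.g. \code{"LANL2DZ"}) are legal
#'   and expected to survive with no dictionary link.
#' @param executable executable string; the default Gaussian-style
#'   \code{<ARCH>-<PRODUCT>Rev<REV>} pattern exercises build-info parsing.
#' @param base_time ISO timestamp base.
#' @return manifest, invisibly.
#' @export
generate_qm_study <- function(dir, seed = 1L, method = NULL, basis_set = NULL,
                              executable = "EM64L-G09RevC.01",
                              base_time = "2013-06-01T00:00:00Z") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed + 2000L, {
    if (is.null(method)) method <- sample(c("MP2", "B3LYP", "HF", "AM1"), 1)
    if (is.null(basis_set)) basis_set <- sample(c("6-31G*", "cc-pVDZ", "LANL2DZ"), 1)
    system_name <- "benzoate ligand"
    mols <- list(mol_spec("LIG", "small molecule", 1L))
    write_topology_file(file.path(dir, "system.top"), system_name, mols)
    elapsed <- round(stats::runif(1, 120, 86400))
    kv <- list(
      METHOD = method, BASIS_SET = basis_set,
      CALCULATION = "Geometry optimization",
      SYSTEM_NAME = system_name,
      SOLVENT_TYPE = "vacuum", BOUNDARY_CONDITIONS = "non-periodic",
      FROZEN_CORE = tolower(as.character(method %in% c("MP2", "CCSD"))),
      CONVERGED = "true",
      SOFTWARE_NAME = "Gaussian", SOFTWARE_VERSION = "09",
      EXECUTABLE = executable,
      OS = "Linux", CPU_ARCHITECTURE = "x86_64",
      START_TIME = fmt_ts(base_time, 0),
      END_TIME = fmt_ts(base_time, elapsed),
      ELAPSED_SECONDS = elapsed)
    writeLines(c("# QM input", sprintf("METHOD = %s", method),
                 sprintf("BASIS_SET = %s", basis_set)),
               file.path(dir, "qm.in"))
    write_kv_file(file.path(dir, "qm.log"), "%SIMDEX_QMOUT 1.0", kv)
    for (k in c(1, 2, 10)) {
      writeLines(sprintf("placeholder checkpoint %d", k),
                 file.path(dir, sprintf("snapshot.%d.chk", k)))
    }
    manifest <- list(
      kind = "qm", seed = seed,
      config = list(method = method, basis_set = basis_set,
                    executable = executable, base_time = base_time),
      expected = list(
        system = list(name = system_name,
                      molecules = list(list(name = "LIG", kind = "small molecule",
                                            count = 1L,
                                            residues = mols[[1]]$residues,
                                            atoms = mols[[1]]$atoms))),
        tasks = stats::setNames(
          list(record_fields(parse_qm_output(file.path(dir, "qm.log")))),
          "qm.log")))
    write_manifest(manifest, dir)
  })
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(manifest)
}

#' Read a fixture manifest
#' @param dir study directory.
#' @export
read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}

#' Parse and assemble a study directory into an experiment
#'
#' Walks the directory, detects each file's format, parses topologies and
#' MD/QM outputs, assigns file roles (\code{.in} files are inputs,
#' topologies attach to the molecular system, everything else is output)
#' and assembles the experiment tree. Manifest files are ignored: assembly
#' never consults the generator's ground truth.
#'
#' @param dir study directory.
#' @param dictionaries optional dictionary set (sequence normalization,
#'   derived attributes downstream).
#' @param replica_mode replica grouping mode, see \code{\link{group_replicas}}.
#' @return an \code{experiment}.
#' @export
parse_study_dir <- function(dir, dictionaries = NULL,
                            replica_mode = c("single_process", "per_replica")) {
  paths <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  paths <- paths[basename(paths) != "manifest.json"]
  systems <- list(); records <- list(); files <- list()
  for (p in paths) {
    full <- file.path(dir, p)
    fmt <- detect_format(full)
    if (fmt == "SIMDEX_TOP") {
      sys <- parse_topology(full, dictionaries)
      sys$topology_file_uid <- p
      systems[[length(systems) + 1L]] <- sys
      files[[length(files) + 1L]] <- file_reference(
        uid = p, path = p, format = fmt, role = "topology",
        size = file.size(full))
    } else if (fmt == "SIMDEX_MDOUT" || fmt == "SIMDEX_QMOUT") {
      rec <- if (fmt == "SIMDEX_MDOUT") parse_md_output(full) else parse_qm_output(full)
      rec$source_file <- file_reference(uid = p, path = p, format = fmt,
                                        role = "output", size = file.size(full))
      records[[length(records) + 1L]] <- rec
    } else {
      role <- if (tolower(tools::file_ext(p)) == "in") "input" else "output"
      files[[length(files) + 1L]] <- file_reference(
        uid = p, path = p, format = if (fmt != "unknown") fmt, role = role,
        size = file.size(full))
    }
  }
  if (length(records) == 0) stopf("simdex_assembly_error", "no task output found in '%s'", dir)
  # canonical stage order, then start time, then name: directory listing
  # order is alphabetical and must not dictate workflow order
  stage_rank <- function(rec) {
    match(rec$stage %||% rec$task_kind,
          c("minimization", "heating", "equilibration", "production", "remd"),
          nomatch = 99L)
  }
  ord <- order(vapply(records, function(r) r$copy %||% "1", character(1)),
               vapply(records, stage_rank, integer(1)),
               vapply(records, function(r) r$execution$start %||% "", character(1)),
               vapply(records, function(r) r$source_file$uid, character(1)))
  assemble_experiment(systems, records[ord], files, replica_mode = replica_mode)
}
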