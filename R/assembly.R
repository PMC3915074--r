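#' Natural ordering of task and trajectory file names
#'
#' Trajectory order is commonly inferred from file names, and a straight
#' string sort mis-ranks them ("10.traj" before "2.traj"). Names are split
#' into digit and non-digit runs and compared token by token: digit runs
#' numerically (leading zeros compare equal, the shorter spelling ranks
#' first on ties), other runs byte-lexicographically, digit runs before
#' text runs, and shorter token sequences before their extensions. The
#' result is a total order; ties on the full key keep input order (stable).
#'
#' @param names non-empty character vector of file names.
#' @return the names in natural order. When no name contains a digit the
#'   order is purely lexicographic and the attribute
#'   \code{"all_lexicographic"} is set to \code{TRUE} so callers can flag
#'   rather than trust the inferred order.
#' @export
order_task_files <- function(names) {
  if (length(names) == 0) stopf("simdex_usage_error", "names must be non-empty")
  keys <- vapply(names, natural_sort_key, character(1))
  ord <- order(keys, method = "radix")
  out <- names[ord]
  if (!any(grepl("[0-9]", names))) attr(out, "all_lexicographic") <- TRUE
  out
}

# one comparable key per name; radix (byte) order over keys realizes the
# tokenized comparator described above
natural_sort_key <- function(name) {
  tokens <- regmatches(name, gregexpr("[0-9]+|[^0-9]+", name))[[1]]
  parts <- vapply(tokens, function(tok) {
    if (grepl("^[0-9]+$", tok)) {
      stripped <- sub("^0+", "", tok)
      if (!nzchar(stripped)) stripped <- "0"
      # digit-count prefix makes numeric comparison length-free;
      # trailing token length realizes the "shorter spelling first" tie rule
      paste0("0", sprintf("%05d", nchar(stripped)), stripped,
             sprintf("%05d", nchar(tok)))
    } else {
      paste0("1", tok)
    }
  }, character(1))
  paste(parts, collapse = "\x01")
}

#' Group replica MD tasks into processes
#'
#' An enhanced-sampling run of n replicas (e.g. a 4-replica REMD run) can
#' legally be represented either as one process holding all n MD tasks or
#' as n processes of one task each; both groupings are supported and
#' \code{"single_process"} is the default.
#'
#' @param md_tasks non-empty list of MD \code{experiment_task}s.
#' @param mode \code{"single_process"} or \code{"per_replica"}.
#' @return list of \code{process} objects.
#' @export
group_replicas <- function(md_tasks, mode = c("single_process", "per_replica")) {
  if (length(md_tasks) == 0) stopf("simdex_usage_error", "md_tasks must be non-empty")
  mode <- match.arg(mode)
  ids <- vapply(md_tasks, function(t) t$id, character(1))
  if (mode == "single_process") {
    list(process(id = content_id(ids, prefix = "proc"), tasks = md_tasks))
  } else {
    lapply(md_tasks, function(t) {
      process(id = content_id(t$id, prefix = "proc"), tasks = list(t))
    })
  }
}

#' Assemble an experiment from parsed records
#'
#' Builds the experiment tree: one process group per (molecular system,
#' copy); within a group, consecutive records of the same stage (or task
#' kind when no stage is recorded) form one process; replica records are
#' grouped per \code{replica_mode}. Consecutive processes and consecutive
#' tasks within a process are chained as dependencies following the task
#' order. Parameter sets from the records are registered on the experiment
#' and referenced by id. Trajectory and input files are attached to their
#' stage's task, trajectories in natural order; topology files attach to
#' the molecular system.
#'
#' @param systems list of \code{molecular_system}.
#' @param tasks list of parsed task records (\code{parse_md_output} /
#'   \code{parse_qm_output} results).
#' @param files list of \code{file_reference} covering the study's files
#'   (the records' own source files are added automatically).
#' @param id,name experiment identity (defaults derived from content).
#' @param role experiment role term.
#' @param replica_mode how replica task sets become processes, see
#'   \code{\link{group_replicas}}.
#' @return a valid \code{experiment}.
#' @export
assemble_experiment <- function(systems, tasks, files = list(),
                                id = NULL, name = NULL, role = "simulation",
                                replica_mode = c("single_process", "per_replica")) {
  replica_mode <- match.arg(replica_mode)
  if (length(systems) == 0) stopf("simdex_assembly_error", "no molecular system")
  names(systems) <- vapply(systems, function(s) s$id, character(1))

  # every record must resolve to exactly one system
  resolve_system <- function(rec) {
    if (!is.null(rec$system_name)) {
      hits <- Filter(function(s) identical(s$name, rec$system_name), systems)
      if (length(hits) == 1) return(hits[[1]]$id)
      if (length(hits) == 0) {
        stopf("simdex_assembly_error",
              "task '%s' targets unknown system '%s'",
              rec$source_file$uid, rec$system_name)
      }
      stopf("simdex_assembly_error", "system name '%s' is ambiguous", rec$system_name)
    }
    if (length(systems) == 1) return(systems[[1]]$id)
    stopf("simdex_assembly_error",
          "task '%s' names no system and several systems are present",
          rec$source_file$uid)
  }

  all_files <- files
  have <- vapply(all_files, function(f) f$uid, character(1))
  for (rec in tasks) {
    if (!rec$source_file$uid %in% have) {
      all_files <- c(all_files, list(rec$source_file))
      have <- c(have, rec$source_file$uid)
    }
  }
  uid_by_role <- function(role) {
    vapply(Filter(function(f) identical(f$role, role), all_files),
           function(f) f$uid, character(1))
  }
  input_uids <- uid_by_role("input")
  output_uids <- uid_by_role("output")
  traj_uids <- output_uids[grepl("\\.traj$", output_uids)]

  param_registry <- list()
  register_params <- function(ps) {
    if (is.null(ps)) return(character())
    param_registry[[ps$id]] <<- ps
    ps$id
  }

  make_task <- function(rec) {
    stage <- rec$stage %||% rec$task_kind
    stem <- tools::file_path_sans_ext(basename(rec$source_file$uid))
    dir_prefix <- dirname(rec$source_file$uid)
    in_prefix <- if (dir_prefix == ".") "" else paste0(dir_prefix, "/")
    my_inputs <- input_uids[tools::file_path_sans_ext(basename(input_uids)) == stem &
                              startsWith(input_uids, in_prefix)]
    my_traj <- traj_uids[startsWith(basename(traj_uids), paste0(stem, ".")) &
                           startsWith(traj_uids, in_prefix)]
    if (length(my_traj) > 0) my_traj <- as.character(order_task_files(my_traj))
    ps_ids <- register_params(rec$parameters)
    experiment_task(
      id = content_id(rec$source_file$uid, prefix = "task"),
      kind = rec$task_kind,
      method_name = rec$method_name,
      boundary_conditions = rec$boundary_conditions,
      solvent_type = rec$solvent_type,
      calculation = rec$calculation,
      conditions = rec$conditions,
      environment = rec$environment,
      execution = rec$execution,
      software = rec$software,
      parameter_set_ids = ps_ids,
      file_uids = c(sort(my_inputs), rec$source_file$uid, my_traj))
  }

  # partition records into (system, copy) groups, preserving input order
  group_key <- vapply(tasks, function(rec) {
    paste(resolve_system(rec), rec$copy %||% "1", sep = "\x1f")
  }, character(1))
  groups <- split(seq_along(tasks), factor(group_key, levels = unique(group_key)))

  process_groups <- lapply(names(groups), function(key) {
    idx <- groups[[key]]
    sys_id <- strsplit(key, "\x1f")[[1]][1]
    recs <- tasks[idx]
    stages <- vapply(recs, function(r) r$stage %||% r$task_kind, character(1))
    runs <- rle(stages)
    procs <- list()
    pos <- 1L
    for (ri in seq_along(runs$lengths)) {
      chunk <- recs[pos:(pos + runs$lengths[ri] - 1L)]
      pos <- pos + runs$lengths[ri]
      tks <- lapply(chunk, make_task)
      # chain tasks in order within the process
      if (length(tks) > 1 && is.null(chunk[[1]]$replica)) {
        for (i in 2:length(tks)) tks[[i]]$depends_on <- tks[[i - 1]]$id
      }
      if (!is.null(chunk[[1]]$replica)) {
        procs <- c(procs, group_replicas(tks, replica_mode))
      } else {
        procs <- c(procs, list(process(
          id = content_id(key, runs$values[ri], ri, prefix = "proc"),
          tasks = tks)))
      }
    }
    if (length(procs) > 1) {
      for (i in 2:length(procs)) procs[[i]]$depends_on <- procs[[i - 1]]$id
    }
    process_group(
      id = content_id(key, prefix = "pg"),
      system_id = sys_id, processes = procs)
  })

  exp_name <- name %||% (systems[[1]]$name %||% "simulation study")
  exp <- experiment(
    id = id %||% content_id(exp_name, vapply(all_files, function(f) f$uid, character(1)),
                            prefix = "exp"),
    name = exp_name, role = role,
    systems = systems,
    parameter_sets = param_registry,
    process_groups = process_groups,
    file_collections = list(file_system_ref(type = "local", files = all_files)))
  exp
}
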