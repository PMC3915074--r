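# Independent oracles and generators shared across tests. The oracles are
# deliberately naive (pairwise comparators, linear scans) and separate from
# the package's implementations.

pkg_dicts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_dictionary_set()
    cache
  }
})

# ---- natural-order comparator oracle ------------------------------------

nat_tokens <- function(name) regmatches(name, gregexpr("[0-9]+|[^0-9]+", name))[[1]]

byte_cmp <- function(x, y) {
  ix <- utf8ToInt(x); iy <- utf8ToInt(y)
  n <- min(length(ix), length(iy))
  for (k in seq_len(n)) if (ix[k] != iy[k]) return(sign(ix[k] - iy[k]))
  sign(length(ix) - length(iy))
}

# tokenized (text, number) tuple comparison: digits numerically (leading
# zeros equal, shorter spelling first), text bytewise, digits before text,
# shorter token sequences first
nat_cmp <- function(a, b) {
  ta <- nat_tokens(a); tb <- nat_tokens(b)
  for (i in seq_len(min(length(ta), length(tb)))) {
    x <- ta[i]; y <- tb[i]
    xd <- grepl("^[0-9]+$", x); yd <- grepl("^[0-9]+$", y)
    if (xd != yd) return(if (xd) -1L else 1L)
    if (xd) {
      xs <- sub("^0+", "", x); if (!nzchar(xs)) xs <- "0"
      ys <- sub("^0+", "", y); if (!nzchar(ys)) ys <- "0"
      if (nchar(xs) != nchar(ys)) return(sign(nchar(xs) - nchar(ys)))
      c_ <- byte_cmp(xs, ys)
      if (c_ != 0L) return(c_)
      if (nchar(x) != nchar(y)) return(sign(nchar(x) - nchar(y)))
    } else {
      c_ <- byte_cmp(x, y)
      if (c_ != 0L) return(c_)
    }
  }
  sign(length(ta) - length(tb))
}

# stable insertion sort under nat_cmp
oracle_nat_sort <- function(names) {
  out <- character()
  for (nm in names) {
    pos <- length(out) + 1L
    for (i in seq_along(out)) {
      if (nat_cmp(nm, out[i]) < 0L) { pos <- i; break }
    }
    out <- append(out, nm, after = pos - 1L)
  }
  out
}

random_filenames <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:12, 1)
  stems <- c("md", "traj", "run", "prod", "min", "a", "b", "seg")
  exts <- c(".traj", ".out", ".nc", "")
  vapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    parts <- vapply(seq_len(k), function(j) {
      if (stats::runif(1) < 0.6) {
        num <- sample(0:120, 1)
        pad <- sample(0:2, 1)
        sprintf(paste0("%0", nchar(num) + pad, "d"), num)
      } else sample(stems, 1)
    }, character(1))
    paste0(paste(parts, collapse = sample(c(".", "_", ""), 1)), sample(exts, 1))
  }, character(1))
}

# ---- triplet store query oracle ------------------------------------------

oracle_query <- function(triplets, preds) {
  subs <- unique(triplets$subject)
  keep <- vapply(subs, function(s) {
    rows <- triplets[triplets$subject == s, , drop = FALSE]
    all(vapply(preds, function(p) {
      hit <- rows$attribute == p[[1]]
      if (p[[2]] == "==") {
        any(hit & rows$value == p[[3]])
      } else {
        any(hit & grepl(tolower(p[[3]]), tolower(rows$value), fixed = TRUE))
      }
    }, logical(1)))
  }, logical(1))
  sort(subs[keep])
}

random_store <- function() {
  attrs <- c("file_format", "solvent_type", "force_field_name", "lab_tag", "note")
  vals <- c("PDB", "CSV", "explicit", "implicit", "AMBER FF99SB", "TIP3P", "x1", "x2")
  n <- sample(5:60, 1)
  data.frame(
    subject = sprintf("s%d", sample(1:12, n, replace = TRUE)),
    subject_type = "file",
    attribute = sample(attrs, n, replace = TRUE),
    value = sample(vals, n, replace = TRUE),
    unit = NA_character_, standard = NA,
    stringsAsFactors = FALSE)
}

random_predicates <- function() {
  attrs <- c("file_format", "solvent_type", "force_field_name", "lab_tag", "note")
  vals <- c("PDB", "CSV", "explicit", "AMBER FF99SB", "x1", "FF", "i")
  k <- sample(1:3, 1)
  lapply(seq_len(k), function(i) {
    list(sample(attrs, 1), sample(c("==", "contains"), 1), sample(vals, 1))
  })
}

# ---- fixture manifest recovery -------------------------------------------

expect_system_matches_manifest <- function(sys, msys) {
  expect_equal(sys$name, msys$name)
  expect_equal(length(sys$molecules), length(msys$molecules))
  for (i in seq_along(sys$molecules)) {
    m <- sys$molecules[[i]]; mm <- msys$molecules[[i]]
    expect_equal(m$name, mm$name)
    expect_equal(m$kind, mm$kind)
    expect_equal(m$count, mm$count)
    expect_equal(m$residues$name, as.character(mm$residues$name))
    expect_equal(m$residues$count, as.integer(mm$residues$count))
    expect_equal(m$atoms$element, as.character(mm$atoms$element))
    expect_equal(m$atoms$count, as.integer(mm$atoms$count))
    if (!is.null(m$chain)) expect_equal(m$chain, as.character(unlist(mm$chain)))
  }
}

expect_recovers_manifest <- function(dir, dicts, replica_mode = "single_process") {
  man <- read_manifest(dir)
  exp <- parse_study_dir(dir, dicts, replica_mode = replica_mode)

  # every output file parses back to exactly its manifest record
  for (uid in names(man$expected$tasks)) {
    rec <- if (man$kind == "qm") {
      parse_qm_output(file.path(dir, uid))
    } else {
      parse_md_output(file.path(dir, uid))
    }
    expect_equal(record_fields(rec), man$expected$tasks[[uid]],
                 info = sprintf("%s: %s", dir, uid))
  }

  expect_system_matches_manifest(exp$systems[[1]], man$expected$system)
  expect_equal(nrow(validate_experiment(exp)), 0L)

  n_tasks <- 0L
  for (pg in exp$process_groups) for (pr in pg$processes) n_tasks <- n_tasks + length(pr$tasks)
  expect_equal(n_tasks, length(man$expected$tasks))

  if (man$kind == "md") {
    expect_equal(length(exp$process_groups), man$expected$n_process_groups)
    for (pg in exp$process_groups) {
      expect_equal(length(pg$processes), man$expected$n_processes_per_group)
    }
    traj <- unlist(lapply(exp$process_groups, function(pg) {
      unlist(lapply(pg$processes, function(pr) {
        unlist(lapply(pr$tasks, function(tk) grep("\\.traj$", tk$file_uids, value = TRUE)))
      }))
    }))
    expect_equal(as.character(traj %||% character()),
                 as.character(unlist(man$expected$trajectory_order %||% character())))
  }
  if (man$kind == "remd") {
    g <- man$expected$groupings[[replica_mode]]
    procs <- exp$process_groups[[1]]$processes
    expect_equal(length(procs), g$n_processes)
    expect_true(all(vapply(procs, function(p) length(p$tasks), integer(1)) ==
                      g$tasks_per_process))
  }
  invisible(exp)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# minimal well-formed experiment for model/serializer tests
tiny_experiment <- function(id = "exp-1") {
  ps <- md_parameter_set("ps-1", force_fields = list(force_field("AMBER FF99SB")),
                         ensemble = "canonical", n_steps = 1000, step_length = 0.002)
  t1 <- experiment_task("t-1", "minimization", method_name = "Energy minimization",
                        parameter_set_ids = "ps-1", file_uids = "min.out")
  t2 <- experiment_task("t-2", "md", method_name = "Molecular dynamics",
                        parameter_set_ids = "ps-1", file_uids = "md.out",
                        conditions = simulated_conditions(300, 1))
  sys <- molecular_system("sys-1", name = "test system",
                          molecules = list(molecule("WAT", 10L, "solvent")))
  experiment(
    id, "tiny study",
    systems = stats::setNames(list(sys), "sys-1"),
    parameter_sets = stats::setNames(list(ps), "ps-1"),
    process_groups = list(process_group("pg-1", "sys-1", processes = list(
      process("pr-1", tasks = list(t1)),
      process("pr-2", tasks = list(t2), depends_on = "pr-1")))),
    file_collections = list(file_system_ref(files = list(
      file_reference("min.out", "min.out", role = "output"),
      file_reference("md.out", "md.out", role = "output")))))
}
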