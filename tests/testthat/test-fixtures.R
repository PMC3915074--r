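tree_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  hashes <- tools::md5sum(file.path(dir, files))
  stats::setNames(unname(hashes), files)
}

test_that("regeneration at equal seed and config is byte-identical", {
  for (gen in list(
    function(d) generate_md_study(d, seed = 5),
    function(d) generate_remd_study(d, seed = 5, n_replicas = 3),
    function(d) generate_qm_study(d, seed = 5))) {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    gen(d1); gen(d2)
    expect_identical(tree_digest(d1), tree_digest(d2))
  }
  # different seeds give different studies
  d3 <- withr::local_tempdir(); d4 <- withr::local_tempdir()
  generate_md_study(d3, seed = 5); generate_md_study(d4, seed = 6)
  expect_false(identical(tree_digest(d3), tree_digest(d4)))
})

test_that("parsing a generated study reproduces its manifest", {
  dicts <- pkg_dicts()
  d <- withr::local_tempdir()
  generate_md_study(d, seed = 1)
  expect_recovers_manifest(d, dicts)

  d2 <- withr::local_tempdir()
  generate_qm_study(d2, seed = 3)
  exp <- expect_recovers_manifest(d2, dicts)
  man <- read_manifest(d2)
  expect_equal(man$expected$tasks[["qm.log"]]$revision, "C.01")
  tk <- exp$process_groups[[1]]$processes[[1]]$tasks[[1]]
  expect_equal(tk$kind, "qm")
})

test_that("explicit-water studies record water as H x2 plus O x1 per molecule", {
  d <- withr::local_tempdir()
  man <- generate_md_study(d, seed = 2, explicit_water = TRUE)
  wat <- Filter(function(m) m$name == "WAT", man$expected$system$molecules)[[1]]
  expect_equal(as.integer(wat$atoms$count[wat$atoms$element == "H"]), 2L)
  expect_equal(as.integer(wat$atoms$count[wat$atoms$element == "O"]), 1L)
  expect_gt(wat$count, 1)

  sys <- parse_topology(file.path(d, "system.top"))
  pwat <- Filter(function(m) m$name == "WAT", sys$molecules)[[1]]
  expect_equal(pwat$atoms$count[pwat$atoms$element == "H"], 2L)
  expect_equal(pwat$count, wat$count)
})

test_that("REMD fixtures support both legal replica groupings", {
  dicts <- pkg_dicts()
  d <- withr::local_tempdir()
  man <- generate_remd_study(d, seed = 4, n_replicas = 4)
  expect_length(man$expected$tasks, 4)

  expect_recovers_manifest(d, dicts, replica_mode = "single_process")
  expect_recovers_manifest(d, dicts, replica_mode = "per_replica")

  # one replica: both modes coincide
  d1 <- withr::local_tempdir()
  generate_remd_study(d1, seed = 4, n_replicas = 1)
  e1 <- parse_study_dir(d1, dicts, replica_mode = "single_process")
  e2 <- parse_study_dir(d1, dicts, replica_mode = "per_replica")
  expect_equal(length(e1$process_groups[[1]]$processes),
               length(e2$process_groups[[1]]$processes))

  expect_error(generate_remd_study(withr::local_tempdir(), seed = 1, n_replicas = 0),
               class = "simdex_usage_error")
})

test_that("every generated tree contains a pair a naive string sort mis-orders", {
  for (gen in list(function(d) generate_md_study(d, seed = 8),
                   function(d) generate_remd_study(d, seed = 8),
                   function(d) generate_qm_study(d, seed = 8))) {
    d <- withr::local_tempdir()
    gen(d)
    files <- list.files(d, recursive = TRUE)
    naive <- sort(files, method = "radix")
    natural <- as.character(order_task_files(files))
    expect_false(identical(naive, natural))
  }
})

test_that("stage subsets and empty stage lists are handled", {
  d <- withr::local_tempdir()
  man <- generate_md_study(d, seed = 9, stages = c("minimization", "production"))
  expect_equal(man$expected$n_processes_per_group, 2)
  exp <- parse_study_dir(d, pkg_dicts())
  expect_length(exp$process_groups[[1]]$processes, 2)
  expect_error(generate_md_study(withr::local_tempdir(), seed = 1, stages = character()),
               class = "simdex_usage_error")
})
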