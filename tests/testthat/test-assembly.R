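test_that("natural ordering fixes the classic 10-before-2 mistake", {
  expect_equal(as.character(order_task_files(c("10.traj", "2.traj"))),
               c("2.traj", "10.traj"))
  expect_equal(as.character(order_task_files(c("1.traj", "2.traj", "3.traj"))),
               c("1.traj", "2.traj", "3.traj"))
  expect_equal(as.character(order_task_files(c("md10.traj", "md02.traj", "md1.traj"))),
               c("md1.traj", "md02.traj", "md10.traj"))
  # leading zeros compare equal numerically, shorter spelling first
  expect_equal(as.character(order_task_files(c("02.traj", "2.traj"))),
               c("2.traj", "02.traj"))
  expect_error(order_task_files(character()), class = "simdex_usage_error")
  # digit-free names fall back to lexicographic order and are flagged
  flagged <- order_task_files(c("beta.traj", "alpha.traj"))
  expect_true(attr(flagged, "all_lexicographic"))
})

test_that("natural ordering agrees with the brute-force tokenized comparator", {
  set.seed(101)
  for (i in 1:250) {
    names <- random_filenames()
    got <- as.character(order_task_files(names))
    expect_equal(got, oracle_nat_sort(names), info = paste(names, collapse = " | "))
    # idempotent and permutation-invariant (same multiset in, same sequence out)
    expect_equal(as.character(order_task_files(got)), got)
    expect_equal(as.character(order_task_files(sample(names))), got)
  }
})

test_that("replica runs group as one process or one process per replica", {
  tasks <- lapply(1:4, function(k) experiment_task(sprintf("t%d", k), "md"))
  one <- group_replicas(tasks, "single_process")
  expect_length(one, 1)
  expect_length(one[[1]]$tasks, 4)

  four <- group_replicas(tasks, "per_replica")
  expect_length(four, 4)
  expect_true(all(vapply(four, function(p) length(p$tasks), integer(1)) == 1))

  single <- group_replicas(tasks[1], "single_process")
  expect_length(single, 1)
  expect_error(group_replicas(list()), class = "simdex_usage_error")
})

test_that("assembly builds one group per system copy and one process per stage", {
  dicts <- pkg_dicts()

  d <- withr::local_tempdir()
  generate_md_study(d, seed = 11)
  exp <- parse_study_dir(d, dicts)
  expect_length(exp$process_groups, 1)
  expect_length(exp$process_groups[[1]]$processes, 3)
  expect_equal(nrow(validate_experiment(exp)), 0L)

  d2 <- withr::local_tempdir()
  generate_md_study(d2, seed = 12, n_copies = 2)
  exp2 <- parse_study_dir(d2, dicts)
  expect_length(exp2$process_groups, 2)

  # ligand and receptor described by separate topologies get separate groups
  d3 <- withr::local_tempdir()
  writeLines(c("%SIMDEX_TOP 1.0", "%SECTION HEADER", "SYSTEM_NAME = receptor",
               "%SECTION MOLECULE R1", "KIND = biomolecule", "COUNT = 1",
               "RESIDUE ALA 3", "ATOM C 9"), file.path(d3, "receptor.top"))
  writeLines(c("%SIMDEX_TOP 1.0", "%SECTION HEADER", "SYSTEM_NAME = ligand",
               "%SECTION MOLECULE L1", "KIND = small molecule", "COUNT = 1",
               "ATOM C 6"), file.path(d3, "ligand.top"))
  for (s in c("receptor", "ligand")) {
    writeLines(c("%SIMDEX_MDOUT 1.0", "TASK_KIND = md",
                 sprintf("SYSTEM_NAME = %s", s), "FORCE_FIELD = AMBER FF99SB",
                 "FOOTER: normal"), file.path(d3, sprintf("%s.out", s)))
  }
  exp3 <- parse_study_dir(d3, dicts)
  expect_length(exp3$process_groups, 2)

  # a record that matches no system is an assembly error
  writeLines(c("%SIMDEX_MDOUT 1.0", "TASK_KIND = md", "SYSTEM_NAME = nothere",
               "FORCE_FIELD = X", "FOOTER: normal"), file.path(d3, "stray.out"))
  expect_error(parse_study_dir(d3, dicts), class = "simdex_assembly_error")
})

test_that("task counts are conserved through assembly", {
  for (seed in 21:23) {
    d <- withr::local_tempdir()
    man <- generate_md_study(d, seed = seed, n_copies = (seed %% 2) + 1)
    exp <- parse_study_dir(d, pkg_dicts())
    n <- sum(unlist(lapply(exp$process_groups, function(pg) {
      vapply(pg$processes, function(pr) length(pr$tasks), integer(1))
    })))
    expect_equal(n, length(man$expected$tasks))
  }
})
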