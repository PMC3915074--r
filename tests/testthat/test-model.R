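test_that("a well-formed experiment validates cleanly", {
  expect_equal(nrow(validate_experiment(tiny_experiment())), 0L)
})

test_that("containment, cycle and file invariants are reported as data", {
  exp <- tiny_experiment()

  # same task in two processes
  bad <- exp
  bad$process_groups[[1]]$processes[[2]]$tasks <-
    c(bad$process_groups[[1]]$processes[[2]]$tasks,
      bad$process_groups[[1]]$processes[[1]]$tasks)
  rep <- validate_experiment(bad)
  expect_true("containment" %in% rep$rule)

  # process dependency cycle A -> B -> A
  bad <- exp
  bad$process_groups[[1]]$processes[[1]]$depends_on <- "pr-2"
  rep <- validate_experiment(bad)
  expect_true("cycle" %in% rep$rule)

  # a task referencing a topology file
  bad <- exp
  bad$file_collections[[1]]$files[[1]]$role <- "topology"
  rep <- validate_experiment(bad)
  expect_true("topology-file" %in% rep$rule)

  # an MD task with no MD parameter set
  bad <- exp
  bad$process_groups[[1]]$processes[[2]]$tasks[[1]]$parameter_set_ids <- character()
  rep <- validate_experiment(bad)
  expect_true("parameter-set" %in% rep$rule)

  # negative simulated conditions
  bad <- exp
  bad$process_groups[[1]]$processes[[2]]$tasks[[1]]$conditions$reference_temperature <- -10
  expect_true("conditions" %in% validate_experiment(bad)$rule)
})

test_that("extended attributes are multi-valued triplets and removable", {
  ps <- md_parameter_set("ps", force_fields = list(force_field("TIP3P")))
  ps2 <- attach_extended_attribute(ps, "PME interpolation order", "4")
  expect_length(ps2$extended, 1)
  expect_equal(ps2$extended[[1]]$value, "4")

  ps3 <- attach_extended_attribute(ps2, "PME tolerance", "1e-5", unit = NULL)
  ps4 <- attach_extended_attribute(ps3, "PME tolerance", "1e-6")
  expect_length(ps4$extended, 3)

  expect_error(attach_extended_attribute(ps, "", "x"), class = "simdex_usage_error")

  # attach then remove restores structural equality
  expect_identical(remove_extended_attribute(ps3, "PME tolerance"), ps2)
  expect_identical(remove_extended_attribute(ps2, "PME interpolation order"), ps)
})

test_that("dependencies stay same-kind and acyclic with a topological order", {
  a <- process("A"); b <- process("B"); c_ <- process("C")
  g <- dependency_graph()
  g <- add_dependency(a, b, g)
  g <- add_dependency(b, c_, g)
  expect_equal(simdex:::topological_order(g$edges), c("A", "B", "C"))

  expect_error(add_dependency(a, a, g), class = "simdex_cycle_error")
  expect_error(add_dependency(c_, a, g), class = "simdex_cycle_error")

  tk <- experiment_task("T", "md")
  expect_error(add_dependency(tk, a, g), class = "simdex_usage_error")
})
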