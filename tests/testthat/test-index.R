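test_that("flattening materializes stored and dictionary-derived attributes", {
  dicts <- pkg_dicts()
  exp <- tiny_experiment()
  tt <- flatten_to_triplets(exp, dicts)

  ff <- tt[tt$attribute == "force_field_name", ]
  expect_true("AMBER FF99SB" %in% ff$value)
  expect_true("classical" %in% tt$value[tt$attribute == "force_field_type"])

  # a QM task with MP2 gains class and family triplets through the dictionaries
  qe <- experiment(
    "exp-qm", "qm study",
    systems = stats::setNames(list(molecular_system("s1", "ligand")), "s1"),
    parameter_sets = stats::setNames(
      list(qm_parameter_set("qps", method = "MP2", basis_set = "6-31G*")), "qps"),
    process_groups = list(process_group("pg", "s1", list(
      process("pr", list(experiment_task("tq", "qm", parameter_set_ids = "qps")))))))
  qt <- flatten_to_triplets(qe, dicts)
  expect_equal(qt$value[qt$attribute == "qm_method_class"], "Moller-Plesset")
  expect_equal(qt$value[qt$attribute == "qm_method_family"], "ab initio")
  expect_equal(qt$value[qt$attribute == "basis_set_type"], "atomic")

  # derived agrees with classify_method for any method the fixtures use
  for (m in c("MP2", "B3LYP", "AM1", "XYZ999")) {
    cls <- classify_method(m, dicts)
    qe$parameter_sets[["qps"]]$method <- m
    qt <- flatten_to_triplets(qe, dicts)
    got <- qt$value[qt$attribute == "qm_method_class"]
    expect_equal(got, cls$method_class %||% character(0))
  }
})

test_that("an empty experiment flattens to identity triplets only", {
  e <- experiment("e0", "bare")
  tt <- flatten_to_triplets(e)
  expect_setequal(tt$attribute, c("experiment_id", "experiment_name", "experiment_role"))
  expect_true(all(tt$subject == "e0"))
})

test_that("flattening is deterministic and idempotent", {
  dicts <- pkg_dicts()
  d <- withr::local_tempdir()
  generate_md_study(d, seed = 31)
  exp <- parse_study_dir(d, dicts)
  t1 <- flatten_to_triplets(exp, dicts)
  t2 <- flatten_to_triplets(exp, dicts)
  expect_identical(t1, t2)
})

test_that("queries equal a linear scan for random stores and conjunctions", {
  set.seed(202)
  for (i in 1:200) {
    store <- triplet_store(random_store())
    preds <- random_predicates()
    expect_equal(query_index(store, preds), oracle_query(store$triplets, preds))
  }
  # two-predicate conjunction is the intersection of the singles
  store <- triplet_store(random_store())
  p1 <- list("file_format", "==", "PDB")
  p2 <- list("solvent_type", "==", "explicit")
  expect_equal(query_index(store, list(p1, p2)),
               sort(intersect(query_index(store, list(p1)),
                              query_index(store, list(p2)))))
  expect_error(query_index(store, list()), class = "simdex_usage_error")
  expect_error(query_index(store, list(list("a", "<>", "b"))),
               class = "simdex_usage_error")
})

test_that("tagging inserts retrievable triplets and flags catalogue status", {
  catalog <- load_cde_catalog()
  store <- triplet_store(catalog = catalog)
  store <- tag_subject(store, "traj/1.traj", "file_format", "PDB")
  expect_equal(query_index(store, list(list("file_format", "==", "PDB"))),
               "traj/1.traj")
  expect_true(store$triplets$standard[1])

  store <- tag_subject(store, "traj/1.traj", "lab_review_grade", "A")
  expect_false(store$triplets$standard[2])
  expect_equal(query_index(store, list(list("lab_review_grade", "==", "A"))),
               "traj/1.traj")

  expect_error(tag_subject(store, "x", "", "v"), class = "simdex_usage_error")
})
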