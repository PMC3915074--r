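test_that("XML serialization mirrors the tree and round-trips exactly", {
  exp <- tiny_experiment()
  doc <- to_xml(exp)
  root <- xml2::xml_root(doc)
  expect_equal(xml2::xml_name(root), "experiment")
  expect_equal(xml2::xml_attr(root, "id"), "exp-1")
  expect_length(xml2::xml_find_all(doc, "//process"), 2)
  expect_identical(from_xml(doc), exp)

  # an empty experiment is a single root element carrying id and name
  bare <- experiment("e0", "bare")
  bdoc <- to_xml(bare)
  expect_length(xml2::xml_children(xml2::xml_root(bdoc)), 0)
  expect_identical(from_xml(bdoc), bare)
})

test_that("extended attributes and dependencies survive the round trip verbatim", {
  exp <- tiny_experiment()
  exp$parameter_sets[["ps-1"]] <- attach_extended_attribute(
    exp$parameter_sets[["ps-1"]], "PME interpolation order", "4")
  exp$parameter_sets[["ps-1"]] <- attach_extended_attribute(
    exp$parameter_sets[["ps-1"]], "PME tolerance", "0.00001", unit = "kcal/mol",
    concept_id = "C123")
  exp <- attach_extended_attribute(exp, "lab", "cheatham")

  back <- from_xml(to_xml(exp))
  expect_identical(back, exp)
  ext <- back$parameter_sets[["ps-1"]]$extended
  expect_equal(ext[[2]]$unit, "kcal/mol")
  expect_equal(ext[[2]]$concept_id, "C123")
  expect_equal(back$process_groups[[1]]$processes[[2]]$depends_on, "pr-1")
})

test_that("invalid experiments are refused and unknown elements rejected with a path", {
  bad <- tiny_experiment()
  bad$process_groups[[1]]$processes[[1]]$depends_on <- "pr-1"  # self-cycle
  err <- expect_error(to_xml(bad), class = "simdex_invalid_experiment")
  expect_gt(nrow(err$report), 0)

  doc <- to_xml(tiny_experiment())
  xml2::xml_add_child(xml2::xml_root(doc), "surpriseElement")
  err <- expect_error(from_xml(doc), class = "simdex_parse_error")
  expect_match(conditionMessage(err), "surpriseElement")
  expect_match(conditionMessage(err), "/experiment/")
})

test_that("the HTML tree view is well-formed and loses no entity", {
  exp <- tiny_experiment()
  doc <- to_xml(exp)
  html <- render_html(doc)
  parsed <- xml2::read_html(html)
  n_entities <- length(xml2::xml_find_all(parsed, "//*[contains(@class,'entity')]"))
  expect_equal(n_entities, length(xml2::xml_find_all(doc, "//*")))
  expect_length(xml2::xml_find_all(parsed, "//*[@data-kind='process']"), 2)

  bare_html <- render_html(experiment("e0", "bare"))
  expect_length(xml2::xml_find_all(xml2::read_html(bare_html),
                                   "//*[contains(@class,'entity')]"), 1)
})

test_that("generated DDL declares foreign keys and extension tables", {
  ddl <- generate_ddl(model_descriptor(), pkg_dicts())
  sql <- paste(ddl, collapse = "\n")
  expect_match(sql, "type_id TEXT REFERENCES force_field_type\\(id\\)")
  expect_match(sql, "class_id TEXT REFERENCES qm_method_class\\(id\\)")
  expect_match(sql, "CREATE TABLE experiment_task_extended_attribute")
  expect_match(sql, "owner_id TEXT NOT NULL REFERENCES md_parameter_set\\(id\\)")
  # referenced tables are created before their referrers
  expect_lt(grep("CREATE TABLE qm_method_family ", ddl),
            grep("CREATE TABLE qm_method_class ", ddl))

  broken <- list(list(name = "a", fields = c(id = "TEXT"),
                      links = list(b_id = "nonexistent"), extension = FALSE))
  expect_error(generate_ddl(broken), class = "simdex_generation_error")
})

test_that("the DDL executes on SQLite and accepts every dictionary row", {
  dicts <- pkg_dicts()
  ddl <- generate_ddl(model_descriptor(), dicts)
  inserts <- generate_dictionary_inserts(dicts)
  db <- withr::local_tempfile(fileext = ".sqlite")
  execute_sql(c(ddl, inserts), db)
  for (d in dicts) {
    expect_equal(query_scalar(db, sprintf("SELECT COUNT(*) FROM %s", d$name)),
                 length(d$entries), info = d$name)
  }
  # idempotent under drop-and-recreate: running the script again succeeds
  execute_sql(c(ddl, inserts), db)
  expect_equal(query_scalar(db, "SELECT COUNT(*) FROM force_field"),
               length(dicts[["force_field"]]$entries))
})
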