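test_that("CSV loading maps rows to entries and enforces the schema", {
  df <- data.frame(ID = c("X1", "X2"), TERM = c("alpha", "beta"),
                   DESCRIPTION = c("first", "second"), stringsAsFactors = FALSE)
  d <- load_dictionary(df, name = "toy")
  expect_length(d$entries, 2)
  expect_equal(d$entries[["X2"]]$term, "beta")

  dup <- rbind(df, df[1, ])
  err <- expect_error(load_dictionary(dup, name = "toy"), class = "simdex_load_error")
  expect_match(conditionMessage(err), "X1")

  expect_error(load_dictionary(df[, c("ID", "TERM")], name = "toy"),
               class = "simdex_schema_error")
})

test_that("force-field rows carry a type link and a coarse-grain flag", {
  ff <- pkg_dicts()[["force_field"]]
  martini <- lookup_term(ff, "MARTINI")
  expect_true(martini$extras[["IS_COARSE_GRAIN"]])
  expect_equal(martini$links[["TYPE_ID"]]$target, "force_field_type")
  amber <- lookup_term(ff, "AMBER FF99SB")
  expect_false(amber$extras[["IS_COARSE_GRAIN"]])
  expect_equal(resolve_link(amber, "TYPE_ID", pkg_dicts())$term, "classical")
})

test_that("term lookup is case-insensitive and absence is a plain NULL", {
  qm <- pkg_dicts()[["qm_method"]]
  hit <- lookup_term(qm, "QM/MM")
  expect_equal(hit$description,
               "Hybrid computational method mixing quantum chemistry and molecular mechanics")
  expect_equal(lookup_term(qm, "qm/mm")$id, hit$id)
  expect_null(lookup_term(qm, "NOSUCHTERM"))
})

test_that("prefix search honours max_n and ranks exact matches first", {
  idx <- build_term_index(pkg_dicts())
  hits <- search_terms(idx, "AMBER FF", max_n = 2)
  expect_lte(length(hits), 2)
  expect_true(all(startsWith(vapply(hits, function(e) e$term, character(1)), "AMBER FF")))

  exact <- search_terms(idx, "AMBER FF99SB", max_n = 5)
  expect_equal(exact[[1]]$term, "AMBER FF99SB")

  expect_length(search_terms(idx, "zzqx", max_n = 3), 0)
  expect_error(search_terms(idx, "  ", max_n = 1), class = "simdex_usage_error")
  expect_error(search_terms(idx, "PME", max_n = 0), class = "simdex_usage_error")
})

test_that("search results are a subset of a brute-force scan and self-retrieving", {
  dicts <- pkg_dicts()
  idx <- build_term_index(dicts)

  all_terms <- unlist(lapply(dicts, function(d) {
    vapply(d$entries, function(e) e$term, character(1))
  }), use.names = FALSE)

  # self-retrievability: every entry's own full term ranks itself first
  for (d in dicts) {
    for (e in d$entries) {
      top <- search_terms(idx, e$term, max_n = 1)
      expect_equal(tolower(top[[1]]$term), tolower(e$term))
    }
  }

  set.seed(42)
  queries <- c("AMBER", "FF", "Nose", "plane", "b3", "6-31", "water model",
               sample(all_terms, 10))
  for (q in queries) {
    got <- vapply(search_terms(idx, q, max_n = 1000),
                  function(e) paste(e$dictionary, e$id), character(1))
    scan <- unlist(lapply(dicts, function(d) {
      keep <- vapply(d$entries, function(e) term_matches(e$term, q), logical(1))
      vapply(d$entries[keep], function(e) paste(e$dictionary, e$id), character(1))
    }), use.names = FALSE)
    expect_setequal(got, scan)
  }

  # deterministic rebuild: identical results from identical CSV input
  idx2 <- build_term_index(load_dictionary_set())
  for (q in queries) {
    expect_identical(
      vapply(search_terms(idx, q, max_n = 5), function(e) e$id, character(1)),
      vapply(search_terms(idx2, q, max_n = 5), function(e) e$id, character(1)))
  }
})

test_that("link resolution reports dangling ids and undeclared links", {
  dicts <- pkg_dicts()
  cls <- dicts[["qm_method_class"]]$entries[["QMC02"]]
  fam <- resolve_link(cls, "FAMILY_ID", dicts)
  expect_equal(fam$term, "ab initio")
  expect_error(resolve_link(cls, "NOT_A_LINK", dicts), class = "simdex_usage_error")

  broken <- load_dictionary(
    data.frame(ID = "B1", TERM = "broken", DESCRIPTION = "links nowhere",
               FAMILY_ID = "QMF99", stringsAsFactors = FALSE),
    name = "broken",
    schema = data.frame(COLUMN = "FAMILY_ID", KIND = "link",
                        TARGET = "qm_method_family", stringsAsFactors = FALSE))
  expect_error(resolve_link(broken$entries[[1]], "FAMILY_ID", dicts),
               class = "simdex_integrity_error")
})

test_that("the packaged dictionary set is referentially intact", {
  expect_equal(nrow(validate_dictionary_set(pkg_dicts())), 0L)
})

test_that("method classification infers class and family but never drops the name", {
  dicts <- pkg_dicts()
  mp2 <- classify_method("MP2", dicts)
  expect_equal(mp2$specific_name, "MP2")
  expect_equal(mp2$method_class, "Moller-Plesset")
  expect_equal(mp2$method_family, "ab initio")

  expect_equal(classify_method("B3LYP", dicts)$method_class, "DFT")
  expect_equal(classify_method("AM1", dicts)$method_family, "semi-empirical")

  unknown <- classify_method("XYZ999", dicts)
  expect_equal(unknown$specific_name, "XYZ999")
  expect_null(unknown$method_class)
  expect_null(unknown$method_family)

  # family is present whenever a class is: holds for every dictionary method
  for (e in dicts[["qm_method"]]$entries) {
    cls <- classify_method(e$term, dicts)
    if (!is.null(cls$method_class)) expect_false(is.null(cls$method_family))
  }
})
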