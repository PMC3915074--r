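test_that("the packaged catalogue is structurally coherent", {
  catalog <- load_cde_catalog()
  s <- cde_stats(catalog)
  expect_equal(s$n_categories, 7)

  # an element is recommended iff it has at least one recommended attribute
  for (i in seq_len(nrow(catalog$elements))) {
    el <- catalog$elements$ELEMENT[i]
    attrs <- catalog$table[catalog$table$ELEMENT == el &
                             catalog$table$CATEGORY == catalog$elements$CATEGORY[i], ]
    expect_equal(catalog$elements$RECOMMENDED[i], any(attrs$RECOMMENDED))
  }

  # recommended flags agree with the strict >4.0 rule wherever a score exists
  scored <- catalog$table[!is.na(catalog$table$MEAN_SCORE), ]
  expect_equal(scored$RECOMMENDED, scored$MEAN_SCORE > 4.0)

  # repeated loads are structurally equal
  expect_identical(catalog$table, load_cde_catalog()$table)

  # an attribute under no element is a schema error
  broken <- tempfile(fileext = ".csv")
  writeLines(c("CATEGORY,ELEMENT,ATTRIBUTE,RECOMMENDED,DERIVED,HAS_UNIT,MEAN_SCORE",
               "methods,,orphan,true,false,false,4.5"), broken)
  expect_error(load_cde_catalog(broken), class = "simdex_schema_error")
})

test_that("importance classification applies the strict >4.0 mean rule", {
  expect_equal(classify_importance(c(5, 5, 4, 4)), "recommended")
  expect_equal(classify_importance(c(4, 4, 4, 4)), "optional")   # mean exactly 4.0
  expect_equal(classify_importance(c(5, 4, NA)), "recommended")  # N/A excluded
  expect_equal(classify_importance(c("5", "4", "N/A")), "recommended")
  expect_error(classify_importance(c(NA, "N/A")), class = "simdex_undefined_score_error")
  expect_error(classify_importance(c(6, 4)), class = "simdex_usage_error")
})

test_that("importance is permutation-invariant and monotone in any one score", {
  set.seed(55)
  for (i in 1:100) {
    scores <- sample(c(1:5, NA), sample(1:6, 1), replace = TRUE)
    if (all(is.na(scores))) next
    base <- classify_importance(scores)
    perm <- scores[sample.int(length(scores))]
    expect_equal(classify_importance(perm), base)
    # raising one response never flips recommended -> optional
    j <- which(!is.na(scores))[1]
    raised <- scores; raised[j] <- 5
    if (base == "recommended") {
      expect_equal(classify_importance(raised), "recommended")
    }
  }
})

test_that("completeness is bounded, monotone, and tolerant of extensions", {
  catalog <- load_cde_catalog()
  rec <- catalog$table$ATTRIBUTE[catalog$table$RECOMMENDED]

  full <- data.frame(subject = "e", subject_type = "experiment",
                     attribute = rec, value = "x", unit = NA, standard = NA,
                     stringsAsFactors = FALSE)
  expect_equal(validate_annotations(full, catalog)$completeness, 1.0)

  none <- full[0, ]
  expect_equal(validate_annotations(none, catalog)$completeness, 0.0)

  ext <- rbind(none, data.frame(subject = "e", subject_type = "experiment",
                                attribute = "lab_custom_score", value = "9",
                                unit = NA, standard = NA, stringsAsFactors = FALSE))
  rep <- validate_annotations(ext, catalog)
  expect_equal(rep$unknown_attributes, "lab_custom_score")
  expect_equal(rep$completeness, 0.0)

  # adding triplets never decreases completeness
  set.seed(77)
  prev <- 0
  acc <- none
  for (a in sample(rec)) {
    acc <- rbind(acc, data.frame(subject = "e", subject_type = "experiment",
                                 attribute = a, value = "v", unit = NA,
                                 standard = NA, stringsAsFactors = FALSE))
    cur <- validate_annotations(acc, catalog)$completeness
    expect_gte(cur, prev)
    expect_lte(cur, 1.0)
    prev <- cur
  }
})
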