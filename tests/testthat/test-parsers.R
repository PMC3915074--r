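write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("format detection keys on content, not extension", {
  pdb <- write_tmp(c("HEADER    NUCLEIC ACID", "ATOM      1  P     G A   1"))
  expect_equal(detect_format(pdb), "PDB")
  top <- write_tmp(c("%SIMDEX_TOP 1.0", "%SECTION HEADER"))
  expect_equal(detect_format(top), "SIMDEX_TOP")
  empty <- write_tmp(character())
  expect_equal(detect_format(empty), "unknown")
  expect_equal(detect_format(write_tmp("just some text")), "unknown")
  expect_error(detect_format(file.path(tempdir(), "no-such-file")),
               class = "simdex_io_error")
})

test_that("MD output parsing maps keys to the record and never invents values", {
  f <- write_tmp(c("%SIMDEX_MDOUT 1.0", "TASK_KIND = md",
                   "THERMOSTAT = Langevin", "N_STEPS = 50000",
                   "FORCE_FIELD = AMBER FF99SB", "FORCE_FIELD = TIP3P",
                   "FOOTER: normal"))
  rec <- parse_md_output(f)
  expect_equal(rec$task_kind, "md")
  expect_equal(rec$parameters$thermostat$implementation, "Langevin")
  expect_equal(rec$parameters$n_steps, 50000)
  expect_equal(vapply(rec$parameters$force_fields, function(x) x$name, character(1)),
               c("AMBER FF99SB", "TIP3P"))
  expect_equal(rec$execution$termination_status, "normal")
  # absent keys stay absent
  expect_null(rec$parameters$barostat)
  expect_null(rec$parameters$step_length)
  expect_null(rec$software)
  expect_null(rec$conditions$reference_temperature)
  expect_equal(rec$source_file$role, "output")
})

test_that("a missing footer is an incomplete run; malformed lines carry line numbers", {
  f <- write_tmp(c("%SIMDEX_MDOUT 1.0", "TASK_KIND = minimization"))
  expect_equal(parse_md_output(f)$execution$termination_status, "incomplete")

  bad <- write_tmp(c("%SIMDEX_MDOUT 1.0", "TASK_KIND = md", "this is not a key value line"))
  err <- expect_error(parse_md_output(bad), class = "simdex_parse_error")
  expect_match(conditionMessage(err), "line 3")

  expect_error(parse_md_output(write_tmp(c("%SIMDEX_MDOUT 1.0", "FOOTER: normal"))),
               class = "simdex_parse_error")
})

test_that("topology parsing yields occurrence counts and checks declared totals", {
  f <- write_tmp(c(
    "%SIMDEX_TOP 1.0",
    "%SECTION HEADER", "SYSTEM_NAME = solvated test",
    "%SECTION MOLECULE WAT", "KIND = solvent", "COUNT = 700",
    "N_RESIDUES = 1", "N_ATOMS = 3",
    "RESIDUE WAT 1", "ATOM H 2", "ATOM O 1"))
  sys <- parse_topology(f)
  wat <- sys$molecules[[1]]
  expect_equal(wat$count, 700L)
  expect_equal(wat$atoms$count[wat$atoms$element == "H"], 2L)
  expect_equal(wat$atoms$count[wat$atoms$element == "O"], 1L)
  expect_equal(sys$name, "solvated test")

  bad <- write_tmp(c(
    "%SIMDEX_TOP 1.0",
    "%SECTION MOLECULE WAT", "N_ATOMS = 4", "ATOM H 2", "ATOM O 1"))
  expect_error(parse_topology(bad), class = "simdex_parse_error")

  chain_mismatch <- write_tmp(c(
    "%SIMDEX_TOP 1.0",
    "%SECTION MOLECULE P1", "N_RESIDUES = 3", "CHAIN = ALA GLY",
    "RESIDUE ALA 2", "RESIDUE GLY 1"))
  expect_error(parse_topology(chain_mismatch), class = "simdex_parse_error")
})

test_that("QM output keeps specific names verbatim and decodes the executable", {
  f <- write_tmp(c("%SIMDEX_QMOUT 1.0", "METHOD = MP2", "BASIS_SET = LANL2DZ",
                   "SOFTWARE_NAME = Gaussian", "SOFTWARE_VERSION = 09",
                   "EXECUTABLE = EM64L-G09RevC.01", "FOOTER: normal"))
  rec <- parse_qm_output(f)
  expect_equal(rec$parameters$method, "MP2")
  expect_equal(rec$parameters$basis_set, "LANL2DZ")
  expect_equal(rec$build_info$revision, "C.01")
  # LANL2DZ is deliberately absent from the packaged basis-set dictionary:
  # the specific name must survive with no link
  expect_null(lookup_term(pkg_dicts()[["basis_set"]], "LANL2DZ"))
})

test_that("executable names parse into build info with graceful degradation", {
  g <- parse_executable_name("EM64L-G09RevC.01")
  expect_equal(g$revision, "C.01")
  expect_equal(g$target_architecture, "EM64L")
  expect_equal(g$product, "G09")

  s <- parse_executable_name("SANDER")
  expect_equal(s$product, "SANDER")
  expect_null(s$revision)

  m <- parse_executable_name("mystery-binary")
  expect_equal(m$raw, "mystery-binary")
  expect_null(m$product)
})

test_that("sequence normalization matches the residue dictionary and preserves length", {
  dicts <- pkg_dicts()
  expect_equal(normalize_sequence(c("ALA", "GLY", "SER"), dicts), "AGS")
  expect_equal(normalize_sequence(c("DA", "DT", "DG", "DC"), dicts), "ATGC")
  expect_equal(normalize_sequence(c("ALA", "LIGX"), dicts), "AX")
  expect_equal(normalize_sequence(c("WAT"), dicts), "X")  # no one-letter code

  # oracle: an independent read of the packaged CSV column
  raw <- read.csv(file.path(simdex_dictionary_dir(), "residue.csv"),
                  stringsAsFactors = FALSE, colClasses = "character")
  code_of <- stats::setNames(raw$ONE_LETTER_CODE, raw$TERM)
  set.seed(7)
  for (i in 1:25) {
    chain <- sample(c(raw$TERM, "FOO", "BAR"), sample(1:30, 1), replace = TRUE)
    expected <- paste(vapply(chain, function(r) {
      c_ <- code_of[r]
      if (is.na(c_) || !nzchar(c_)) "X" else c_
    }, character(1)), collapse = "")
    got <- normalize_sequence(chain, dicts)
    expect_equal(got, expected)
    expect_equal(nchar(got), length(chain))
  }
})
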