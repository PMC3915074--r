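test_that("variable description rank equals dataset shape rank", {
  d <- describe_variables(list(
    avg_rmsd = 1.27,
    rmsd_series = stats::rnorm(100),
    covariance = matrix(0, 30, 30)))
  dims_of <- function(nm) {
    v <- Filter(function(x) x$name == nm, d$variables)[[1]]
    v$dimensions
  }
  expect_length(dims_of("avg_rmsd"), 0)        # scalar
  expect_length(dims_of("rmsd_series"), 1)     # array
  expect_length(dims_of("covariance"), 2)      # matrix
  expect_equal(d$dimensions$rmsd_series_dim1, 100L)
  expect_equal(unlist(d$dimensions[dims_of("covariance")], use.names = FALSE),
               c(30L, 30L))

  set.seed(9)
  for (i in 1:30) {
    rank <- sample(0:3, 1)
    shape <- if (rank == 0) integer() else sample(1:6, rank)
    x <- if (rank == 0) stats::runif(1) else array(0, dim = shape)
    dd <- describe_variables(list(v = x))
    expect_length(dd$variables[[1]]$dimensions, rank)
  }

  expect_error(describe_variables(list(bad = list(1:3, 1:4))),
               class = "simdex_shape_error")
  expect_error(describe_variables(list(1, 2)), class = "simdex_usage_error")
})

test_that("provenance records require method and program", {
  p <- build_provenance("RMSD", "Root mean square deviation calculation",
                        program = "CPPTRAJ", version = "13.1",
                        command = "cpptraj -i rmsd.in",
                        timestamp = "2013-06-02T10:00:00Z", reference = "self")
  expect_equal(p$method_name, "RMSD")
  expect_equal(p$reference_system, "self")
  d <- analysis_descriptor(describe_variables(list(r = 1:10)), p)
  expect_null(d$filters$file_dependencies)  # filters optional by default
  expect_error(build_provenance("RMSD", program = ""), class = "simdex_usage_error")
})

test_that("currency compares whole seconds with ties current and unknowns propagated", {
  p <- build_provenance("RMSD", program = "CPPTRAJ")
  d <- analysis_descriptor(describe_variables(list(r = 1:10)), p,
                           file_dependencies = c("md.traj", "system.top"))
  t0 <- 1000000
  expect_equal(check_currency(d, t0, list(md.traj = t0 - 50, system.top = t0 - 10)),
               "current")
  expect_equal(check_currency(d, t0, list(md.traj = t0 + 5, system.top = t0 - 10)),
               "needs_update")
  expect_equal(check_currency(d, t0, list(md.traj = t0 - 50)), "unknown")
  expect_equal(check_currency(d, t0, list(md.traj = t0 + 0.4, system.top = t0)),
               "current")  # sub-second and exact ties

  # monotone: advancing a dependency never un-stales an analysis
  set.seed(13)
  for (i in 1:50) {
    ts <- list(md.traj = t0 + sample(-100:100, 1),
               system.top = t0 + sample(-100:100, 1))
    before <- check_currency(d, t0, ts)
    ts$md.traj <- ts$md.traj + sample(1:100, 1)
    after <- check_currency(d, t0, ts)
    if (before == "needs_update") expect_equal(after, "needs_update")
  }
})

test_that("descriptors round-trip through the JSON sidecar losslessly", {
  p <- build_provenance("RMSD", "Root mean square deviation calculation",
                        program = "CPPTRAJ", version = "13.1",
                        command = "cpptraj -i rmsd.in", inputs = "rmsd.in",
                        timestamp = "2013-06-02T10:00:00Z", reference = "self")
  d <- analysis_descriptor(
    describe_variables(list(avg = 1.5, series = 1:20)), p,
    file_dependencies = c("production.1.traj", "system.top"),
    time_filter = "frames 100-500",
    space_filter = "@CA,C,N", space_filter_program = "CPPTRAJ")
  f <- withr::local_tempfile(fileext = ".simdex.json")
  write_descriptor(d, f)
  back <- read_descriptor(f)
  expect_equal(back$dimensions, d$dimensions)
  expect_equal(back$provenance$method_name, d$provenance$method_name)
  expect_equal(back$provenance$command, d$provenance$command)
  expect_equal(back$filters$file_dependencies, d$filters$file_dependencies)
  expect_equal(back$filters$space_filter, d$filters$space_filter)
  expect_equal(length(back$variables), length(d$variables))
  expect_equal(back$variables[[2]]$dimensions, d$variables[[2]]$dimensions)
})
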