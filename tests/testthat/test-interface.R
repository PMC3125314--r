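cli_quiet <- function(argv) {
  status <- NULL
  suppressMessages(status <- run_cli(argv))
  status
}

test_that("validate subcommand exits 0 on a valid model, 2 on usage errors", {
  path <- system.file("extdata", "models", "srna.yaml", package = "robnet")
  expect_identical(cli_quiet(c("validate", path)), 0L)
  expect_identical(cli_quiet(character(0)), 2L)
  expect_identical(cli_quiet("frobnicate"), 2L)
  expect_identical(cli_quiet("simulate"), 2L) # --case is required
})

test_that("simulate subcommand writes an RFC-4180 CSV trajectory", {
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(out))
  expect_identical(cli_quiet(c("simulate", "--case", "srna", "--t1", "30",
                               "--x0", "2,0.1", "--out", out)), 0L)
  got <- utils::read.csv(out)
  expect_identical(names(got), c("t", "x1", "x2"))
  expect_equal(unname(as.numeric(got[nrow(got), c("x1", "x2")])),
               rep(golden_eq, 2), tolerance = 1e-5)
})

test_that("equilibria subcommand writes valid JSON with spectra", {
  out <- tempfile(fileext = ".json")
  on.exit(unlink(out))
  expect_identical(cli_quiet(c("equilibria", "--case", "srna",
                               "--starts", "40", "--seed", "3",
                               "--out", out)), 0L)
  obj <- jsonlite::read_json(out)
  expect_identical(obj$case, "srna")
  expect_identical(obj$seed, 3L)
  expect_length(obj$equilibria, 1)
  expect_equal(obj$equilibria[[1]]$x1, golden_eq, tolerance = 1e-6)
  expect_length(obj$eigenvalues[[1]]$re, 2)
})

test_that("certify subcommand reports a holding sRNA certificate", {
  out <- tempfile(fileext = ".json")
  on.exit(unlink(out))
  expect_identical(cli_quiet(c("certify", "--case", "srna", "--out", out)), 0L)
  obj <- jsonlite::read_json(out)
  expect_true(obj$holds)
  expect_equal(obj$estimated_rate, 1, tolerance = 1e-5)
})

test_that("suite subcommand logs per-claim verdicts and exits by outcome", {
  out <- tempfile(fileext = ".json")
  on.exit(unlink(out))
  expect_identical(cli_quiet(c("suite", "--name", "srna", "--ensemble", "2",
                               "--seed", "42", "--claims",
                               "positivity,unique-equilibrium",
                               "--out", out)), 0L)
  obj <- jsonlite::read_json(out)
  expect_identical(obj$seed, 42L)
  expect_length(obj$results, 2)
  expect_true(all(vapply(obj$results, function(r) r$robust, logical(1))))
})

test_that("the installed thin wrapper script exists and is an Rscript", {
  path <- system.file("cli", "robnet", package = "robnet")
  expect_true(nzchar(path))
  expect_match(readLines(path, n = 1), "Rscript")
})
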