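test_that("sample_instance is a pure function of (model, config, seed)", {
  m <- build_case("srna")$model
  a <- sample_instance(m, seed = 11L)
  b <- sample_instance(m, seed = 11L)
  c <- sample_instance(m, seed = 12L)
  expect_identical(instance_parameters(a), instance_parameters(b))
  expect_false(identical(instance_parameters(a), instance_parameters(c)))
})

test_that("coupled terms share the identical drawn function", {
  m <- build_case("srna")$model
  inst <- sample_instance(m, seed = 3L)
  expect_identical(inst$functions$b12[[1]]$parameters,
                   inst$functions$b21[[1]]$parameters)
  # and for the manually built MAPK default (phosphatase couplings)
  cs <- build_case("mapk")
  expect_identical(cs$default_instance$functions$c23[[1]]$parameters,
                   cs$default_instance$functions$g33[[1]]$parameters)
})

test_that("sampled instances respect their tags", {
  m <- build_case("camp")$model
  for (s in 1:3) {
    inst <- sample_instance(m, seed = s)
    v <- validate_instance(inst)
    expect_true(v$pass, info = paste("seed", s))
  }
})

test_that("sigmoidal draws never produce Hill exponent 1", {
  m <- build_case("arabinose")$model
  for (s in 1:10) {
    inst <- sample_instance(m, seed = s)
    expect_gte(inst$functions$c1u[[1]]$parameters$H, 2)
  }
})

test_that("ensembles are reproducible and member-independent", {
  m <- build_case("srna")$model
  e1 <- generate_ensemble(m, 4, seed = 9L)
  e2 <- generate_ensemble(m, 6, seed = 9L)
  # the first 4 members of the larger ensemble are the same instances
  for (i in 1:4) {
    expect_identical(instance_parameters(e1[[i]]), instance_parameters(e2[[i]]))
  }
})

test_that("manual_instance enforces tag agreement slot by slot", {
  m <- build_case("srna")$model
  fns <- robnet:::srna_functions(1, 1, 1, 1, 1)
  fns$c1 <- list(make_function("mm_saturating", list(V = 1, K = 1)))
  expect_error(manual_instance(m, fns), "does not match term tag")
  fns$c1 <- NULL
  expect_error(manual_instance(m, fns), "missing functions")
})

test_that("instance JSON round-trips exactly", {
  m <- build_case("lac")$model
  inst <- sample_instance(m, seed = 21L)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_instance_json(inst, path)
  back <- read_instance_json(m, path)
  expect_equal(instance_parameters(inst), instance_parameters(back))
  expect_error(read_instance_json(build_case("srna")$model, path),
               "is for model")
})

test_that("split_seed gives distinct sub-seeds without touching the RNG state", {
  seeds <- vapply(1:500, function(i) split_seed(42L, i), integer(1))
  expect_identical(anyDuplicated(seeds), 0L)
  set.seed(1); before <- .Random.seed
  invisible(sample_instance(build_case("srna")$model, seed = 5L))
  expect_identical(.Random.seed, before)
})
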