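test_that("all five case studies build with valid frozen defaults", {
  for (nm in c("arabinose", "srna", "camp", "lac", "mapk")) {
    cs <- build_case(nm)
    expect_s3_class(cs, "case_study")
    expect_true(validate_model(cs$model)$pass, info = nm)
    expect_true(validate_instance(cs$default_instance)$pass, info = nm)
  }
  expect_error(build_case("krebs"), "unknown case study")
})

test_that("packaged model YAML files reproduce the built-in structures", {
  dir <- system.file("extdata", "models", package = "robnet")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  expect_length(files, 5)
  pairs <- list(arabinose = build_case("arabinose")$model,
                srna = build_case("srna")$model,
                camp = build_case("camp")$model,
                lac = build_case("lac")$model,
                mapk = build_case("mapk")$model)
  for (nm in names(pairs)) {
    m <- read_model(file.path(dir, paste0(nm, ".yaml")))
    ref <- pairs[[nm]]
    expect_identical(m$states, ref$states, info = nm)
    expect_identical(names(m$terms), names(ref$terms), info = nm)
    for (lab in names(ref$terms)) {
      expect_identical(m$terms[[lab]]$tags, ref$terms[[lab]]$tags,
                       info = paste(nm, lab))
      expect_identical(m$terms[[lab]]$args, ref$terms[[lab]]$args,
                       info = paste(nm, lab))
      expect_identical(m$terms[[lab]]$kind, ref$terms[[lab]]$kind,
                       info = paste(nm, lab))
    }
  }
})

test_that("unknown tags in model YAML are named in the error", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c(
    "states:", "- x1",
    "terms:",
    "- target: x1", "  kind: c", "  args:", "  - x1",
    "  tags:", "  - super-increasing"
  ), path)
  expect_error(read_model(path), "super-increasing")
})

test_that("camp_xi is the monotone saturating G-protein map", {
  cs <- build_case("camp")
  inst <- cs$default_instance
  expect_identical(camp_xi(inst, 0), 0)
  expect_equal(camp_xi(inst, 1), 2 / 3, tolerance = 1e-9)
  us <- c(0.1, 1, 10, 1e4)
  xi <- vapply(us, function(u) camp_xi(inst, u), numeric(1))
  expect_true(all(diff(xi) > 0))
  expect_lt(xi[4], 2) # saturates below the activation threshold
})

test_that("the compliant cAMP default satisfies both conditions, the violator neither bound", {
  cs <- build_case("camp")
  chk <- camp_existence_check(cs$default_instance, u = 1)
  expect_true(chk$exists)
  tb <- camp_transient_bound(cs$default_instance, u = 1)
  expect_true(tb$condition_holds)
  expect_true(tb$verified)
  expect_equal(tb$bound, 0.1977, tolerance = 1e-3)

  bad <- camp_violating_case()
  tbv <- camp_transient_bound(bad$default_instance, u = 1)
  expect_false(tbv$condition_holds)
  expect_gt(tbv$peak, tb$bound) # the spike escapes the compliant-style bound
})

test_that("lac_scan shows the 1 -> 3 -> 1 bistability pattern", {
  cs <- build_case("lac")
  sc <- lac_scan(cs$default_instance, c(0.05, 1, 40), box = cs$box,
                 n_starts = 120, seed = 1L)
  expect_identical(sc$n_eq, c(1L, 3L, 1L))
  expect_identical(sc$pattern[2], "SUS")
  expect_true(all(sc$ordered))
})

test_that("mapk_scan counts equilibria per feedback family", {
  cs <- build_case("mapk")
  sc <- mapk_scan(cs, c(0.8), feedback = "constant", n_starts = 200, seed = 1L)
  expect_identical(sc$n_eq, 3L)
  expect_identical(sc$pattern, "SUS")
})

test_that("run_suite returns a tidy claim table and honours claim selection", {
  res <- run_suite("srna", n_ensemble = 2, seed = 42L,
                   claims = c("positivity", "unique-equilibrium"))
  expect_identical(nrow(res), 2L)
  expect_setequal(res$claim, c("positivity", "unique-equilibrium"))
  expect_true(all(res$robust))
  expect_identical(res$n_total, c(2L, 2L))
  # reproducibility
  res2 <- run_suite("srna", n_ensemble = 2, seed = 42L,
                    claims = c("positivity", "unique-equilibrium"))
  expect_identical(res, res2)
})
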