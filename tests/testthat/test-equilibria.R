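test_that("find_equilibria recovers the unique stable sRNA equilibrium", {
  cs <- srna_unit_case()
  eq <- find_equilibria(case_field(cs), c(2.4, 2.4), n_starts = 60, seed = 1L)
  expect_identical(nrow(eq), 1L)
  expect_identical(eq$class, "stable")
  expect_equal(unname(as.numeric(eq[1, c("x1", "x2")])), rep(golden_eq, 2),
               tolerance = 1e-9)
  expect_lt(eq$residual, 1e-9)
})

test_that("find_equilibria results are independent of the multistart seed", {
  cs <- build_case("lac")
  field <- case_field(cs)
  e1 <- find_equilibria(field, cs$box, n_starts = 150, seed = 1L)
  e2 <- find_equilibria(field, cs$box, n_starts = 150, seed = 99L)
  expect_identical(nrow(e1), nrow(e2))
  expect_equal(as.matrix(e1[, cs$model$states]),
               as.matrix(e2[, cs$model$states]), tolerance = 1e-6)
})

test_that("an empty equilibrium set is returned, not an error", {
  # constant production, degradation saturating below it: no equilibrium
  m <- network_model(
    states = "x1",
    terms = list(
      term("x1", "c", args = NA, tags = "positive-constant", label = "c1"),
      term("x1", "b", mult = "x1", args = "x1",
           tags = "increasing-asymptotically-constant",
           absorbed = TRUE, label = "g11")
    )
  )
  inst <- manual_instance(m, list(
    c1 = list(make_function("constant", list(c = 2))),
    g11 = list(make_function("mm_saturating", list(V = 1, K = 1)))
  ))
  field <- assemble_rhs(m, inst)
  eq <- find_equilibria(field, 50, n_starts = 40, seed = 1L)
  expect_identical(nrow(eq), 0L)
  expect_s3_class(eq, "robnet_equilibria")
})

test_that("classify rejects non-equilibria and reports eigenvalues", {
  cs <- srna_unit_case()
  field <- case_field(cs)
  expect_error(classify(field, c(1, 1)), "not an equilibrium")
  row <- classify(field, rep(golden_eq, 2))
  ev <- sort(Re(row$eigenvalues[[1]]))
  expect_equal(ev, c(-sqrt(5), -1), tolerance = 1e-6)
})

test_that("check_order detects componentwise ordering and its absence", {
  eq <- tibble::tibble(x1 = c(0.1, 1, 3), x2 = c(0.2, 1.5, 4),
                       residual = 0, class = c("stable", "unstable", "stable"),
                       eigenvalues = list(0, 0, 0))
  expect_true(check_order(eq)$ordered)
  eq2 <- eq; eq2$x2 <- c(4, 1.5, 0.2)
  expect_false(check_order(eq2)$ordered)
  expect_true(check_order(eq2, reversed = "x2")$ordered)
})

test_that("response_curve tracks branches and labels monotonicity", {
  cs <- build_case("arabinose")
  rc <- response_curve(cs$model, cs$default_instance, "u",
                       grid = c(0.2, 0.6, 1.5, 4), box = c(6, 6),
                       n_starts = 40, seed = 1L)
  expect_s3_class(rc, "robnet_response")
  expect_identical(nrow(rc), 4L)
  expect_true(all(rc$branch == 1))
  mono <- attr(rc, "monotonicity")
  expect_setequal(mono$direction, "increasing")
  expect_length(attr(rc, "folds"), 0)
})

test_that("tidy and glance summarise equilibrium sets", {
  cs <- build_case("lac")
  eq <- find_equilibria(case_field(cs), cs$box, n_starts = 150, seed = 1L)
  gl <- glance(eq)
  expect_identical(gl$n_equilibria, nrow(eq))
  expect_identical(gl$n_stable + gl$n_unstable + gl$n_marginal, nrow(eq))
  td <- tidy(eq)
  expect_identical(nrow(td), sum(lengths(eq$eigenvalues)))
  expect_true(all(c("re", "im", "class") %in% names(td)))
})
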