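test_that("assemble_rhs reproduces the closed-form sRNA field", {
  cs <- srna_unit_case()
  field <- case_field(cs)
  # dx1 = 1 - x1 - x1 x2 ; dx2 = 1 - x2 - x1 x2
  expect_equal(field$fn(0, c(1, 1)), c(-1, -1))
  expect_equal(field$fn(0, c(0, 0)), c(1, 1))
  expect_equal(field$fn(0, c(0.5, 2)), c(1 - 0.5 - 1, 1 - 2 - 1))
  X <- rbind(c(1, 1), c(0, 0), c(0.5, 2))
  expect_equal(field$fn_mat(X, 0), rbind(c(-1, -1), c(1, 1), c(-0.5, -2)))
})

test_that("assemble_rhs demands complete input bindings and a matching instance", {
  cs <- build_case("arabinose")
  expect_error(assemble_rhs(cs$model, cs$default_instance, list()),
               "unbound inputs: u")
  other <- build_case("lac")
  expect_error(assemble_rhs(cs$model, other$default_instance, list(u = 1)),
               "different model")
})

test_that("time-varying inputs are honoured", {
  cs <- build_case("arabinose")
  field <- assemble_rhs(cs$model, cs$default_instance, list(u = function(t) 1 + t))
  f0 <- field$fn(0, c(0, 0))
  f3 <- field$fn(3, c(0, 0))
  expect_gt(f3[1], f0[1]) # larger input, larger activation
})

test_that("simulate reaches steady state and flags it", {
  cs <- srna_unit_case()
  traj <- simulate(case_field(cs), c(2, 0.1), c(0, 60))
  expect_s3_class(traj, "robnet_trajectory")
  expect_true(attr(traj, "steady"))
  expect_equal(unname(as.numeric(traj[nrow(traj), c("x1", "x2")])),
               rep(golden_eq, 2), tolerance = 1e-6)
})

test_that("simulate enforces the positivity contract", {
  # a hand-built field that goes negative must be rejected
  bad <- structure(list(
    n = 1, state_names = "x1",
    fn = function(t, x) -1,
    fn_mat = function(X, t) matrix(-1, nrow(X), 1)
  ), class = "vector_field")
  expect_error(simulate(bad, 0.001, c(0, 1)), "positivity violated")
  expect_error(simulate(bad, -0.5, c(0, 1))) # negative initial state
})

test_that("invariant_box recovers the sRNA aggregate bound kappa = 2", {
  cs <- srna_unit_case()
  b <- invariant_box(cs$model, cs$default_instance)
  expect_identical(unname(attr(b, "sum_bound")), 2)
})

test_that("invariant_box bounds the arabinose cascade finitely", {
  cs <- build_case("arabinose")
  b <- invariant_box(cs$model, cs$default_instance, list(u = 1))
  expect_true(all(is.finite(b)))
  # x1 <= (c1 + c1u(u_max)) / b11 with c1u(1) = 0.5
  expect_equal(unname(b[1]), (0.25 + 0.5) / 1, tolerance = 1e-6)
  expect_lte(b[2], 0.5)
})

test_that("the cAMP activation thresholds bound the conserved actives", {
  cs <- build_case("camp")
  b <- invariant_box(cs$model, cs$default_instance, list(u = 5))
  expect_lte(b[["x1"]], 2) # theta of a1u
  expect_lte(b[["x2"]], 2) # theta of a23
})

test_that("detect_conserved_sums finds both MAPK moieties and nothing for sRNA", {
  mk <- build_case("mapk")
  cons <- detect_conserved_sums(mk$model, mk$default_instance, seed = 1L)
  expect_identical(nrow(cons), 2L)
  W <- as.matrix(cons[, mk$model$states])
  W <- W[order(apply(W, 1, function(r) which(r != 0)[1])), , drop = FALSE]
  expect_identical(unname(W[1, ]), c(0, 1, 1, 1, 0, 0, 0))
  expect_identical(unname(W[2, ]), c(0, 0, 0, 0, 1, 1, 1))
  # seed invariance of the weight set
  cons2 <- detect_conserved_sums(mk$model, mk$default_instance, seed = 77L)
  W2 <- as.matrix(cons2[, mk$model$states])
  W2 <- W2[order(apply(W2, 1, function(r) which(r != 0)[1])), , drop = FALSE]
  expect_identical(unname(W2), unname(W))

  sr <- srna_unit_case()
  expect_identical(nrow(detect_conserved_sums(sr$model, sr$default_instance)), 0L)
})

test_that("a degenerate zero field warns and returns all directions", {
  m <- network_model(
    states = "x1",
    terms = list(term("x1", "b", mult = "x1", args = NA,
                      tags = "nonnegative-constant"))
  )
  lab <- names(m$terms)[1]
  fns <- stats::setNames(list(list(make_function("constant", list(c = 0)))), lab)
  inst <- manual_instance(m, fns)
  expect_warning(cons <- detect_conserved_sums(m, inst), "zero field")
  expect_true(isTRUE(attr(cons, "degenerate")))
})

test_that("reduced fields agree with the full field on the conservation slice", {
  cs <- build_case("mapk")
  red <- mapk_reduced_field(cs)
  full <- case_field(cs)
  xr <- c(0.5, 0.3, 0.2, 0.4, 0.1)
  x_full <- red$embed(xr)
  expect_equal(sum(x_full[2:4]), 1.2, tolerance = 1e-12)
  fr <- red$fn(0, xr)
  ff <- full$fn(0, x_full)
  expect_equal(fr, ff[c(1, 2, 4, 5, 7)], tolerance = 1e-12)
})
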