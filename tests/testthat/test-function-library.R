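test_that("make_function returns evaluable families with analytic derivatives", {
  f <- make_function("hill_sigmoid", list(K = 1, H = 2))
  expect_s3_class(f, "parametric_fn")
  expect_equal(f$fn(1), 0.5)
  expect_equal(f$fn(0), 0)
  x <- c(0.2, 1, 3.7)
  expect_equal(f$deriv(x), f$num_deriv(x), tolerance = 1e-6)

  g <- make_function("mm_saturating", list(V = 2, K = 0.5))
  expect_equal(g$fn(0.5), 1)
  expect_equal(g$deriv(x), g$num_deriv(x), tolerance = 1e-6)

  h <- make_function("threshold_decreasing", list(A = 1, theta = 2))
  expect_equal(h$fn(0), 1)
  expect_identical(h$fn(2), 0)
  expect_identical(h$fn(5), 0)
  # C1 at the blend boundaries
  expect_equal(h$deriv(c(1.89, 1.91)), h$num_deriv(c(1.89, 1.91)), tolerance = 1e-5)
})

test_that("invalid parameters are rejected with informative errors", {
  expect_error(make_function("hill_sigmoid", list(K = -1)), "K must be > 0")
  expect_error(make_function("constant", list(c = -2)), "c must be >= 0")
  expect_error(make_function("linear_unbounded", list(slope = 0)), "slope")
  expect_error(make_function("nope", list()), "unknown function family")
})

test_that("natural tags depend on parameters (Hill exponent rule)", {
  expect_identical(make_function("hill_sigmoid", list(H = 2))$tag, "sigmoidal")
  expect_identical(make_function("hill_sigmoid", list(H = 1))$tag,
                   "increasing-asymptotically-constant")
  expect_identical(make_function("constant", list(c = 0))$tag, "nonnegative-constant")
  expect_identical(make_function("constant", list(c = 1))$tag, "positive-constant")
})

test_that("verify_property accepts matched pairs for all ten tags", {
  pairs <- list(
    list("constant", list(c = 0), "nonnegative-constant"),
    list("constant", list(c = 2), "positive-constant"),
    list("hill_sigmoid", list(K = 1, H = 3), "sigmoidal"),
    list("comp_hill", list(K = 1, H = 2), "complementary-sigmoidal"),
    list("constant_plus_hill", list(c = 0.1, K = 2, H = 2), "constant-sigmoidal"),
    list("constant_plus_comp_hill", list(c = 0.1, K = 2, H = 2),
         "constant-complementary-sigmoidal"),
    list("mm_saturating", list(V = 1, K = 0.3), "increasing-asymptotically-constant"),
    list("decreasing_null", list(A = 1, K = 0.3), "decreasing-asymptotically-null"),
    list("threshold_decreasing", list(A = 1, theta = 2), "decreasing-exactly-null"),
    list("linear_unbounded", list(slope = 0.5), "increasing-asymptotically-unbounded")
  )
  for (p in pairs) {
    f <- make_function(p[[1]], p[[2]], tag = p[[3]])
    v <- verify_property(f, p[[3]])
    expect_true(v$pass, info = p[[3]])
  }
})

test_that("verify_property works on bare functions via numeric derivatives", {
  v <- verify_property(function(x) x / (1 + x), "increasing-asymptotically-constant")
  expect_true(v$pass)
  v2 <- verify_property(function(x) x^2 / (1 + x^2), "sigmoidal")
  expect_true(v2$pass)
})
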