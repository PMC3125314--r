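test_that("pwl_norm evaluates the weighted 1-norm and enumerates pieces", {
  V <- pwl_norm(c(1, 2), weights = c(1, 3))
  expect_equal(V$value(c(1, 2)), 0)
  expect_equal(V$value(c(2, 0)), 1 + 6)
  expect_identical(nrow(V$pieces), 4L)
  X <- rbind(c(0, 0), c(1, 3))
  expect_equal(V$value(X), c(7, 3))
})

test_that("the sRNA decrease certificate holds with the analytic rate", {
  cs <- srna_unit_case()
  field <- case_field(cs)
  V <- pwl_norm(rep(golden_eq, 2))
  rep <- decrease_certificate(field, V, c(2, 2), n_samples = 4000, seed = 1L)
  expect_true(rep$holds)
  # dV/dt = -V exactly along both coordinates for the unit system
  expect_equal(rep$estimated_rate, 1, tolerance = 1e-6)
  expect_lt(rep$worst_margin, 0)
})

test_that("decrease certificates refuse a non-equilibrium center", {
  cs <- srna_unit_case()
  V <- pwl_norm(c(1, 1))
  expect_error(decrease_certificate(case_field(cs), V, c(2, 2)),
               "not an equilibrium")
})

test_that("enlarging n_samples never flips a certificate from failing to holding", {
  # an outward-spiralling field fails the decrease condition at the origin norm
  spiral <- structure(list(
    n = 2, state_names = c("x1", "x2"),
    fn = function(t, x) c(0.2 * x[1] - x[2], x[1] + 0.2 * x[2]),
    fn_mat = function(X, t) cbind(0.2 * X[, 1] - X[, 2], X[, 1] + 0.2 * X[, 2])
  ), class = "vector_field")
  V <- pwl_norm(c(0, 0))
  region <- rbind(c(-1, -1), c(1, 1))
  small <- decrease_certificate(spiral, V, region, n_samples = 500, seed = 5L)
  expect_false(small$holds)
  for (n in c(1000, 4000, 16000)) {
    big <- decrease_certificate(spiral, V, region, n_samples = n, seed = 5L)
    expect_false(big$holds)
    expect_gte(big$worst_margin, small$worst_margin)
  }
})

test_that("the orthant passes Nagumo sampling for packaged cases", {
  for (nm in c("srna", "camp")) {
    cs <- build_case(nm)
    field <- case_field(cs)
    rep <- nagumo_certificate(field, orthant_set(field$n), cs$box,
                              n_boundary = 500, seed = 1L)
    expect_true(rep$holds, info = nm)
  }
})

test_that("a genuinely exited set is caught by the Nagumo sampler", {
  cs <- srna_unit_case()
  field <- case_field(cs)
  # x1 <= 0.1 is not invariant: production pushes through that face
  cons <- constraint_set(list(
    list(w = c(1, 0), sigma = 0.1, label = "x1<=0.1"),
    list(w = c(-1, 0), sigma = 0, label = "x1>=0"),
    list(w = c(0, 1), sigma = 2, label = "x2<=2"),
    list(w = c(0, -1), sigma = 0, label = "x2>=0")
  ))
  rep <- nagumo_certificate(field, cons, c(0.1, 2), n_boundary = 400, seed = 1L)
  expect_false(rep$holds)
  expect_identical(rep$details$worst_constraint, "x1<=0.1")
  expect_true(is.matrix(rep$witnesses))
})

test_that("nonlinear constraints are projected by bisection", {
  cs <- srna_unit_case()
  field <- case_field(cs)
  # the disc of radius 2 about the equilibrium contains [0, kappa]^2 corners
  ctr <- rep(golden_eq, 2)
  cons <- constraint_set(list(
    list(fn = function(X) sqrt(rowSums(sweep(X, 2, ctr)^2)), sigma = 2,
         label = "disc"),
    list(w = c(-1, 0), sigma = 0, label = "x1>=0"),
    list(w = c(0, -1), sigma = 0, label = "x2>=0")
  ))
  rep <- nagumo_certificate(field, cons, c(3, 3), n_boundary = 300, seed = 1L)
  expect_true(rep$holds)
})

test_that("sector invariance holds about the sRNA equilibrium and is sound", {
  cs <- srna_unit_case()
  field <- case_field(cs)
  xs <- rep(golden_eq, 2)
  rep <- sector_certificate(field, xs, c(">=", "<="), rbind(c(0, 0), c(2, 2)),
                            n_boundary = 400, seed = 1L)
  expect_true(rep$holds)
  expect_identical(rep$kind, "sector-invariance")
  # soundness: start inside the sector, never leave it
  traj <- simulate(field, c(1.5, 0.2), c(0, 30))
  expect_true(all(traj$x1 >= xs[1] - 1e-6))
  expect_true(all(traj$x2 <= xs[2] + 1e-6))
})

test_that("crossing_count and decay_rate summarise trajectories", {
  cs <- srna_unit_case()
  field <- case_field(cs)
  xs <- rep(golden_eq, 2)
  traj <- simulate(field, c(2, 2), c(0, 30))
  cr <- crossing_count(traj, xs, dead_band = 1e-6)
  expect_true(all(cr <= 1))
  V <- pwl_norm(xs)
  dr <- decay_rate(V$value(as.matrix(traj[, c("x1", "x2")])), traj$t)
  expect_gte(dr$rate, 0.9)
  expect_null(dr$warning)
  # non-monotone series are flagged
  up <- decay_rate(c(1, 0.5, 0.9, 0.4, 0.2), 0:4)
  expect_match(up$warning, "not monotonically decreasing")
  expect_identical(decay_rate(rep(2, 5), 0:4)$rate, 0)
})

test_that("certificate reports tidy into one-row tibbles", {
  cs <- srna_unit_case()
  rep <- nagumo_certificate(case_field(cs), orthant_set(2), c(2, 2),
                            n_boundary = 200, seed = 1L)
  td <- tidy(rep)
  expect_identical(nrow(td), 1L)
  expect_true(td$holds)
  expect_identical(td$kind, "nagumo-invariance")
})
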