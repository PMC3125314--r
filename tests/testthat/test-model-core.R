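test_that("terms validate their structure at construction", {
  expect_s3_class(term("x1", "c", args = "u", tags = "sigmoidal"), "network_term")
  expect_error(term("x1", "a", args = NA, tags = "positive-constant"),
               "need a `mult`")
  expect_error(term("x1", "c", args = c("u", "v"), tags = "sigmoidal"),
               "one tag per argument")
  expect_error(term("x1", "c", args = "u", tags = "wiggly"), "wiggly")
  expect_error(term("x1", "c", args = "u", tags = "sigmoidal", absorbed = TRUE),
               "only for b terms")
})

test_that("all packaged models pass structural validation", {
  for (nm in c("arabinose", "srna", "camp", "lac", "mapk")) {
    v <- validate_model(build_case(nm)$model)
    expect_true(v$pass, info = nm)
    expect_true(all(v$report$ok), info = nm)
  }
})

test_that("validate_model distinguishes structural errors from assumption violations", {
  m_struct <- network_model(
    states = "x1",
    terms = list(term("x1", "b", mult = "ghost", args = NA,
                      tags = "positive-constant"))
  )
  v <- validate_model(m_struct)
  expect_false(v$pass)
  expect_true(v$report$structural[1])
  expect_match(unlist(v$report$violations), "unknown mult")

  # a d-kind production with a non-decreasing tag breaks the monotonicity rule
  m_a4 <- network_model(
    states = "x1",
    terms = list(
      term("x1", "d", args = "x1", tags = "increasing-asymptotically-constant"),
      term("x1", "b", mult = "x1", args = NA, tags = "positive-constant")
    )
  )
  v2 <- validate_model(m_a4)
  expect_false(v2$pass)
  expect_false(v2$report$structural[1])
  expect_match(unlist(v2$report$violations), "A4")

  # off-target degradation without the null-at-zero flag
  m_a5 <- network_model(
    states = c("x1", "x2"),
    terms = list(
      term("x1", "c", args = NA, tags = "positive-constant"),
      term("x1", "b", mult = "x2", args = "x1",
           tags = "increasing-asymptotically-unbounded"),
      term("x2", "c", args = NA, tags = "positive-constant"),
      term("x2", "b", mult = "x2", args = NA, tags = "positive-constant")
    )
  )
  v3 <- validate_model(m_a5)
  expect_false(v3$pass)
  expect_match(unlist(v3$report$violations), "A5")
})

test_that("orphan states fail validation", {
  m <- network_model(
    states = c("x1", "x2"),
    terms = list(term("x1", "b", mult = "x1", args = NA,
                      tags = "positive-constant"))
  )
  v <- validate_model(m)
  expect_false(v$pass)
  expect_identical(v$orphan_states, "x2")
})

test_that("duplicate term labels are rejected", {
  expect_error(network_model(
    states = "x1",
    terms = list(
      term("x1", "c", args = NA, tags = "positive-constant", label = "c1"),
      term("x1", "b", mult = "x1", args = NA, tags = "positive-constant",
           label = "c1")
    )
  ), "duplicate term labels")
})

test_that("the typed graph exposes term arcs and modulators", {
  g <- build_graph(build_case("arabinose")$model)
  expect_true(igraph::is_directed(g))
  expect_setequal(igraph::V(g)$name, c("x1", "x2", "u"))
  ed <- graph_edges(build_case("arabinose")$model)
  # the two-argument c2u1 term contributes a solid arc plus a dashed modulator
  expect_true(any(ed$term == "c2u1" & ed$dashed))
  # constant production (args all NA) contributes no arc
  expect_false(any(ed$term == "c1"))
})

test_that("MAPK conserved-pool metadata lands in graph vertex attributes", {
  g <- build_graph(build_case("mapk")$model)
  agg <- igraph::V(g)$aggregate
  names(agg) <- igraph::V(g)$name
  expect_identical(unname(agg[c("x2", "x3", "x4")]), rep("MEK total", 3))
  expect_true(is.na(agg[["x1"]]))
})
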