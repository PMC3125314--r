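#' Packaged case-study networks
#'
#' Five qualitative network models from the gene-regulation and signaling
#' literature, each with its property-tagged term structure, a frozen default
#' instance, an invariant sampling box and a set of robustness claims:
#'
#' * `arabinose` — two-gene feedforward loop: a transcription factor with
#'   basal production, activated by an external inducer, driving an output
#'   gene that needs both the factor and the inducer (Hill activation).
#' * `srna` — small-RNA silencing: target mRNA and sRNA produced at constant
#'   rates, each linearly degraded, and removed jointly by stoichiometric
#'   complex formation (mass action, shared rate).
#' * `camp` — cyclic-AMP signaling: receptor-activated G protein (exact
#'   activation threshold from mass conservation), kinase activated by cAMP,
#'   and cAMP produced by the G protein and removed by
#'   phosphodiesterase-mediated feedback with saturating kinetics.
#' * `lac` — reduced 3-state lactose-operon model: permease mRNA/protein and
#'   internal inducer, with basal-plus-cooperative production and competing
#'   saturating import/consumption terms; bistable at intermediate external
#'   inducer.
#' * `mapk` — three-tier phosphorylation cascade (7 species) with saturating
#'   (de)phosphorylation kinetics, two conserved totals, and a positive
#'   feedback of strength `mu` from the doubly phosphorylated output onto
#'   the top-tier kinase; the feedback coefficient may be constant, bounded
#'   increasing, or unbounded increasing in the top-tier kinase itself
#'   (autocatalysis).
#'
#' @param name one of `"arabinose"`, `"srna"`, `"camp"`, `"lac"`, `"mapk"`.
#' @param ... case-specific options: for `mapk`, `feedback` (one of
#'   `"constant"`, `"bounded_increasing"`, `"unbounded_increasing"`) and
#'   `mu` (feedback strength of the default instance).
#' @return an object of class `case_study`: `$model`, `$default_instance`,
#'   `$inputs` (default bindings), `$box` (root-finding bounds), `$claims`
#'   (claim descriptors for [run_suite()]) and case metadata.
#' @examples
#' cs <- build_case("srna")
#' length(cs$model$terms) # 6
#' @export
build_case <- function(name, ...) {
  switch(name,
    arabinose = case_arabinose(),
    srna = case_srna(),
    camp = case_camp(),
    lac = case_lac(),
    mapk = case_mapk(...),
    stop("unknown case study: ", name, call. = FALSE)
  )
}

case_names <- function() c("arabinose", "srna", "camp", "lac", "mapk")

new_case <- function(name, model, functions, inputs = list(), box, extra = list()) {
  inst <- manual_instance(model, functions)
  structure(
    c(list(name = name, model = model, default_instance = inst,
           inputs = inputs, box = box, claims = case_claims(name)),
      extra),
    class = "case_study"
  )
}

#' @export
print.case_study <- function(x, ...) {
  cat("<case_study>", x$name, "-", length(x$model$states), "states,",
      length(x$model$terms), "terms\n")
  invisible(x)
}

cfn <- function(family, ...) make_function(family, list(...))

# ---- L-arabinose feedforward loop -----------------------------------------

case_arabinose <- function() {
  model <- network_model(
    name = "arabinose",
    states = c("x1", "x2"),
    inputs = "u",
    terms = list(
      term("x1", "c", args = NA, tags = "positive-constant", label = "c1"),
      term("x1", "c", args = "u", tags = "sigmoidal", label = "c1u"),
      term("x1", "b", mult = "x1", args = NA, tags = "positive-constant", label = "b11"),
      term("x2", "c", args = c("u", "x1"),
           tags = c("sigmoidal", "increasing-asymptotically-constant"), label = "c2u1"),
      term("x2", "b", mult = "x2", args = NA, tags = "positive-constant", label = "b22")
    ),
    notes = "Feedforward activation cascade; hierarchical, hence iteratively solvable."
  )
  functions <- list(
    c1 = list(cfn("constant", c = 0.25)),
    c1u = list(cfn("hill_sigmoid", K = 1, H = 2, A = 1)),
    b11 = list(cfn("constant", c = 1)),
    c2u1 = list(cfn("hill_sigmoid", K = 1, H = 2, A = 1),
                cfn("mm_saturating", V = 1, K = 0.5)),
    b22 = list(cfn("constant", c = 1))
  )
  new_case("arabinose", model, functions, inputs = list(u = 1),
           box = c(5, 5))
}

# ---- sRNA silencing --------------------------------------------------------

case_srna <- function(c1 = 1, c2 = 1, b11 = 1, b22 = 1, k = 1) {
  model <- srna_model()
  functions <- srna_functions(c1, c2, b11, b22, k)
  new_case("srna", model, functions, inputs = list(),
           box = c(3, 3),
           extra = list(parameters = list(c1 = c1, c2 = c2, b11 = b11,
                                          b22 = b22, k = k)))
}

srna_model <- function() {
  network_model(
    name = "srna",
    states = c("x1", "x2"),
    terms = list(
      term("x1", "c", args = NA, tags = "positive-constant", label = "c1"),
      term("x1", "b", mult = "x1", args = NA, tags = "positive-constant", label = "b11"),
      term("x1", "b", mult = "x2", args = "x1",
           tags = "increasing-asymptotically-unbounded",
           coupling = "k", a5 = TRUE, label = "b12"),
      term("x2", "c", args = NA, tags = "positive-constant", label = "c2"),
      term("x2", "b", mult = "x2", args = NA, tags = "positive-constant", label = "b22"),
      term("x2", "b", mult = "x1", args = "x2",
           tags = "increasing-asymptotically-unbounded",
           coupling = "k", a5 = TRUE, label = "b21")
    ),
    notes = "Stoichiometric mutual degradation; the coupled terms share the binding rate."
  )
}

srna_functions <- function(c1, c2, b11, b22, k) {
  kf <- cfn("linear_unbounded", slope = k)
  list(
    c1 = list(cfn("constant", c = c1)),
    b11 = list(cfn("constant", c = b11)),
    b12 = list(kf),
    c2 = list(cfn("constant", c = c2)),
    b22 = list(cfn("constant", c = b22)),
    b21 = list(kf)
  )
}

#' The unit-parameter sRNA instance
#'
#' All rates equal to one; its equilibrium is the positive root of
#' `1 - x - x^2 = 0` in each coordinate, a convenient closed-form anchor.
#' @return a `case_study`.
#' @export
srna_unit_case <- function() case_srna(1, 1, 1, 1, 1)

# ---- cAMP signaling --------------------------------------------------------

camp_model <- function() {
  network_model(
    name = "camp",
    states = c("x1", "x2", "x3"),
    inputs = "u",
    terms = list(
      term("x1", "a", mult = "u", args = "x1",
           tags = "decreasing-exactly-null", label = "a1u"),
      term("x1", "b", mult = "x1", args = NA, tags = "positive-constant", label = "b11"),
      term("x2", "a", mult = "x3", args = "x2",
           tags = "decreasing-exactly-null", label = "a23"),
      term("x2", "b", mult = "x2", args = NA, tags = "positive-constant", label = "b22"),
      term("x3", "d", args = "x2", tags = "decreasing-asymptotically-null", label = "d32"),
      term("x3", "a", mult = "x1", args = "x2",
           tags = "decreasing-asymptotically-null", label = "a31"),
      term("x3", "b", mult = "x2", args = "x3",
           tags = "increasing-asymptotically-constant", a5 = TRUE, label = "b32"),
      term("x3", "b", mult = "x3", args = "x3",
           tags = "increasing-asymptotically-constant", absorbed = TRUE, label = "g33")
    ),
    notes = paste("Activation terms vanish exactly at the total-amount thresholds,",
                  "so the actives stay below their totals (mass conservation).")
  )
}

case_camp <- function(compliant = TRUE) {
  model <- camp_model()
  functions <- if (compliant) {
    list(
      a1u = list(cfn("threshold_decreasing", A = 1, theta = 2)),
      b11 = list(cfn("constant", c = 1)),
      a23 = list(cfn("threshold_decreasing", A = 0.5, theta = 2)),
      b22 = list(cfn("constant", c = 1)),
      d32 = list(cfn("decreasing_null", A = 0.3, K = 1)),
      a31 = list(cfn("decreasing_null", A = 0.4, K = 1)),
      b32 = list(cfn("mm_saturating", V = 1, K = 0.5)),
      g33 = list(cfn("mm_saturating", V = 2, K = 0.5))
    )
  } else {
    # removal ceiling of cAMP deliberately below the zero-kinase production:
    # the transient spike is then unchecked by the self-removal route.
    list(
      a1u = list(cfn("threshold_decreasing", A = 1, theta = 2)),
      b11 = list(cfn("constant", c = 1)),
      a23 = list(cfn("threshold_decreasing", A = 0.05, theta = 2)),
      b22 = list(cfn("constant", c = 1)),
      d32 = list(cfn("decreasing_null", A = 1.5, K = 0.2)),
      a31 = list(cfn("decreasing_null", A = 2, K = 0.2)),
      b32 = list(cfn("mm_saturating", V = 1, K = 0.5)),
      g33 = list(cfn("mm_saturating", V = 0.3, K = 0.5))
    )
  }
  new_case("camp", model, functions, inputs = list(u = 1),
           box = c(2, 2, 10),
           extra = list(compliant = compliant))
}

#' The packaged cAMP instance violating the spike-domination condition
#'
#' Its cAMP self-removal ceiling is below the production seen at low kinase
#' activity, so the transient spike escapes the bound that holds for the
#' compliant default.
#' @return a `case_study`.
#' @export
camp_violating_case <- function() case_camp(compliant = FALSE)

# ---- lac operon (reduced 3-state) -----------------------------------------

lac_model <- function() {
  network_model(
    name = "lac",
    states = c("x1", "x2", "x3"),
    inputs = "u",
    terms = list(
      term("x1", "c", args = "x3", tags = "constant-sigmoidal", label = "c13"),
      term("x1", "b", mult = "x1", args = NA, tags = "positive-constant", label = "b11"),
      term("x2", "a", mult = "x1", args = NA, tags = "positive-constant", label = "a21"),
      term("x2", "b", mult = "x2", args = NA, tags = "positive-constant", label = "b22"),
      term("x3", "a", mult = "x2", args = "u",
           tags = "increasing-asymptotically-constant", label = "a32"),
      term("x3", "b", mult = "x2", args = "x3",
           tags = "increasing-asymptotically-constant", a5 = TRUE, label = "b32"),
      term("x3", "b", mult = "x3", args = NA, tags = "positive-constant", label = "b33")
    ),
    notes = paste("Reduced model: the enzyme readout is slaved to the inducer",
                  "equilibrium and tracked separately; the linear external-inducer",
                  "inflow is neglected.")
  )
}

case_lac <- function() {
  model <- lac_model()
  functions <- list(
    c13 = list(cfn("constant_plus_hill", c = 0.1, A = 20, K = 2, H = 2)),
    b11 = list(cfn("constant", c = 1)),
    a21 = list(cfn("constant", c = 1)),
    b22 = list(cfn("constant", c = 1)),
    a32 = list(cfn("mm_saturating", V = 1, K = 1)),
    b32 = list(cfn("mm_saturating", V = 0.3, K = 1)),
    b33 = list(cfn("constant", c = 1))
  )
  new_case("lac", model, functions, inputs = list(u = 1),
           box = c(25, 25, 25),
           extra = list(
             slaved_readout = paste("enzyme concentration x4 follows",
                                    "gamma * f1(x3*) / delta4 once x3 settles"),
             u_bistable = 1
           ))
}

# ---- MAPK cascade ----------------------------------------------------------

mapk_model <- function(feedback = "constant") {
  fb_tag <- switch(feedback,
    constant = "nonnegative-constant",
    bounded_increasing = "increasing-asymptotically-constant",
    unbounded_increasing = "increasing-asymptotically-unbounded",
    stop("unknown feedback family: ", feedback, call. = FALSE)
  )
  mm_tag <- "increasing-asymptotically-constant"
  network_model(
    name = paste0("mapk-", feedback),
    states = paste0("x", 1:7),
    terms = list(
      term("x1", "c", args = NA, tags = "positive-constant", label = "c10"),
      term("x1", "a", mult = "x7", args = "x1", tags = fb_tag, label = "a17"),
      term("x1", "b", mult = "x1", args = "x1", tags = mm_tag,
           absorbed = TRUE, label = "g11"),
      # tier 2: x2 -> x3 -> x4, kinase x1, saturating phosphatases
      term("x2", "c", args = "x3", tags = mm_tag, coupling = "g33", label = "c23"),
      term("x2", "b", mult = "x1", args = "x2", tags = mm_tag,
           a5 = TRUE, coupling = "phos2", label = "b21"),
      term("x3", "a", mult = "x1", args = "x2", tags = mm_tag,
           coupling = "phos2", label = "a31"),
      term("x3", "c", args = "x4", tags = mm_tag, coupling = "g44", label = "c34"),
      term("x3", "b", mult = "x1", args = "x3", tags = mm_tag,
           a5 = TRUE, coupling = "phos3", label = "b31"),
      term("x3", "b", mult = "x3", args = "x3", tags = mm_tag,
           absorbed = TRUE, coupling = "g33", label = "g33"),
      term("x4", "a", mult = "x1", args = "x3", tags = mm_tag,
           coupling = "phos3", label = "a41"),
      term("x4", "b", mult = "x4", args = "x4", tags = mm_tag,
           absorbed = TRUE, coupling = "g44", label = "g44"),
      # tier 3: x5 -> x6 -> x7, kinase x4
      term("x5", "c", args = "x6", tags = mm_tag, coupling = "g66", label = "c56"),
      term("x5", "b", mult = "x4", args = "x5", tags = mm_tag,
           a5 = TRUE, coupling = "phos5", label = "b54"),
      term("x6", "a", mult = "x4", args = "x5", tags = mm_tag,
           coupling = "phos5", label = "a64"),
      term("x6", "c", args = "x7", tags = mm_tag, coupling = "g77", label = "c67"),
      term("x6", "b", mult = "x4", args = "x6", tags = mm_tag,
           a5 = TRUE, coupling = "phos6", label = "b64"),
      term("x6", "b", mult = "x6", args = "x6", tags = mm_tag,
           absorbed = TRUE, coupling = "g66", label = "g66"),
      term("x7", "a", mult = "x4", args = "x6", tags = mm_tag,
           coupling = "phos6", label = "a74"),
      term("x7", "b", mult = "x7", args = "x7", tags = mm_tag,
           absorbed = TRUE, coupling = "g77", label = "g77")
    ),
    conserved = list(
      list(states = c("x2", "x3", "x4"), label = "MEK total"),
      list(states = c("x5", "x6", "x7"), label = "MAPK total")
    ),
    notes = paste("Positive feedback strength mu lives in the a17 amplitude;",
                  "the basal drive must stay below the top-tier removal ceiling",
                  "or no equilibrium is possible.")
  )
}

mapk_feedback_fn <- function(feedback, mu) {
  switch(feedback,
    constant = make_function("constant", list(c = mu), tag = "nonnegative-constant"),
    bounded_increasing = make_function("mm_saturating", list(V = max(mu, 1e-12), K = 0.5)),
    unbounded_increasing = cfn("linear_unbounded", slope = max(mu, 1e-12))
  )
}

mapk_functions <- function(feedback = "constant", mu = 1) {
  phos2 <- cfn("mm_saturating", V = 1, K = 0.1)
  phos3 <- cfn("mm_saturating", V = 1, K = 0.1)
  g33 <- cfn("mm_saturating", V = 0.3, K = 0.1)
  g44 <- cfn("mm_saturating", V = 0.3, K = 0.1)
  phos5 <- cfn("mm_saturating", V = 1, K = 0.1)
  phos6 <- cfn("mm_saturating", V = 1, K = 0.1)
  g66 <- cfn("mm_saturating", V = 0.3, K = 0.1)
  g77 <- cfn("mm_saturating", V = 0.3, K = 0.1)
  list(
    c10 = list(cfn("constant", c = 0.1)),
    a17 = list(mapk_feedback_fn(feedback, mu)),
    g11 = list(cfn("mm_saturating", V = 2.5, K = 1)),
    c23 = list(g33), b21 = list(phos2), a31 = list(phos2),
    c34 = list(g44), b31 = list(phos3), g33 = list(g33),
    a41 = list(phos3), g44 = list(g44),
    c56 = list(g66), b54 = list(phos5), a64 = list(phos5),
    c67 = list(g77), b64 = list(phos6), g66 = list(g66),
    a74 = list(phos6), g77 = list(g77)
  )
}

case_mapk <- function(feedback = "constant", mu = 1, k = 1.2, h = 1.2) {
  model <- mapk_model(feedback)
  functions <- mapk_functions(feedback, mu)
  new_case("mapk", model, functions, inputs = list(),
           box = c(6, k, k, k, h, h, h),
           extra = list(
             feedback = feedback, mu = mu, totals = c(k = k, h = h),
             mu_window = c(0.5, 0.8, 1, 1.2),
             reduced_dim = 5,
             existence_note = paste("the basal drive c10 must be below the",
                                    "top-tier removal ceiling sup b11(x1)x1")
           ))
}

#' Reduced vector field of a MAPK case (conserved states eliminated)
#'
#' Drops the singly phosphorylated species of each tier using the conserved
#' totals, leaving the 5 coordinates `(x1, x2, x4, x5, x7)`.
#'
#' @param case a MAPK `case_study`.
#' @param instance optional instance override (default: the case default).
#' @return a `vector_field` of dimension 5.
#' @export
mapk_reduced_field <- function(case, instance = NULL) {
  instance <- instance %||% case$default_instance
  full <- assemble_rhs(instance$model, instance, case$inputs)
  reduced_vector_field(full, list(
    list(drop = "x3", members = c("x2", "x3", "x4"), total = case$totals[["k"]]),
    list(drop = "x6", members = c("x5", "x6", "x7"), total = case$totals[["h"]])
  ))
}

mapk_reduced_box <- function(case, x1_cap = 6) {
  k <- case$totals[["k"]]; h <- case$totals[["h"]]
  rbind(rep(0, 5), c(x1_cap, k, k, h, h))
}
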