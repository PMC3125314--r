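---
title: "Structural robustness of qualitative biomolecular networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural robustness of qualitative biomolecular networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robnet)
```

## The question robnet answers

A dynamical property of a biomolecular circuit is *structurally robust* when
it holds for every system in a family sharing the same qualitative
interaction structure, regardless of parameter values. robnet turns that
definition into a computation in three moves:

1. write the model as tagged terms, not formulas;
2. instantiate the tags with concrete random functions, many times, across
   decades of parameter scales;
3. verify the property numerically on every instance with deterministic,
   seeded procedures.

A claim that survives the whole ensemble is evidence for structure-driven
behavior; a single failing instance is a counterexample, and the report
records it.

## Model form

A model (`network_model()`) is a set of nonnegative states with terms
(`term()`) of four kinds contributing to each state's derivative:

- `a`: a production coefficient multiplying a source species,
- `b`: a degradation/conversion coefficient multiplying a species (signed
  negatively),
- `c`: a saturating production term,
- `d`: a decreasing production term.

Each term's scalar coefficient is a product of unary functions, one per
entry of `args`; a constant factor is an arg-less slot. Multi-species
dependence is therefore expressed as a product of tagged unary factors,
which is what the qualitative theory characterizes.

Two structural flags need explanation:

- `a5`: a `b` term that degrades a species *other* than the one its
  coefficient reads must have a coefficient that vanishes when the target is
  zero, or positivity could fail. `validate_model()` enforces the flag, and
  `validate_instance()` spot-checks the identity numerically.
- `absorbed`: for saturating self-degradation, the qualitatively
  characterized object is the whole product `g(x) = b(x)·x` (increasing,
  saturating, null at zero), not the bare coefficient. Absorbed terms store
  `g` directly and contribute `-g(x)`.

## The ten property tags

`property_tags` enumerates the vocabulary: nonnegative and positive
constants; sigmoidal (zero value and slope at the origin, finite positive
limit, derivative with a unique maximum); complementary sigmoidal; both with
constant offsets; increasing asymptotically constant (saturating);
decreasing asymptotically null; decreasing *exactly* null above a finite
threshold (the signature of mass conservation: an activation coefficient
that vanishes once the active fraction exhausts the total); and increasing
unbounded (mass action).

`verify_property()` checks any function against any tag on a logarithmic
grid: sign, monotonicity, origin value and slope, two-probe limits a decade
apart, and derivative shape via sign changes of second differences with a
dead band. Violations are named predicates (`"f'(0)=0"`,
`"finite-positive-limit"`, ...), so a mis-tagged function fails for the
stated reason, not just somewhere.

## Function families and sampling

`make_function()` provides nine parametric families covering the tags: Hill
sigmoids and their complements (exponent rule: a Hill function with exponent
1 has a *positive* slope at zero and is therefore tagged saturating, not
sigmoidal — the sampler never draws exponent 1 for sigmoidal slots),
constant offsets of both, Michaelis–Menten saturation, a decreasing
hyperbola, a C1-smoothed affine threshold decline that is exactly null above
its threshold, constants, and linear functions. All carry analytic
derivatives; a central-difference fallback exists for bare functions.

`sampling_config()` defaults draw amplitudes, velocities and slopes
log-uniformly over `[1e-2, 1e2]`, thresholds over the same range, and Hill
exponents uniformly over `{2, 3, 4}` where zero origin slope is required.
Log-uniform sampling is deliberate: structural claims are about *scale-free*
behavior, so each decade of parameter space gets equal weight. Coupled terms
(same `coupling` label) receive the identical draw — stoichiometric removal
and phosphorylation/conversion pairs must share their rate function or the
model changes meaning. Instance generation is a pure function of
`(model, config, seed)` via counter-based seed splitting, and ensemble
members are independent: adding draws for one never perturbs another.

## Certificates

All certificates are *sampled* checks with seeded, nested streams: the
first `k` points of a stream are a prefix of the first `k' > k`, so raising
a density parameter can only add evidence. A certificate that fails at some
density can therefore never be rescued by sampling harder, which is the
soundness direction that matters; a holding certificate remains a
finite-sample statement, and the packaged densities were chosen so that
deliberately broken inputs (non-invariant sets, spiraling fields) are caught
reliably.

- **Lyapunov decrease** (`decrease_certificate()`): candidates are
  max-of-affine functions; the preset `pwl_norm()` is the weighted 1-norm
  about an equilibrium, whose pieces are all sign combinations. The
  generalized derivative at a sample is the maximum over active pieces of
  `gradient · f(x)`; the certificate requires it negative away from an
  exclusion ball (default relative radius `1e-3`, default 20000 samples)
  and reports the certified exponential rate `min(-D/V)`.
- **Nagumo invariance** (`nagumo_certificate()`): for a set
  `{x : s_i(x) <= sigma_i}`, samples each constraint's boundary (projection
  for linear constraints, bisection toward an interior point otherwise,
  default 2000 points per constraint), keeps points satisfying the other
  constraints, and requires the outward derivative non-positive up to a
  field-scaled slack. `sector_certificate()` specializes to axis-aligned
  order cones about an equilibrium: a holding pair of sector certificates is
  overshoot-free monotone convergence.
- **Trajectory summaries**: `crossing_count()` (per-coordinate equilibrium
  crossings outside a dead band; no-oscillation means at most one) and
  `decay_rate()` (log-linear fit of a Lyapunov series over the window above
  `1e-8` of its initial value, flagging non-monotonicity).

## Equilibria

`find_equilibria()` runs damped Newton iterations from a half-Halton,
half-seeded set of multistarts (default 200) in a finite box, deduplicates
within a merge radius, polishes, and classifies by the eigenvalues of a
central-difference Jacobian with a `1e-6` marginality dead band. An empty
result is a legitimate outcome: regimes without equilibria exist (strong
feedback in the MAPK cascade below). `response_curve()` re-solves along an
input grid and tracks branches by nearest neighbor, recording fold points
where branch counts change rather than failing. `check_order()` tests
componentwise ordering, with a `reversed` argument for cascade species that
move opposite to the active forms.

`invariant_box()` derives per-state upper bounds by the saturation
argument — bounded production ceiling over linear degradation floor,
propagated through the dependency order — plus the threshold rule: a state
whose every production carries an exactly-null-above-threshold factor in
that state is bounded by the largest threshold. For models without
cross-species production coefficients it also derives an aggregate bound on
the total concentration. `detect_conserved_sums()` finds conserved moieties
numerically (left null space of stacked right-hand sides, rationalized to
small integer weights and re-verified), independent of the sampling seed.

## The five case studies

Each case freezes a default instance whose parameters were chosen once, by
hand, to sit comfortably inside the qualitative regime the claim describes —
they are study conditions, not tuned outcomes.

- **arabinose**: a two-gene feedforward loop (inducer-activated factor,
  output needing factor and inducer). Hierarchical, hence a unique stable
  equilibrium, monotone in the input.
- **srna**: mRNA and small RNA with constant production, linear decay, and
  shared-rate stoichiometric mutual removal. Structurally: a unique stable
  equilibrium, a 1-norm Lyapunov function with decay rate at least
  `min(b11, b22)`, sector invariance (no over/undershoot), and a monotone
  equilibrium shift under transcription steps. The unit-parameter instance
  (`srna_unit_case()`) anchors everything in closed form: equilibrium
  `(sqrt(5)-1)/2` in both coordinates, eigenvalues `-1` and `-sqrt(5)`,
  total-concentration bound 2.
- **camp**: receptor-driven G protein and cAMP-activated kinase, both with
  exact conservation thresholds, and cAMP produced by the G protein,
  inhibited by the kinase, and removed by saturating routes. The key
  threshold structure: equilibria exist iff production at kinase saturation
  drops below the removal ceiling (`camp_existence_check()`), and when the
  self-removal ceiling dominates zero-kinase production, the transient
  spike is capped by an explicitly computable level
  (`camp_transient_bound()`). `camp_violating_case()` packages an instance
  breaking that condition, whose spike escapes the cap by two orders of
  magnitude.
- **lac**: a reduced three-state operon (mRNA, permease, internal inducer)
  with basal-plus-cooperative transcription and competing saturating
  import/consumption. Bistable at intermediate external inducer: branch
  counts 1 → 3 → 1 along the inducer scan, stable/unstable/stable and
  componentwise ordered at the three-equilibrium point.
- **mapk**: a three-tier, seven-species phosphorylation cascade with
  saturating kinetics, two conserved totals, and positive feedback of
  strength `mu` from the output onto top-tier activation. The feedback
  coefficient's qualitative class decides everything: constant feedback
  yields a bistable `mu`-window (S/U/S) and *no* equilibria at extreme
  `mu` (production outruns the bounded removal); linear unbounded feedback
  (autocatalysis) yields an even number of equilibria — typically two, one
  stable, one unstable — wherever any exist. Analysis runs on the reduced
  5-dimensional coordinates (`mapk_reduced_field()`), discarding roots that
  imply negative eliminated species.

`run_suite()` evaluates each case's claims over a seeded ensemble
(ensemble-scoped claims must hold for every member; frozen multistability
witnesses run on the default instance) and returns a tidy verdict table.
The MAPK ensemble constrains one sampled quantity for admissibility: the
basal drive is resampled to a fraction of the top-tier removal ceiling,
because an open cascade whose drive exceeds that ceiling has no equilibrium
to analyze.

## Limitations

- Certificates are sampled, not interval-verified: a holding report is
  strong evidence at the stated density, not a proof. The failing direction
  is exact in spirit — a found witness is a genuine counterexample up to
  residual tolerance.
- Root finding is multistart-based; the packaged start counts were sized on
  the case studies (200 starts resolve the 5-dimensional reduced cascade
  reliably; fewer occasionally miss the middle branch).
- `invariant_box()` is conservative by construction and returns `Inf` where
  no bound is derivable (e.g. states with unbounded net production), in
  which case downstream equilibrium searches need an explicit cap.
- The smoothed threshold family is C1 but not C2 at its blend boundary;
  derivative-shape checks use dead-banded second differences for exactly
  this reason.
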