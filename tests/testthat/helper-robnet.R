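# Shared helpers for the robnet test suite.

# Closed-form positive root of 1 - x - x^2 = 0 (unit sRNA equilibrium).
golden_eq <- (sqrt(5) - 1) / 2

# Assemble the field of a case study's default instance with its default
# input bindings.
case_field <- function(case) {
  assemble_rhs(case$model, case$default_instance, case$inputs)
}

# Minimum state value over a batch of seeded simulations.
min_over_sims <- function(field, his, n_ic, seed, t_max = 10, atol = 1e-8) {
  worst <- Inf
  for (j in seq_len(n_ic)) {
    x0 <- with_seed_test(split_seed(seed, j), stats::runif(length(his), 0, his))
    traj <- simulate(field, x0, c(0, t_max), rtol = 1e-6, atol = atol,
                     n_out = 51, check_positive = FALSE)
    worst <- min(worst, min(as.matrix(traj[, -1])))
  }
  worst
}

# Local copy of the package's seed-preserving evaluation (not exported).
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
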