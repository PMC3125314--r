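# Case-specific operations: steady-state maps, existence conditions,
# transient bounds, bifurcation scans, and the ensemble claim suites.

fn_sup <- function(f) {
  # upper saturation value of a bounded non-decreasing function
  f$fn(1e9 * max(f$scale, 1))
}

inst_fn <- function(instance, term, slot = 1) instance$functions[[term]][[slot]]
inst_const <- function(instance, term) inst_fn(instance, term)$fn(0)

#' Steady-state active G-protein level of the cAMP case
#'
#' Solves the scalar balance `a1u(x1) * u = b11 * x1` by monotone bisection:
#' the left side is non-increasing in `x1` (exactly null at the conservation
#' threshold), the right side increasing, so the solution is unique for every
#' `u >= 0`, increasing in `u`, and saturates at the threshold.
#'
#' @param instance a cAMP `concrete_instance`.
#' @param u glucose input (>= 0).
#' @return the steady-state level `xi(u)`.
#' @export
camp_xi <- function(instance, u) {
  stopifnot(u >= 0)
  if (u == 0) return(0)
  f <- inst_fn(instance, "a1u")
  b11 <- inst_const(instance, "b11")
  theta <- f$parameters$theta %||% (10 * f$scale)
  g <- function(x) f$fn(x) * u - b11 * x
  lo <- 0; hi <- theta
  while (g(hi) > 0) hi <- hi * 2 # only if the activation never vanishes
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Equilibrium-existence condition for the cAMP case
#'
#' An equilibrium exists iff the kinase-saturated production of cAMP drops
#' below the saturating-removal ceiling: with `xi = ` [camp_xi()],
#' `d32(th2) + a31(th2) * xi(u) < b32(inf) * th2 + g33(inf)`, where `th2` is
#' the kinase conservation threshold. The flag is monotone in `u` (once
#' false, it stays false), because `xi` is increasing.
#'
#' @inheritParams camp_xi
#' @return list with `exists`, `margin` (removal ceiling minus production),
#'   `xi`.
#' @export
camp_existence_check <- function(instance, u) {
  xi <- camp_xi(instance, u)
  th2 <- inst_fn(instance, "a23")$parameters$theta
  lhs <- inst_fn(instance, "d32")$fn(th2) + inst_fn(instance, "a31")$fn(th2) * xi
  rhs <- fn_sup(inst_fn(instance, "b32")) * th2 + fn_sup(inst_fn(instance, "g33"))
  list(exists = lhs < rhs, margin = rhs - lhs, xi = xi)
}

#' Transient bound on the cAMP spike
#'
#' With the G protein at its steady state, cAMP production is largest at zero
#' kinase activity: `r(u) = d32(0) + a31(0) * xi(u)`. When the self-removal
#' ceiling dominates (`g33(inf) > r(u)`), the level
#' `kappa(u) = g33^{-1}(r(u))` cannot be crossed from below, giving the
#' transient bound `x3(t) <= max(x3(0), kappa(u))`, an increasing function of
#' `u`. When the condition fails the spike is unchecked by this route and no
#' bound is asserted.
#'
#' @inheritParams camp_xi
#' @param x0 initial `(x1, x2, x3)`; `x1` is reset to `xi(u)` (the bound's
#'   standing assumption).
#' @param t_max simulation horizon for verification.
#' @return list with `bound` (`Inf` if the condition fails), `condition_holds`,
#'   `verified` (simulated spike stayed below the bound; `NA` when no bound),
#'   `peak` (observed max of `x3`), `xi`.
#' @export
camp_transient_bound <- function(instance, u, x0 = c(0, 0, 0), t_max = 120) {
  xi <- camp_xi(instance, u)
  r <- inst_fn(instance, "d32")$fn(0) + inst_fn(instance, "a31")$fn(0) * xi
  g33 <- inst_fn(instance, "g33")
  ceiling33 <- fn_sup(g33)
  condition <- ceiling33 > r
  bound <- if (condition) max(x0[3], inverse_increasing(g33$fn, r)) else Inf
  field <- assemble_rhs(instance$model, instance, list(u = u))
  x0[1] <- xi
  traj <- simulate(field, x0, c(0, t_max), rtol = 1e-8, atol = 1e-10)
  peak <- max(traj$x3)
  list(
    bound = bound,
    condition_holds = condition,
    verified = if (condition) peak <= bound * (1 + 1e-6) + 1e-9 else NA,
    peak = peak,
    xi = xi
  )
}

inverse_increasing <- function(fn, y, lo = 0, hi = 1) {
  while (fn(hi) < y) {
    hi <- hi * 2
    if (hi > 1e12) return(Inf)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (fn(mid) < y) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Equilibrium count and stability scan of the lac case over the inducer
#'
#' Multistart root finding at each external-inducer level; reports counts,
#' the stability pattern (sorted by the mRNA coordinate), and componentwise
#' ordering where several equilibria coexist. The hallmark of the case is a
#' 1 -> 3 -> 1 branch-count pattern with stable/unstable/stable classes in
#' the window.
#'
#' @param instance a lac `concrete_instance`.
#' @param u_grid increasing inducer grid.
#' @param box root-finding bounds.
#' @param n_starts,seed multistart configuration.
#' @return tibble with `u`, `n_eq`, `n_stable`, `pattern` (e.g. `"SUS"`),
#'   `ordered`; attribute `equilibria` holds the per-u tables.
#' @export
lac_scan <- function(instance, u_grid, box = c(25, 25, 25),
                     n_starts = 120, seed = 1L) {
  eqs <- purrr::map(u_grid, function(u) {
    field <- assemble_rhs(instance$model, instance, list(u = u))
    find_equilibria(field, box, n_starts = n_starts, seed = seed)
  })
  out <- purrr::map2_dfr(u_grid, eqs, function(u, eq) {
    simple <- eq[eq$class != "marginal", , drop = FALSE]
    tibble::tibble(
      u = u,
      n_eq = nrow(simple),
      n_stable = sum(simple$class == "stable"),
      pattern = paste(substr(toupper(simple$class), 1, 1), collapse = ""),
      ordered = if (nrow(simple) >= 2) check_order(simple)$ordered else TRUE
    )
  })
  attr(out, "equilibria") <- eqs
  out
}

#' Equilibrium count and stability scan of the MAPK cascade over the
#' feedback strength
#'
#' For each `mu`, rebuilds the feedback term in the requested qualitative
#' family (constant coefficient; bounded increasing in the top-tier kinase;
#' or unbounded increasing, i.e. autocatalytic), reduces the cascade by its
#' two conserved totals, and counts equilibria by multistart root finding on
#' the reduced 5-dimensional simplex box. Roots implying negative eliminated
#' species are discarded.
#'
#' @param case a MAPK `case_study` (supplies kinetics and totals).
#' @param mu_grid nonnegative feedback strengths.
#' @param feedback one of `"constant"`, `"bounded_increasing"`,
#'   `"unbounded_increasing"`.
#' @param n_starts,seed multistart configuration.
#' @param x1_cap cap on the (structurally unbounded) top-tier coordinate.
#' @return tibble with `mu`, `n_eq`, `n_stable`, `pattern`; attribute
#'   `equilibria`.
#' @export
mapk_scan <- function(case, mu_grid, feedback = case$feedback,
                      n_starts = 200, seed = 1L, x1_cap = 6) {
  model_v <- mapk_model(feedback)
  k <- case$totals[["k"]]; h <- case$totals[["h"]]
  box <- mapk_reduced_box(case, x1_cap)
  eqs <- purrr::map(mu_grid, function(mu) {
    fns <- case$default_instance$functions
    fns$a17 <- list(mapk_feedback_fn(feedback, mu))
    inst <- manual_instance(model_v, fns)
    red <- mapk_reduced_field(case, inst)
    eq <- find_equilibria(red, box, n_starts = n_starts, seed = seed)
    mapk_filter_simplex(eq, case)
  })
  out <- purrr::map2_dfr(mu_grid, eqs, function(mu, eq) {
    simple <- eq[eq$class != "marginal", , drop = FALSE]
    tibble::tibble(
      mu = mu,
      n_eq = nrow(simple),
      n_stable = sum(simple$class == "stable"),
      pattern = paste(substr(toupper(simple$class), 1, 1), collapse = "")
    )
  })
  attr(out, "equilibria") <- eqs
  out
}

# Discard reduced-coordinate roots implying negative eliminated species.
mapk_filter_simplex <- function(eq, case, tol = 1e-7) {
  if (!nrow(eq)) return(eq)
  k <- case$totals[["k"]]; h <- case$totals[["h"]]
  ok <- (eq$x2 + eq$x4 <= k + tol) & (eq$x5 + eq$x7 <= h + tol)
  eq[ok, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Claim suites

srna_params <- function(instance) {
  list(
    c1 = inst_const(instance, "c1"), c2 = inst_const(instance, "c2"),
    b11 = inst_const(instance, "b11"), b22 = inst_const(instance, "b22"),
    k = inst_fn(instance, "b12")$parameters$slope
  )
}

srna_kappa <- function(instance) {
  p <- srna_params(instance)
  (p$c1 + p$c2) / min(p$b11, p$b22)
}

claim <- function(id, scope, fun) list(id = id, scope = scope, fun = fun)

rand_x0 <- function(hi, seed) with_seed(seed, stats::runif(length(hi), 0, hi))

sim_box <- function(case, instance, cap = 10) {
  b <- invariant_box(case$model, instance, case$inputs)
  ifelse(is.finite(b), b, cap)
}

positivity_claim <- claim("positivity", "ensemble", function(instance, case, seed, opts) {
  n_ic <- opts$n_ic %||% 3
  atol <- 1e-8
  field <- assemble_rhs(case$model, instance, case$inputs)
  hi <- sim_box(case, instance)
  worst <- Inf
  for (i in seq_len(n_ic)) {
    x0 <- rand_x0(hi, split_seed(seed, 7000L + i))
    traj <- try(simulate(field, x0, c(0, opts$t_max %||% 10), rtol = 1e-6,
                         atol = atol, n_out = 101, check_positive = FALSE),
                silent = TRUE)
    if (inherits(traj, "try-error")) return(list(pass = FALSE, details = "integration failed"))
    worst <- min(worst, min(trajectory_states(traj)))
  }
  list(pass = worst >= -10 * atol, details = list(min_state = worst))
})

case_claims <- function(name) {
  common <- list(positivity_claim)
  specific <- switch(name,
    srna = list(
      claim("unique-equilibrium", "ensemble", function(instance, case, seed, opts) {
        kap <- srna_kappa(instance)
        field <- assemble_rhs(instance$model, instance, list())
        eq <- find_equilibria(field, rep(1.2 * kap, 2),
                              n_starts = opts$n_starts %||% 60, seed = seed)
        list(pass = nrow(eq) == 1 && eq$class[1] == "stable",
             details = list(n_eq = nrow(eq)))
      }),
      claim("lyapunov-decrease", "ensemble", function(instance, case, seed, opts) {
        p <- srna_params(instance)
        beta <- min(p$b11, p$b22)
        kap <- srna_kappa(instance)
        field <- assemble_rhs(instance$model, instance, list())
        eq <- find_equilibria(field, rep(1.2 * kap, 2), n_starts = 40, seed = seed)
        if (nrow(eq) != 1) return(list(pass = FALSE, details = "no unique equilibrium"))
        xs <- as.numeric(eq[1, instance$model$states])
        V <- pwl_norm(xs)
        rep <- decrease_certificate(field, V, rep(kap, 2),
                                    n_samples = opts$n_samples %||% 2000,
                                    seed = seed)
        list(pass = isTRUE(rep$holds) && rep$estimated_rate >= 0.9 * beta,
             details = list(rate = rep$estimated_rate, beta = beta))
      }),
      claim("exponential-decay", "ensemble", function(instance, case, seed, opts) {
        p <- srna_params(instance)
        beta <- min(p$b11, p$b22)
        kap <- srna_kappa(instance)
        field <- assemble_rhs(instance$model, instance, list())
        eq <- find_equilibria(field, rep(1.2 * kap, 2), n_starts = 40, seed = seed)
        if (nrow(eq) != 1) return(list(pass = FALSE, details = "no unique equilibrium"))
        xs <- as.numeric(eq[1, instance$model$states])
        V <- pwl_norm(xs)
        x0 <- rand_x0(rep(kap, 2), split_seed(seed, 11L))
        traj <- simulate(field, x0, c(0, 12 / beta))
        rate <- decay_rate(V$value(trajectory_states(traj)), traj$t)$rate
        list(pass = rate >= 0.9 * beta, details = list(rate = rate, beta = beta))
      }),
      claim("no-oscillation", "ensemble", function(instance, case, seed, opts) {
        p <- srna_params(instance)
        beta <- min(p$b11, p$b22)
        kap <- srna_kappa(instance)
        field <- assemble_rhs(instance$model, instance, list())
        eq <- find_equilibria(field, rep(1.2 * kap, 2), n_starts = 40, seed = seed)
        if (nrow(eq) != 1) return(list(pass = FALSE, details = "no unique equilibrium"))
        xs <- as.numeric(eq[1, instance$model$states])
        ok <- TRUE
        for (i in 1:2) {
          x0 <- rand_x0(rep(kap, 2), split_seed(seed, 20L + i))
          traj <- simulate(field, x0, c(0, 12 / beta))
          cr <- crossing_count(traj, xs, dead_band = 1e-6 * (1 + max(xs)))
          ok <- ok && all(cr <= 1)
        }
        list(pass = ok, details = NULL)
      }),
      claim("sector-invariance", "ensemble", function(instance, case, seed, opts) {
        kap <- srna_kappa(instance)
        field <- assemble_rhs(instance$model, instance, list())
        eq <- find_equilibria(field, rep(1.2 * kap, 2), n_starts = 40, seed = seed)
        if (nrow(eq) != 1) return(list(pass = FALSE, details = "no unique equilibrium"))
        xs <- as.numeric(eq[1, instance$model$states])
        box <- rbind(c(0, 0), rep(1.2 * kap, 2))
        r1 <- sector_certificate(field, xs, c(">=", "<="), box,
                                 n_boundary = opts$n_boundary %||% 400, seed = seed)
        r2 <- sector_certificate(field, xs, c("<=", ">="), box,
                                 n_boundary = opts$n_boundary %||% 400, seed = seed)
        list(pass = isTRUE(r1$holds) && isTRUE(r2$holds), details = NULL)
      }),
      claim("transcription-step-monotone", "ensemble", function(instance, case, seed, opts) {
        p <- srna_params(instance)
        beta <- min(p$b11, p$b22)
        kap0 <- srna_kappa(instance)
        field <- assemble_rhs(instance$model, instance, list())
        eq0 <- find_equilibria(field, rep(1.2 * kap0, 2), n_starts = 40, seed = seed)
        if (nrow(eq0) != 1) return(list(pass = FALSE, details = "no unique equilibrium"))
        x_old <- as.numeric(eq0[1, instance$model$states])
        inst2 <- instance
        inst2$functions$c2 <- list(make_function("constant", list(c = 2 * p$c2)))
        field2 <- assemble_rhs(inst2$model, inst2, list())
        kap2 <- srna_kappa(inst2)
        eq2 <- find_equilibria(field2, rep(1.2 * kap2, 2), n_starts = 40, seed = seed)
        if (nrow(eq2) != 1) return(list(pass = FALSE, details = "no unique new equilibrium"))
        x_new <- as.numeric(eq2[1, instance$model$states])
        mono <- x_new[1] < x_old[1] && x_new[2] > x_old[2]
        traj <- simulate(field2, x_old, c(0, 12 / beta))
        cr <- crossing_count(traj, x_new, dead_band = 1e-6 * (1 + max(x_new)))
        list(pass = mono && all(cr == 0),
             details = list(x_old = x_old, x_new = x_new, crossings = cr))
      })
    ),
    arabinose = list(
      claim("unique-stable-equilibrium", "ensemble", function(instance, case, seed, opts) {
        hi <- sim_box(case, instance)
        field <- assemble_rhs(case$model, instance, case$inputs)
        eq <- find_equilibria(field, 1.2 * hi + 0.1,
                              n_starts = opts$n_starts %||% 60, seed = seed)
        list(pass = nrow(eq) == 1 && eq$class[1] == "stable",
             details = list(n_eq = nrow(eq)))
      }),
      claim("monotone-in-input", "ensemble", function(instance, case, seed, opts) {
        K <- inst_fn(instance, "c1u")$parameters$K
        grid <- K * c(0.2, 0.6, 1.5, 4)
        # bound the box at the largest swept input, or roots fall outside
        hi <- invariant_box(case$model, instance, list(u = max(grid)))
        rc <- response_curve(case$model, instance, "u", grid, 1.5 * hi + 0.2,
                             n_starts = 40, seed = seed)
        ok <- nrow(rc) == length(grid) &&
          all(diff(rc$x1) >= -1e-6 * (1 + max(rc$x1))) &&
          all(diff(rc$x2) >= -1e-6 * (1 + max(rc$x2)))
        list(pass = ok, details = rc)
      })
    ),
    camp = list(
      claim("existence-agreement", "ensemble", function(instance, case, seed, opts) {
        chk <- camp_existence_check(instance, u = 1)
        rel <- abs(chk$margin) / (1e-12 + abs(chk$margin) +
                                    fn_sup(inst_fn(instance, "g33")))
        if (rel < 0.02) return(list(pass = NA, details = "margin too close to call"))
        th1 <- inst_fn(instance, "a1u")$parameters$theta
        th2 <- inst_fn(instance, "a23")$parameters$theta
        x3cap <- if (chk$exists) {
          3 * inverse_increasing(inst_fn(instance, "g33")$fn,
                                 min(0.999 * fn_sup(inst_fn(instance, "g33")),
                                     inst_fn(instance, "d32")$fn(0) +
                                       inst_fn(instance, "a31")$fn(0) * chk$xi)) + 10
        } else 100 * max(inst_fn(instance, "g33")$scale, 1)
        field <- assemble_rhs(case$model, instance, list(u = 1))
        eq <- find_equilibria(field, c(1.2 * th1, 1.2 * th2, x3cap),
                              n_starts = opts$n_starts %||% 150, seed = seed)
        # the cap is derived from the saturating self-removal alone; when the
        # cross-species removal route carries the balance the root can lie
        # above it, so widen the box before concluding non-existence
        tries <- 0
        while (chk$exists && nrow(eq) == 0 && tries < 3) {
          x3cap <- 4 * x3cap
          eq <- find_equilibria(field, c(1.2 * th1, 1.2 * th2, x3cap),
                                n_starts = opts$n_starts %||% 150, seed = seed)
          tries <- tries + 1
        }
        list(pass = (nrow(eq) > 0) == chk$exists,
             details = list(exists = chk$exists, n_eq = nrow(eq)))
      }),
      claim("gprotein-map-monotone", "ensemble", function(instance, case, seed, opts) {
        us <- c(0.1, 0.5, 1, 5, 20)
        xi <- vapply(us, function(u) camp_xi(instance, u), numeric(1))
        # saturation probe scaled to the instance (slow activation needs
        # larger inputs before the threshold is approached)
        f1 <- inst_fn(instance, "a1u")
        U <- 1e6 * max(1, inst_const(instance, "b11") * f1$parameters$theta /
                            f1$fn(0))
        sat <- abs(camp_xi(instance, U) - camp_xi(instance, 10 * U)) <
          1e-3 * (1 + camp_xi(instance, 10 * U))
        list(pass = all(diff(xi) >= -1e-12) && sat, details = list(xi = xi))
      }),
      claim("transient-bound", "default", function(instance, case, seed, opts) {
        n_x0 <- opts$n_x0 %||% 10
        ok <- TRUE
        for (i in seq_len(n_x0)) {
          x0 <- rand_x0(c(2, 2, 0.2), split_seed(seed, 300L + i))
          tb <- camp_transient_bound(instance, u = 1, x0 = x0)
          if (!isTRUE(tb$condition_holds) || !isTRUE(tb$verified)) ok <- FALSE
        }
        list(pass = ok, details = NULL)
      }),
      claim("equilibrium-monotone-in-input", "default", function(instance, case, seed, opts) {
        grid <- c(0.3, 1, 3, 10)
        rc <- response_curve(case$model, instance, "u", grid, c(3, 3, 10),
                             n_starts = 60, seed = seed)
        mono <- attr(rc, "monotonicity")
        list(pass = nrow(rc) == length(grid) &&
               all(mono$direction %in% c("increasing", "flat")),
             details = mono)
      })
    ),
    lac = list(
      claim("bounded-evolution", "ensemble", function(instance, case, seed, opts) {
        hi <- invariant_box(case$model, instance, case$inputs)
        if (!all(is.finite(hi))) return(list(pass = FALSE, details = "unbounded box"))
        field <- assemble_rhs(case$model, instance, case$inputs)
        x0 <- rand_x0(hi, split_seed(seed, 5L))
        traj <- simulate(field, x0, c(0, 10), rtol = 1e-6, atol = 1e-8, n_out = 101)
        ok <- all(t(trajectory_states(traj)) <= pmax(x0, hi) * (1 + 1e-6) + 1e-7)
        list(pass = ok, details = list(box = hi))
      }),
      claim("branch-pattern", "default", function(instance, case, seed, opts) {
        grid <- c(0.05, 0.2, 1, 8, 40)
        sc <- lac_scan(instance, grid, box = case$box,
                       n_starts = opts$n_starts %||% 120, seed = seed)
        counts <- sc$n_eq
        ok <- counts[1] == 1 && counts[length(counts)] == 1 && any(counts == 3)
        list(pass = ok, details = sc)
      }),
      claim("three-equilibria-structure", "default", function(instance, case, seed, opts) {
        sc <- lac_scan(instance, case$u_bistable, box = case$box,
                       n_starts = opts$n_starts %||% 150, seed = seed)
        eq <- attr(sc, "equilibria")[[1]]
        simple <- eq[eq$class != "marginal", ]
        ok <- nrow(simple) == 3 &&
          identical(simple$class, c("stable", "unstable", "stable")) &&
          check_order(simple)$ordered
        list(pass = ok, details = simple)
      }),
      claim("no-overshoot-from-below", "default", function(instance, case, seed, opts) {
        sc <- lac_scan(instance, case$u_bistable, box = case$box,
                       n_starts = 150, seed = seed)
        eq <- attr(sc, "equilibria")[[1]]
        if (nrow(eq) < 3) return(list(pass = FALSE, details = "expected three equilibria"))
        xA <- as.numeric(eq[1, case$model$states])
        field <- assemble_rhs(case$model, instance, case$inputs)
        ok <- TRUE
        for (i in 1:5) {
          x0 <- with_seed(split_seed(seed, 40L + i), stats::runif(3, 0, 1)) * xA
          traj <- simulate(field, x0, c(0, 60))
          cr <- crossing_count(traj, xA, dead_band = 1e-6 * (1 + max(xA)))
          over <- max(sweep(trajectory_states(traj), 2, xA, "-"))
          ok <- ok && all(cr == 0) && over <= 1e-6 * (1 + max(xA))
        }
        list(pass = ok, details = NULL)
      })
    ),
    mapk = list(
      claim("conserved-totals", "ensemble", function(instance, case, seed, opts) {
        field <- assemble_rhs(case$model, instance, list())
        x0 <- rand_x0(rep(1, 7), split_seed(seed, 60L))
        traj <- simulate(field, x0, c(0, 20))
        S <- trajectory_states(traj)
        s1 <- S[, 2] + S[, 3] + S[, 4]
        s2 <- S[, 5] + S[, 6] + S[, 7]
        drift <- max(abs(s1 - s1[1]) / s1[1], abs(s2 - s2[1]) / s2[1])
        list(pass = drift < 1e-6, details = list(drift = drift))
      }),
      claim("open-loop-unique-stable", "ensemble", function(instance, case, seed, opts) {
        fns <- instance$functions
        fns$a17 <- list(make_function("constant", list(c = 0)))
        inst0 <- manual_instance(mapk_model("constant"), fns)
        red <- mapk_reduced_field(case, inst0)
        # open loop: the top tier settles where its removal balances the
        # basal drive, which fixes the scale of the search box
        x1_star <- inverse_increasing(inst_fn(inst0, "g11")$fn,
                                      inst_const(inst0, "c10"))
        box <- mapk_reduced_box(case, 2 * x1_star + 1)
        # weak tier-to-tier coupling puts the equilibrium within 1e-6 of the
        # simplex boundary, where random multistarts cannot land: seed one
        # deterministic start from a long simulation of the reduced field
        traj <- simulate(red, box[2, ] / 3, c(0, 500), n_out = 2,
                         check_positive = FALSE)
        endpoint <- pmax(as.numeric(utils::tail(trajectory_states(traj), 1)), 0)
        eq <- find_equilibria(red, box, n_starts = opts$n_starts %||% 200,
                              seed = seed, extra_starts = rbind(endpoint))
        eq <- mapk_filter_simplex(eq, case)
        list(pass = nrow(eq) == 1 && eq$class[1] == "stable",
             details = list(n_eq = nrow(eq)))
      }),
      claim("bistable-window", "default", function(instance, case, seed, opts) {
        sc <- mapk_scan(case, case$mu_window %||% case$mu, feedback = "constant",
                        n_starts = opts$n_starts %||% 200, seed = seed)
        ok <- any(sc$n_eq == 3 & sc$pattern == "SUS")
        list(pass = ok, details = sc)
      }),
      claim("no-equilibria-strong-feedback", "default", function(instance, case, seed, opts) {
        sc <- mapk_scan(case, 1e8, feedback = "constant",
                        n_starts = opts$n_starts %||% 200, seed = seed,
                        x1_cap = opts$x1_cap_large %||% 50)
        list(pass = all(sc$n_eq == 0), details = sc)
      }),
      claim("autocatalytic-even-counts", "default", function(instance, case, seed, opts) {
        grid <- 10^seq(-1, 2, length.out = 7)
        sc <- mapk_scan(case, grid, feedback = "unbounded_increasing",
                        n_starts = opts$n_starts %||% 200, seed = seed,
                        x1_cap = opts$x1_cap_unbounded %||% 60)
        ok <- all(sc$n_eq %% 2 == 0) && any(sc$n_eq == 2)
        two <- sc[sc$n_eq == 2, ]
        ok <- ok && all(two$pattern == "SU" | two$pattern == "US")
        list(pass = ok, details = sc)
      })
    ),
    stop("unknown case study: ", name, call. = FALSE)
  )
  c(common, specific)
}

#' Run the robustness claim suite of a case study over a seeded ensemble
#'
#' Ensemble-scoped claims are evaluated on every sampled instance (a claim is
#' robust iff it holds for each member); default-scoped claims (the packaged
#' multistability witnesses) run once on the frozen default instance.
#' Results are a pure function of `(name, n_ensemble, seed)`.
#'
#' @param name case-study name.
#' @param n_ensemble ensemble size.
#' @param seed master seed.
#' @param claims `"all"` or a character vector of claim ids.
#' @param config a [sampling_config()] for the ensemble.
#' @param opts named list of per-claim tuning (sample counts etc.).
#' @return a tibble: `claim`, `scope`, `n_pass`, `n_na`, `n_total`, `robust`,
#'   list-column `failures` (indices of failing instances).
#' @export
run_suite <- function(name, n_ensemble = 20, seed = 1L, claims = "all",
                      config = sampling_config(), opts = list()) {
  case <- build_case(name)
  cl <- case$claims
  if (!identical(claims, "all")) {
    cl <- cl[vapply(cl, function(c) c$id %in% claims, logical(1))]
  }
  ens <- case_ensemble(case, n_ensemble, config, seed)
  rows <- purrr::map(cl, function(cc) {
    if (cc$scope == "default") {
      r <- cc$fun(case$default_instance, case, split_seed(seed, 1L), opts)
      tibble::tibble(claim = cc$id, scope = cc$scope,
                     n_pass = as.integer(isTRUE(r$pass)), n_na = 0L, n_total = 1L,
                     robust = isTRUE(r$pass),
                     failures = list(if (isTRUE(r$pass)) integer(0) else 1L))
    } else {
      res <- purrr::imap(ens, function(inst, i) {
        cc$fun(inst, case, split_seed(seed, 100L + i), opts)$pass
      })
      pass <- vapply(res, function(p) isTRUE(p), logical(1))
      na <- vapply(res, function(p) length(p) == 1 && is.na(p), logical(1))
      tibble::tibble(claim = cc$id, scope = cc$scope,
                     n_pass = sum(pass), n_na = sum(na),
                     n_total = length(ens),
                     robust = all(pass | na),
                     failures = list(which(!(pass | na))))
    }
  })
  dplyr::bind_rows(rows)
}

# Ensemble generation with case-specific admissibility constraints.
case_ensemble <- function(case, n, config = sampling_config(), seed = 1L) {
  ens <- generate_ensemble(case$model, n, config, seed)
  if (startsWith(case$model$name, "mapk")) {
    # the basal drive must sit below the top-tier removal ceiling, or the
    # open cascade has no equilibrium at all
    ens <- purrr::imap(ens, function(inst, i) {
      ceiling11 <- fn_sup(inst_fn(inst, "g11"))
      frac <- with_seed(split_seed(seed, 3000L + i), stats::runif(1, 0.05, 0.8))
      inst$functions$c10 <- list(make_function("constant", list(c = frac * ceiling11)))
      inst
    })
  }
  ens
}
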