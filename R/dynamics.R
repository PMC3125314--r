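#' Assemble the vector field of a concrete instance
#'
#' Sums, for each state `i`, the production coefficients times their source
#' species, minus degradation/conversion coefficients times theirs, plus
#' saturating and decreasing saturating production terms, with modulator
#' dependencies honored. Inputs are bound to constants or to functions of
#' time.
#'
#' @param model a [network_model()].
#' @param instance a matching `concrete_instance`.
#' @param inputs named list binding every model input to a constant or to a
#'   `function(t)`.
#' @return an object of class `vector_field` with `$fn(t, x)` (vector in,
#'   vector out), `$fn_mat(X, t)` (states in rows, vectorized over rows), and
#'   `$n`, `$state_names`.
#' @export
assemble_rhs <- function(model, instance, inputs = list()) {
  if (!identical(instance$model$name, model$name)) {
    stop("instance was built for a different model", call. = FALSE)
  }
  missing <- setdiff(model$inputs, names(inputs))
  if (length(missing)) {
    stop("unbound inputs: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vars <- model_vars(model)
  n <- length(model$states)
  input_fns <- lapply(model$inputs, function(nm) {
    b <- inputs[[nm]]
    if (is.function(b)) b else function(t) rep(b, length(t))
  })
  names(input_fns) <- model$inputs

  compiled <- lapply(model$terms, function(tm) {
    list(
      target = match(tm$target, model$states),
      sign = if (tm$kind == "b") -1 else 1,
      mult = if (!is.null(tm$mult)) match(tm$mult, vars) else NA_integer_,
      absorbed = tm$absorbed,
      slots = lapply(seq_along(tm$args), function(k) {
        list(arg = if (is.na(tm$args[k])) NA_integer_ else match(tm$args[k], vars),
             fn = instance$functions[[tm$label]][[k]]$fn)
      })
    )
  })

  eval_mat <- function(X, t = 0) {
    m <- nrow(X)
    U <- if (length(model$inputs)) {
      vapply(input_fns, function(f) rep(f(t)[1], m), numeric(m)) |>
        matrix(nrow = m)
    } else NULL
    V <- if (is.null(U)) X else cbind(X, U)
    D <- matrix(0, m, n)
    zero <- numeric(m)
    for (tm in compiled) {
      coef <- 1
      for (s in tm$slots) {
        coef <- coef * (if (is.na(s$arg)) s$fn(zero) else s$fn(V[, s$arg]))
      }
      contrib <- if (is.na(tm$mult) || tm$absorbed) coef else coef * V[, tm$mult]
      D[, tm$target] <- D[, tm$target] + tm$sign * contrib
    }
    D
  }

  structure(
    list(
      n = n,
      state_names = model$states,
      fn = function(t, x) as.numeric(eval_mat(matrix(x, nrow = 1), t)),
      fn_mat = eval_mat,
      model = model, instance = instance, inputs = inputs
    ),
    class = "vector_field"
  )
}

#' @export
print.vector_field <- function(x, ...) {
  cat("<vector_field> dim", x$n, ":", paste(x$state_names, collapse = ", "), "\n")
  invisible(x)
}

#' Reduce a vector field by eliminating conserved states
#'
#' For each group, one member is dropped and recovered as
#' `total - sum(other members)`; the reduced field evolves the remaining
#' coordinates. Used for cascades with conserved phosphorylation totals.
#'
#' @param field a `vector_field`.
#' @param groups list of `list(drop = <state>, members = <states>, total = <num>)`.
#' @return a `vector_field` on the retained coordinates.
#' @export
reduced_vector_field <- function(field, groups) {
  nm <- field$state_names
  drop_idx <- vapply(groups, function(g) match(g$drop, nm), integer(1))
  keep <- setdiff(seq_along(nm), drop_idx)
  embed <- function(Xr) {
    X <- matrix(0, nrow(Xr), length(nm))
    X[, keep] <- Xr
    for (g in seq_along(groups)) {
      others <- setdiff(match(groups[[g]]$members, nm), drop_idx[g])
      X[, drop_idx[g]] <- groups[[g]]$total - rowSums(X[, others, drop = FALSE])
    }
    X
  }
  eval_mat <- function(Xr, t = 0) {
    field$fn_mat(embed(Xr), t)[, keep, drop = FALSE]
  }
  structure(
    list(
      n = length(keep),
      state_names = nm[keep],
      fn = function(t, x) as.numeric(eval_mat(matrix(x, nrow = 1), t)),
      fn_mat = eval_mat,
      embed = function(xr) as.numeric(embed(matrix(xr, nrow = 1))),
      model = field$model, instance = field$instance, inputs = field$inputs,
      groups = groups
    ),
    class = "vector_field"
  )
}

#' Simulate a vector field
#'
#' Adaptive stiff-capable integration (lsoda). Trajectories are checked for
#' positivity: entries within `-10 * atol` of zero are solver noise and are
#' clamped to zero; anything below that fails the run. The terminal state is
#' flagged steady when the scale-free residual
#' `max|f(x)| < 1e-9 * (1 + max|x|)` holds.
#'
#' @param field a `vector_field`.
#' @param x0 nonnegative initial state.
#' @param t_span either `c(t0, t1)` or a full vector of output times.
#' @param rtol,atol solver tolerances.
#' @param n_out number of output grid points when `t_span` has length 2.
#' @param check_positive enforce the positivity invariant (default TRUE).
#' @return a tibble with `t` and one column per state; attributes
#'   `diagnostics` (solver info), `steady` (flag), `field`.
#' @export
simulate <- function(field, x0, t_span, rtol = 1e-8, atol = 1e-10,
                     n_out = 401, check_positive = TRUE) {
  stopifnot(all(x0 >= 0))
  times <- if (length(t_span) == 2) seq(t_span[1], t_span[2], length.out = n_out) else t_span
  f <- field$fn
  out <- deSolve::lsoda(
    y = stats::setNames(as.numeric(x0), field$state_names),
    times = times,
    func = function(t, y, parms) list(f(t, y)),
    rtol = rtol, atol = atol
  )
  diag <- attributes(out)$istate
  out <- as.data.frame(out)
  if (nrow(out) < length(times)) {
    stop("integration failed at t = ", max(out$time), "; last state: ",
         paste(signif(as.numeric(out[nrow(out), -1]), 6), collapse = ", "),
         call. = FALSE)
  }
  states <- as.matrix(out[, -1, drop = FALSE])
  if (check_positive) {
    worst <- min(states)
    if (worst < -10 * atol) {
      stop("positivity violated: min state ", worst, " < -10*atol", call. = FALSE)
    }
    states[states < 0] <- 0
  }
  xT <- states[nrow(states), ]
  steady <- max(abs(f(max(times), xT))) < 1e-9 * (1 + max(abs(xT)))
  traj <- tibble::as_tibble(as.data.frame(states))
  names(traj) <- field$state_names
  traj <- dplyr::bind_cols(tibble::tibble(t = out$time), traj)
  attr(traj, "steady") <- steady
  attr(traj, "diagnostics") <- list(rtol = rtol, atol = atol, istate = diag)
  attr(traj, "field") <- field
  class(traj) <- c("robnet_trajectory", class(traj))
  traj
}

trajectory_states <- function(traj) {
  as.matrix(traj[, setdiff(names(traj), "t"), drop = FALSE])
}

#' Upper bounds on an invariant box
#'
#' Computes per-state upper bounds by the saturation argument: the ceiling of
#' all bounded production into a state divided by the floor of its linear
#' degradation, propagated through the dependency order; additionally, a
#' state whose every production carries an exact-threshold factor in the
#' state itself is bounded by the largest such threshold. Entries are `+Inf`
#' where no bound is derivable. When the model has no cross-species
#' production coefficients, an aggregate bound on the total concentration
#' (total bounded production over the smallest degradation floor) is attached
#' as attribute `sum_bound`.
#'
#' @inheritParams assemble_rhs
#' @return named numeric vector of upper bounds (possibly `Inf`).
#' @export
invariant_box <- function(model, instance, inputs = list()) {
  vars <- model_vars(model)
  n <- length(model$states)
  input_vals <- vapply(model$inputs, function(nm) {
    b <- inputs[[nm]]
    if (is.function(b)) stop("invariant_box needs constant inputs", call. = FALSE)
    as.numeric(b)
  }, numeric(1))
  B <- c(rep(Inf, n), input_vals) # bounds on all variables
  names(B) <- vars

  slot_minmax <- function(f, tag, hi) {
    dir <- tag_direction(tag)
    big <- 1e9 * max(f$scale, 1)
    if (dir == "constant") {
      v <- f$fn(0); return(c(v, v))
    }
    if (dir == "non-decreasing") {
      mx <- if (is.finite(hi)) f$fn(hi) else {
        if (f$tag == "increasing-asymptotically-unbounded") Inf else f$fn(big)
      }
      return(c(f$fn(0), mx))
    }
    mn <- if (is.finite(hi)) f$fn(hi) else f$fn(big)
    c(mn, f$fn(0))
  }

  has_a_terms <- any(vapply(model$terms, function(tm) tm$kind == "a", logical(1)))

  for (pass in seq_len(2 * n + 2)) {
    for (i in seq_len(n)) {
      st <- model$states[i]
      ceiling_i <- 0
      floor_i <- 0
      prod_terms <- 0
      thetas <- numeric(0)
      theta_all <- TRUE
      for (lab in names(model$terms)) {
        tm <- model$terms[[lab]]
        if (tm$target != st) next
        ranges <- lapply(seq_along(tm$args), function(k) {
          a <- tm$args[k]
          hi <- if (is.na(a)) Inf else B[[a]]
          slot_minmax(instance$functions[[lab]][[k]], tm$tags[k], hi)
        })
        lo_prod <- prod(vapply(ranges, `[`, numeric(1), 1))
        hi_prod <- prod(vapply(ranges, `[`, numeric(1), 2))
        if (tm$kind %in% c("c", "d") || tm$kind == "a") {
          prod_terms <- prod_terms + 1
          top <- if (tm$kind == "a") hi_prod * B[[tm$mult]] else hi_prod
          ceiling_i <- ceiling_i + top
          p9 <- which(tm$tags == "decreasing-exactly-null" & tm$args %in% st)
          if (length(p9)) {
            thetas <- c(thetas, instance$functions[[lab]][[p9[1]]]$parameters$theta)
          } else theta_all <- FALSE
        } else if (tm$kind == "b" && !tm$absorbed && identical(tm$mult, st)) {
          floor_i <- floor_i + lo_prod
        }
      }
      cand <- if (floor_i > 0) ceiling_i / floor_i else Inf
      if (prod_terms > 0 && theta_all && length(thetas)) {
        cand <- min(cand, max(thetas))
      }
      B[i] <- min(B[i], cand)
    }
  }
  out <- B[seq_len(n)]

  if (!has_a_terms) {
    tot_ceiling <- 0
    floors <- rep(0, n)
    for (lab in names(model$terms)) {
      tm <- model$terms[[lab]]
      i <- match(tm$target, model$states)
      ranges <- lapply(seq_along(tm$args), function(k) {
        a <- tm$args[k]
        hi <- if (is.na(a)) Inf else B[[a]]
        slot_minmax(instance$functions[[lab]][[k]], tm$tags[k], hi)
      })
      if (tm$kind %in% c("c", "d")) {
        tot_ceiling <- tot_ceiling + prod(vapply(ranges, `[`, numeric(1), 2))
      } else if (tm$kind == "b" && !tm$absorbed && identical(tm$mult, tm$target)) {
        floors[i] <- floors[i] + prod(vapply(ranges, `[`, numeric(1), 1))
      }
    }
    if (all(floors > 0)) attr(out, "sum_bound") <- tot_ceiling / min(floors)
  }
  out
}

#' Detect conserved sums (moieties) of an instantiated model
#'
#' Samples random states in the (finite part of the) invariant box, stacks
#' the right-hand-side vectors, and extracts the numerical left null space;
#' weights are rationalized to small integers (denominator at most 12) and
#' re-verified on the samples. The weight set is invariant to the sampling
#' seed up to sign and scale.
#'
#' @inheritParams assemble_rhs
#' @param n_samples number of sampled states (at least `3 * n` recommended).
#' @param seed integer seed.
#' @param tol relative drift tolerance for acceptance.
#' @return a tibble with one row per conserved sum: integer weight columns
#'   named after the states and `max_residual`; zero rows if none. A
#'   degenerate (identically zero) field returns all unit directions with
#'   attribute `degenerate = TRUE`.
#' @export
detect_conserved_sums <- function(model, instance, inputs = list(),
                                  n_samples = NULL, seed = 1L, tol = 1e-6) {
  n <- length(model$states)
  n_samples <- n_samples %||% (3 * n)
  field <- assemble_rhs(model, instance, inputs)
  box <- invariant_box(model, instance, inputs)
  hi <- ifelse(is.finite(box), box, 10)
  X <- box_samples(n_samples, rbind(rep(0, n), hi), seed)
  F <- field$fn_mat(X, 0)
  fn_norm <- sqrt(rowSums(F^2))
  empty <- tibble::as_tibble(matrix(numeric(0), 0, n, dimnames = list(NULL, model$states)))
  empty$max_residual <- numeric(0)
  if (max(fn_norm) < 1e-12) {
    out <- tibble::as_tibble(diag(n), .name_repair = ~model$states)
    out$max_residual <- 0
    attr(out, "degenerate") <- TRUE
    warning("zero field everywhere: all directions are conserved", call. = FALSE)
    return(out)
  }
  sv <- svd(F)
  small <- sv$d <= 1e-8 * max(sv$d)
  if (!any(small)) return(empty)
  basis <- sv$v[, small, drop = FALSE]
  # Canonicalize the null-space basis by row reduction so disjoint-support
  # moieties come out as separate sparse vectors.
  W <- rref_rows(t(basis))
  rows <- list()
  for (r in seq_len(nrow(W))) {
    w <- W[r, ]
    w <- w / max(abs(w))
    ratio <- NULL
    for (dnm in 1:12) {
      if (all(abs(w * dnm - round(w * dnm)) < 1e-6 * dnm)) {
        ratio <- round(w * dnm)
        break
      }
    }
    if (is.null(ratio)) next
    g <- Reduce(gcd_int, abs(ratio[ratio != 0]))
    ratio <- ratio / g
    if (ratio[which(ratio != 0)[1]] < 0) ratio <- -ratio
    resid <- max(abs(F %*% ratio) / pmax(fn_norm, 1e-300))
    if (resid <= tol * sqrt(sum(ratio^2))) {
      rows[[length(rows) + 1]] <- c(ratio, resid)
    }
  }
  if (!length(rows)) return(empty)
  M <- do.call(rbind, rows)
  out <- tibble::as_tibble(M[, seq_len(n), drop = FALSE], .name_repair = ~model$states)
  out$max_residual <- M[, n + 1]
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Reduced row echelon form with partial pivoting (small matrices only).
rref_rows <- function(M, tol = 1e-10) {
  M <- as.matrix(M)
  lead <- 1
  for (r in seq_len(nrow(M))) {
    if (lead > ncol(M)) break
    piv <- which.max(abs(M[r:nrow(M), lead])) + r - 1
    while (abs(M[piv, lead]) < tol) {
      lead <- lead + 1
      if (lead > ncol(M)) return(M)
      piv <- which.max(abs(M[r:nrow(M), lead])) + r - 1
    }
    M[c(r, piv), ] <- M[c(piv, r), ]
    M[r, ] <- M[r, ] / M[r, lead]
    for (j in seq_len(nrow(M))) {
      if (j != r) M[j, ] <- M[j, ] - M[j, lead] * M[r, ]
    }
    lead <- lead + 1
  }
  M
}
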