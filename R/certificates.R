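#' Piecewise-linear (max-of-affine) Lyapunov candidates
#'
#' `V(x) = max_p (g_p . x + o_p)`, the classical non-smooth Lyapunov family.
#' The weighted 1-norm about a center `x*`, `V(x) = sum_i w_i |x_i - x_i*|`,
#' is the preset used throughout: its pieces are all sign combinations
#' `sum_i s_i w_i (x_i - x_i*)`. For a two-species pool it is the worst case
#' between the total-concentration error and the concentration mismatch.
#'
#' @param center the reference point `x*`.
#' @param weights positive weights (recycled).
#' @return an object of class `pwl_fn` with `$value(x)` (matrix rows ok),
#'   `$pieces` (gradient matrix), `$center`.
#' @export
pwl_norm <- function(center, weights = 1) {
  n <- length(center)
  w <- rep(weights, length.out = n)
  stopifnot(all(w > 0))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  G <- sweep(signs, 2, w, "*")
  structure(
    list(
      center = center,
      pieces = G,
      value = function(x) {
        X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
        D <- sweep(X, 2, center, "-")
        v <- abs(D) %*% w
        as.numeric(v)
      }
    ),
    class = "pwl_fn"
  )
}

# Active pieces at x: indices of pieces within active_tol * (1 + V) of the max.
active_pieces <- function(V, x, active_tol = 1e-9) {
  d <- x - V$center
  vals <- as.numeric(V$pieces %*% d)
  vmax <- max(vals)
  which(vals >= vmax - active_tol * (1 + abs(vmax)))
}

new_certificate <- function(kind, holds, worst_margin, witnesses,
                            estimated_rate = NA_real_, n_samples = NA_integer_,
                            seed = NA_integer_, details = list()) {
  structure(
    list(kind = kind, holds = holds, worst_margin = worst_margin,
         witnesses = witnesses, estimated_rate = estimated_rate,
         n_samples = n_samples, seed = seed, details = details),
    class = "certificate_report"
  )
}

#' @export
print.certificate_report <- function(x, ...) {
  cat("<certificate_report> ", x$kind, ": ",
      if (isTRUE(x$holds)) "HOLDS" else "FAILS",
      " (worst margin ", signif(x$worst_margin, 4),
      if (is.finite(x$estimated_rate)) paste0(", rate ", signif(x$estimated_rate, 4)),
      ")\n", sep = "")
  invisible(x)
}

#' Sampled decrease certificate for a non-smooth Lyapunov function
#'
#' At seeded sample states in `region` (excluding a ball around the center,
#' where the decrease condition degenerates), evaluates the generalized
#' Lyapunov derivative — the maximum over active pieces of `gradient . f(x)`
#' — and certifies `D(x) <= -rate * V(x)` for the largest such rate. The
#' comparison function is taken linear, matching an exponential convergence
#' bound. Samples are a prefix of a fixed seeded stream, so enlarging
#' `n_samples` only extends the evidence (the worst margin cannot improve).
#'
#' @param field a `vector_field` whose center is an equilibrium.
#' @param V a [pwl_norm()] (or compatible `pwl_fn`).
#' @param region `2 x n` box (or upper-bound vector).
#' @param exclusion_radius relative radius of the excluded ball.
#' @param n_samples sample count.
#' @param seed integer seed.
#' @param active_tol active-set tolerance.
#' @return a `certificate_report`; `estimated_rate` is the certified decay
#'   rate (min over samples of `-D/V`).
#' @export
decrease_certificate <- function(field, V, region, exclusion_radius = 1e-3,
                                 n_samples = 20000, seed = 1L,
                                 active_tol = 1e-9) {
  n <- field$n
  region <- as_box(region, n)
  res <- max(abs(field$fn(0, V$center)))
  if (res > 1e-6) {
    stop("V center is not an equilibrium (residual ", signif(res, 3), ")", call. = FALSE)
  }
  scale <- max(region[2, ] - region[1, ])
  X <- box_samples(n_samples, region, seed)
  d2 <- sqrt(rowSums(sweep(X, 2, V$center, "-")^2))
  X <- X[d2 > exclusion_radius * scale, , drop = FALSE]
  F <- field$fn_mat(X, 0)
  D <- sweep(X, 2, V$center, "-")
  vals <- V$value(X)
  # generalized derivative: max over active pieces of g . f
  PV <- D %*% t(V$pieces)          # piece values
  PF <- F %*% t(V$pieces)          # piece directional derivatives
  vmax <- apply(PV, 1, max)
  act <- PV >= vmax - active_tol * (1 + abs(vmax))
  PF[!act] <- -Inf
  Dgen <- apply(PF, 1, max)
  ratio <- -Dgen / vals
  worst_i <- which.max(Dgen / pmax(vals, 1e-300))
  holds <- all(Dgen < 0)
  new_certificate(
    "lyapunov-decrease",
    holds = holds,
    worst_margin = Dgen[worst_i],
    witnesses = X[worst_i, , drop = FALSE],
    estimated_rate = if (holds) min(ratio) else NA_real_,
    n_samples = nrow(X), seed = seed,
    details = list(exclusion_radius = exclusion_radius)
  )
}

#' Constraint sets for Nagumo invariance checks
#'
#' A set `{x : s_i(x) <= sigma_i for all i}`. Linear constraints
#' (`w . x <= sigma`) carry their normal vector for exact boundary
#' projection; nonlinear constraints supply `fn` (vectorized over rows) and
#' are projected by bisection toward an interior point.
#'
#' @param constraints list of `list(w =, sigma =, label =)` or
#'   `list(fn =, sigma =, label =)` entries.
#' @return an object of class `constraint_set`.
#' @export
constraint_set <- function(constraints) {
  structure(list(constraints = constraints), class = "constraint_set")
}

#' Nonnegative-orthant constraint set
#' @param n dimension.
#' @export
orthant_set <- function(n) {
  constraint_set(lapply(seq_len(n), function(i) {
    w <- numeric(n); w[i] <- -1
    list(w = w, sigma = 0, label = paste0("x", i, ">=0"))
  }))
}

cons_value <- function(cn, X) {
  if (!is.null(cn$w)) as.numeric(X %*% cn$w) else cn$fn(X)
}

cons_grad <- function(cn, x) {
  if (!is.null(cn$w)) return(cn$w)
  num_jacobian(function(z) cn$fn(matrix(z, nrow = 1)), x)[1, ]
}

#' Sampled Nagumo boundary certificate for a constraint set
#'
#' Positive invariance of a constraint set requires the field not to point
#' outward across any active constraint. The certificate samples states on
#' each constraint's boundary (within the others), computes the outward
#' directional derivative `grad s_i . f`, and holds iff it never exceeds the
#' slack. Sample streams are nested in `n_boundary`.
#'
#' @param field a `vector_field`.
#' @param cset a [constraint_set()].
#' @param box sampling box (upper-bound vector or `2 x n`).
#' @param n_boundary boundary samples per constraint.
#' @param seed integer seed.
#' @param slack tolerance on the directional derivative.
#' @return a `certificate_report`.
#' @export
nagumo_certificate <- function(field, cset, box, n_boundary = 2000, seed = 1L,
                               slack = NULL) {
  n <- field$n
  box <- as_box(box, n)
  cons <- cset$constraints
  worst <- -Inf
  witness <- NULL
  worst_label <- NA_character_
  total <- 0L
  for (ci in seq_along(cons)) {
    cn <- cons[[ci]]
    cand <- box_samples(n_boundary, box, split_seed(seed, ci))
    if (!is.null(cn$w)) {
      # orthogonal projection onto the hyperplane w . x = sigma
      t <- (cn$sigma - cand %*% cn$w) / sum(cn$w^2)
      B <- cand + t %*% t(cn$w)
    } else {
      interior <- find_interior(cons, box, split_seed(seed, 500L + ci))
      if (is.null(interior)) {
        stop("cannot sample constraint '", cn$label %||% ci,
             "': no interior point found", call. = FALSE)
      }
      B <- t(apply(cand, 1, function(y) project_bisect(cn, interior, y)))
      B <- B[stats::complete.cases(B), , drop = FALSE]
      if (!nrow(B)) {
        stop("projection failure on constraint '", cn$label %||% ci, "'", call. = FALSE)
      }
    }
    # keep boundary points satisfying the other constraints (and the box)
    ok <- rep(TRUE, nrow(B))
    for (cj in seq_along(cons)) {
      if (cj == ci) next
      ok <- ok & (cons_value(cons[[cj]], B) <= cons[[cj]]$sigma + 1e-9)
    }
    ok <- ok & apply(B, 1, function(x) all(x >= box[1, ] - 1e-9 & x <= box[2, ] + 1e-9))
    B <- B[ok, , drop = FALSE]
    if (!nrow(B)) next
    total <- total + nrow(B)
    F <- field$fn_mat(B, 0)
    dd <- if (!is.null(cn$w)) {
      as.numeric(F %*% cn$w)
    } else {
      vapply(seq_len(nrow(B)), function(i) sum(cons_grad(cn, B[i, ]) * F[i, ]), numeric(1))
    }
    sl <- slack %||% (1e-7 * (1 + max(abs(F))))
    i <- which.max(dd)
    if (dd[i] - sl > worst) {
      worst <- dd[i] - sl
      witness <- B[i, , drop = FALSE]
      worst_label <- cn$label %||% as.character(ci)
    }
  }
  new_certificate(
    "nagumo-invariance",
    holds = worst <= 0,
    worst_margin = worst,
    witnesses = witness,
    n_samples = total, seed = seed,
    details = list(worst_constraint = worst_label)
  )
}

find_interior <- function(cons, box, seed, n_try = 2000) {
  X <- box_samples(n_try, box, seed)
  ok <- rep(TRUE, nrow(X))
  for (cn in cons) ok <- ok & (cons_value(cn, X) < cn$sigma - 1e-9)
  if (!any(ok)) return(NULL)
  X[which(ok)[1], ]
}

project_bisect <- function(cn, inside, outside, iters = 60) {
  si <- cons_value(cn, matrix(inside, nrow = 1)) - cn$sigma
  so <- cons_value(cn, matrix(outside, nrow = 1)) - cn$sigma
  if (so < 0) return(rep(NA_real_, length(inside))) # candidate not outside
  lo <- 0; hi <- 1
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    x <- inside + mid * (outside - inside)
    if (cons_value(cn, matrix(x, nrow = 1)) - cn$sigma > 0) hi <- mid else lo <- mid
  }
  inside + hi * (outside - inside)
}

#' Sector (order-cone) invariance certificate about an equilibrium
#'
#' Specializes the Nagumo check to the axis-aligned sector through `x_star`
#' given by a per-state sign pattern (`">="` or `"<="`). A holding
#' certificate means trajectories entering the sector stay in it: monotone
#' approach with no over- or undershoot in the constrained coordinates.
#'
#' @param field a `vector_field`.
#' @param x_star equilibrium the sector is anchored at.
#' @param sign_pattern character vector (length n) of `">="` / `"<="`.
#' @param box sampling box.
#' @param ... passed to [nagumo_certificate()].
#' @export
sector_certificate <- function(field, x_star, sign_pattern, box, ...) {
  n <- field$n
  stopifnot(length(sign_pattern) == n, all(sign_pattern %in% c(">=", "<=")))
  res <- max(abs(field$fn(0, x_star)))
  if (res > 1e-6) stop("x_star is not an equilibrium", call. = FALSE)
  cons <- lapply(seq_len(n), function(i) {
    w <- numeric(n)
    if (sign_pattern[i] == ">=") {
      w[i] <- -1
      list(w = w, sigma = -x_star[i],
           label = paste0(field$state_names[i], ">=", signif(x_star[i], 6)))
    } else {
      w[i] <- 1
      list(w = w, sigma = x_star[i],
           label = paste0(field$state_names[i], "<=", signif(x_star[i], 6)))
    }
  })
  rep <- nagumo_certificate(field, constraint_set(cons), box, ...)
  rep$kind <- "sector-invariance"
  rep
}

#' Count equilibrium crossings along a trajectory
#'
#' Per-state count of sign changes of `x_i(t) - x_i*` outside a dead band;
#' the no-oscillation property bounds each count by one.
#'
#' @param trajectory a [simulate()] tibble.
#' @param x_star reference state.
#' @param dead_band absolute half-width ignored around the reference.
#' @return named integer vector of crossing counts.
#' @export
crossing_count <- function(trajectory, x_star, dead_band = 1e-6) {
  S <- trajectory_states(trajectory)
  vapply(seq_len(ncol(S)), function(i) {
    s <- S[, i] - x_star[i]
    q <- sign(s)
    q[abs(s) <= dead_band] <- 0
    q <- q[q != 0]
    if (length(q) < 2) return(0L)
    sum(diff(q) != 0)
  }, integer(1)) |> stats::setNames(colnames(S))
}

#' Fit an exponential decay rate to a Lyapunov time series
#'
#' Least-squares slope of `log V` against `t` over the window where
#' `V > 1e-8 * V(0)`. A constant series has rate 0; non-monotone series
#' (beyond a relative tolerance) are flagged, since they indicate that the
#' decrease certificate likely failed.
#'
#' @param V_series positive numeric vector of Lyapunov values.
#' @param times matching time vector.
#' @return list with `rate` (>= 0), `warning` (NULL or message).
#' @export
decay_rate <- function(V_series, times) {
  stopifnot(length(V_series) == length(times))
  v0 <- V_series[1]
  warn <- NULL
  if (v0 <= 0 || max(V_series) - min(V_series) <= 1e-12 * (1 + v0)) {
    return(list(rate = 0, warning = NULL))
  }
  inc <- diff(V_series)
  if (any(inc > 1e-3 * v0)) {
    warn <- "V is not monotonically decreasing beyond tolerance"
  }
  keep <- V_series > 1e-8 * v0
  if (sum(keep) < 3) return(list(rate = 0, warning = "window too short"))
  fit <- stats::lm.fit(cbind(1, times[keep]), log(V_series[keep]))
  list(rate = max(0, -fit$coefficients[2]), warning = warn)
}
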