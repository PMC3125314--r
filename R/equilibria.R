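#' Find all equilibria of a vector field in a box
#'
#' Damped-Newton root finding from quasi-random (Halton) multistarts plus
#' seeded uniform starts, with deduplication within a merge radius, a polish
#' step, and local stability classification from the eigenvalues of a
#' central-difference Jacobian. An empty result is a valid outcome (regimes
#' without equilibria exist).
#'
#' @param field a `vector_field`.
#' @param box upper bounds (numeric vector, finite; replace any `Inf` from
#'   [invariant_box()] by a cap first) or a `2 x n` matrix of bounds.
#' @param n_starts number of multistarts.
#' @param seed integer seed for the random half of the starts.
#' @param merge_radius deduplication radius, relative to the box scale.
#' @param tol residual tolerance `max|f(x*)|`.
#' @param margin eigenvalue dead band for the marginal classification.
#' @param extra_starts optional matrix (rows = points) of deterministic
#'   additional starts, tried before the quasi-random pool; useful for
#'   simulation-seeded starts when an attractor hugs the box boundary.
#' @return a `robnet_equilibria` tibble, one row per equilibrium, sorted by
#'   first coordinate: state columns, `residual`, `class`
#'   (stable/unstable/marginal) and list-column `eigenvalues`.
#' @export
find_equilibria <- function(field, box, n_starts = 200, seed = 1L,
                            merge_radius = 1e-6, tol = 1e-9, margin = 1e-6,
                            extra_starts = NULL) {
  n <- field$n
  box <- as_box(box, n)
  if (any(!is.finite(box))) stop("box must be finite; cap unbounded states", call. = FALSE)
  scale <- max(box[2, ] - box[1, ], 1)
  f <- function(x) field$fn(0, x)

  n_h <- ceiling(n_starts / 2)
  H <- halton_seq(n_h, n)
  starts <- rbind(
    sweep(sweep(H, 2, box[2, ] - box[1, ], "*"), 2, box[1, ], "+"),
    box_samples(n_starts - n_h, box, seed)
  )
  if (!is.null(extra_starts)) {
    E <- matrix(as.numeric(extra_starts), ncol = n)
    starts <- rbind(E, starts)
  }

  roots <- list()
  for (s in seq_len(nrow(starts))) {
    x <- newton_root(f, starts[s, ], tol = tol, box = box)
    if (is.null(x)) next
    if (any(x < box[1, ] - 0.05 * scale) || any(x > box[2, ] + 0.05 * scale)) next
    if (any(x < -1e-9)) next
    x[x < 0] <- 0
    dup <- FALSE
    for (r in roots) {
      if (max(abs(r - x)) < merge_radius * (1 + scale)) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  if (!length(roots)) {
    out <- tibble::as_tibble(matrix(numeric(0), 0, n,
                                    dimnames = list(NULL, field$state_names)))
    out$residual <- numeric(0)
    out$class <- character(0)
    out$eigenvalues <- list()
    class(out) <- c("robnet_equilibria", class(out))
    return(out)
  }
  # polish + classify
  rows <- purrr::map(roots, function(x) {
    x <- newton_root(f, x, tol = tol * 1e-2, box = box, max_iter = 10) %||% x
    x[x < 0 & x > -1e-12] <- 0
    classify(field, x, tol = tol, margin = margin)
  })
  out <- dplyr::bind_rows(rows)
  # re-deduplicate after polishing
  keep <- rep(TRUE, nrow(out))
  S <- as.matrix(out[, field$state_names, drop = FALSE])
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1)) {
      if (keep[j] && max(abs(S[i, ] - S[j, ])) < merge_radius * (1 + scale)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out[[field$state_names[1]]]), , drop = FALSE]
  class(out) <- c("robnet_equilibria", class(out))
  out
}

# Damped Newton iteration; returns the root or NULL.
newton_root <- function(f, x0, tol = 1e-9, box = NULL, max_iter = 60) {
  x <- x0
  fx <- f(x)
  if (any(!is.finite(fx))) return(NULL)
  for (it in seq_len(max_iter)) {
    if (max(abs(fx)) < tol) return(x)
    J <- num_jacobian(f, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (!is.null(box)) {
        lo <- box[1, ] - 0.5 * (box[2, ] - box[1, ]) - 1
        xn <- pmax(xn, lo)
      }
      fn_ <- f(xn)
      if (all(is.finite(fn_)) && max(abs(fn_)) < max(abs(fx)) * (1 - 1e-4 * lam)) break
      lam <- lam / 2
      if (lam < 1e-6) return(if (max(abs(fx)) < tol) x else NULL)
    }
    x <- xn
    fx <- fn_
  }
  if (max(abs(fx)) < tol) x else NULL
}

#' Classify the local stability of an equilibrium
#'
#' Central-difference Jacobian; stable iff all eigenvalue real parts are
#' below `-margin`, unstable iff any exceeds `+margin`, marginal otherwise
#' (marginal points sit inside the dead band and are excluded from
#' multistability counts by downstream helpers).
#'
#' @param field a `vector_field`.
#' @param x_star state vector with small residual.
#' @param fd_step finite-difference step (default `sqrt(eps) * (1 + |x|)`).
#' @param tol residual tolerance (a larger residual raises an error).
#' @param margin eigenvalue dead band.
#' @return a one-row `robnet_equilibria` tibble.
#' @export
classify <- function(field, x_star, fd_step = NULL, tol = 1e-8, margin = 1e-6) {
  f <- function(x) field$fn(0, x)
  res <- max(abs(f(x_star)))
  if (res > tol * 10) {
    stop("not an equilibrium: residual ", signif(res, 3), call. = FALSE)
  }
  J <- num_jacobian(f, x_star, fd_step = fd_step)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  cls <- if (all(re < -margin)) "stable" else if (any(re > margin)) "unstable" else "marginal"
  out <- tibble::as_tibble(as.list(stats::setNames(x_star, field$state_names)))
  out$residual <- res
  out$class <- cls
  out$eigenvalues <- list(ev)
  class(out) <- c("robnet_equilibria", class(out))
  out
}

#' Check componentwise ordering of a set of equilibria
#'
#' Equilibria are totally ordered componentwise when some permutation makes
#' every listed state non-decreasing; states named in `reversed` are required
#' to be non-increasing along the same permutation (the partial order of
#' phosphorylation cascades, where unphosphorylated pools move opposite to
#' active forms).
#'
#' @param equilibria a `robnet_equilibria` tibble with at least 2 rows.
#' @param states state names to order on (default: all forward).
#' @param reversed states expected in reverse order.
#' @param tol comparison tolerance.
#' @return list with `ordered` flag and the sorting `permutation`.
#' @export
check_order <- function(equilibria, states = NULL,
                        reversed = character(0), tol = 1e-6) {
  stopifnot(nrow(equilibria) >= 2)
  nms <- setdiff(names(equilibria), c("residual", "class", "eigenvalues"))
  states <- states %||% nms
  fwd <- setdiff(states, reversed)
  key <- if (length(fwd)) fwd[1] else reversed[1]
  perm <- order(equilibria[[key]], decreasing = key %in% reversed)
  sc <- max(abs(as.matrix(equilibria[, states, drop = FALSE])), 1)
  ok <- TRUE
  for (s in fwd) if (any(diff(equilibria[[s]][perm]) < -tol * sc)) ok <- FALSE
  for (s in reversed) if (any(diff(equilibria[[s]][perm]) > tol * sc)) ok <- FALSE
  list(ordered = ok, permutation = perm)
}

#' Steady-state response curve of equilibria against an input
#'
#' Re-solves the equilibrium problem at each grid value of one input, matches
#' branches across the grid by nearest neighbor within a merge radius, and
#' flags per-state monotonicity on each branch. Changes in branch count are
#' recorded as fold markers, not errors.
#'
#' @param model,instance the model and a concrete instance.
#' @param input_id name of the input to sweep.
#' @param grid increasing numeric grid of input values.
#' @param box upper-bound vector (or `2 x n` matrix) for root finding.
#' @param inputs bindings for the remaining inputs.
#' @param ... passed to [find_equilibria()].
#' @return a `robnet_response` tibble: `u`, `branch`, state columns, `class`;
#'   attributes `monotonicity` (tibble branch x state: "increasing",
#'   "decreasing", "flat", "non-monotone") and `folds` (grid values where the
#'   branch count changes).
#' @export
response_curve <- function(model, instance, input_id, grid, box,
                           inputs = list(), ...) {
  stopifnot(all(diff(grid) > 0))
  per_u <- purrr::map(grid, function(u) {
    b <- inputs
    b[[input_id]] <- u
    fld <- assemble_rhs(model, instance, b)
    eq <- find_equilibria(fld, box, ...)
    eq
  })
  counts <- vapply(per_u, nrow, integer(1))
  folds <- grid[which(diff(counts) != 0)]
  snames <- model$states
  # nearest-neighbor branch matching along the grid
  branch_of <- vector("list", length(grid))
  next_id <- 0
  prev <- NULL
  for (g in seq_along(grid)) {
    eq <- per_u[[g]]
    ids <- integer(nrow(eq))
    if (nrow(eq)) {
      S <- as.matrix(eq[, snames, drop = FALSE])
      if (!is.null(prev) && nrow(prev$S)) {
        for (i in seq_len(nrow(S))) {
          d <- apply(prev$S, 1, function(r) max(abs(r - S[i, ])))
          j <- which.min(d)
          scale_d <- 1 + max(abs(S[i, ]))
          if (length(d) && d[j] < 0.25 * scale_d && !(prev$ids[j] %in% ids)) {
            ids[i] <- prev$ids[j]
          }
        }
      }
      for (i in seq_len(nrow(S))) {
        if (ids[i] == 0) { next_id <- next_id + 1; ids[i] <- next_id }
      }
      prev <- list(S = S, ids = ids)
    }
    branch_of[[g]] <- ids
  }
  rows <- purrr::map2(seq_along(grid), per_u, function(g, eq) {
    if (!nrow(eq)) return(NULL)
    dplyr::bind_cols(tibble::tibble(u = grid[g], branch = branch_of[[g]]),
                     eq[, c(snames, "residual", "class")])
  })
  out <- dplyr::bind_rows(rows)
  mono <- NULL
  if (nrow(out)) {
    mono <- out |>
      tidyr::pivot_longer(dplyr::all_of(snames), names_to = "state") |>
      dplyr::group_by(.data$branch, .data$state) |>
      dplyr::summarise(direction = mono_label(.data$value), .groups = "drop")
  }
  attr(out, "monotonicity") <- mono
  attr(out, "folds") <- folds
  class(out) <- c("robnet_response", class(out))
  out
}

mono_label <- function(v, tol = 1e-6) {
  if (length(v) < 2) return("flat")
  d <- diff(v)
  sc <- max(abs(v), 1)
  if (all(abs(d) <= tol * sc)) "flat"
  else if (all(d >= -tol * sc)) "increasing"
  else if (all(d <= tol * sc)) "decreasing"
  else "non-monotone"
}
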