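#' Numerically verify that a function satisfies a property tag
#'
#' Checks the tag's defining predicates (sign, monotonicity, value and slope
#' at the origin, limit behavior, derivative shape) on a logarithmic grid.
#' Limits are probed with two points a decade apart (`grid_max` and
#' `10 * grid_max`); derivative unimodality is decided by counting sign
#' changes of second differences with a dead band, which is robust to float
#' noise. The check is deterministic given `(f, tag, grid)`.
#'
#' @param f a `parametric_fn` from [make_function()] (or a bare function; a
#'   central-difference derivative is then used).
#' @param tag claimed property tag; defaults to `f$tag`.
#' @param grid_max largest grid abscissa; default `1e4` times the function's
#'   characteristic scale.
#' @param n_grid number of grid points.
#' @return a list with `pass` (flag), `violated` (character vector of failed
#'   predicates) and `details`.
#' @examples
#' verify_property(make_function("hill_sigmoid", list(K = 1, H = 2)))$pass
#' verify_property(make_function("constant", list(c = 1)), "sigmoidal")$violated
#' @export
verify_property <- function(f, tag = NULL, grid_max = NULL, n_grid = 400) {
  if (is.function(f)) {
    f <- list(fn = f, deriv = NULL, scale = 1, tag = NULL)
  }
  tag <- assert_tag(tag %||% f$tag)
  scale <- f$scale %||% 1
  grid_max <- grid_max %||% (1e4 * scale)
  fn <- f$fn
  dfn <- f$deriv %||% function(x) vapply(x, function(xx) num_deriv(fn, xx), numeric(1))

  x <- c(0, exp(seq(log(scale * 1e-4), log(grid_max), length.out = n_grid - 1)))
  fx <- fn(x)
  if (any(!is.finite(fx))) {
    stop("non-finite evaluation at x = ", x[which(!is.finite(fx))[1]], call. = FALSE)
  }
  dfx <- dfn(x)
  f_inf <- fn(grid_max)
  f_inf10 <- fn(10 * grid_max)
  fmax <- max(abs(fx), abs(f_inf10))
  eps_f <- 1e-9 * (1 + fmax)
  eps_mon <- 1e-9 * (1 + fmax)
  limit_tol <- 1e-3

  violated <- character(0)
  fail <- function(name) violated <<- c(violated, name)

  if (any(fx < -eps_f)) fail("nonnegative")

  non_decreasing <- all(diff(fx) >= -eps_mon)
  non_increasing <- all(diff(fx) <= eps_mon)
  f0 <- fx[1]
  df0 <- dfx[1]
  dmax <- max(abs(dfx), 1e-300)
  finite_limit <- abs(f_inf10 - f_inf) <= limit_tol * (abs(f_inf) + eps_f)
  null_limit <- abs(f_inf10) <= max(limit_tol * fmax, eps_f)
  unbounded_growth <- is.finite(f_inf10) && f_inf10 > 1.5 * max(f_inf, eps_f)

  # Unimodality of the derivative: one sign change of its increments, in the
  # stated direction, after dropping changes inside a dead band.
  deriv_shape <- function(direction) {
    dd <- diff(dfx)
    band <- 1e-8 * max(abs(dd), 1e-300)
    s <- sign(dd)
    s[abs(dd) <= band] <- 0
    s <- s[s != 0]
    if (length(s) == 0) return(FALSE)
    r <- rle(s)$values
    if (direction == "max") identical(r, c(1, -1)) else identical(r, c(-1, 1))
  }

  is_constant <- (max(fx) - min(fx)) <= eps_f

  switch(tag,
    "nonnegative-constant" = {
      if (!is_constant) fail("constant")
    },
    "positive-constant" = {
      if (!is_constant) fail("constant")
      if (f0 <= eps_f) fail("positive")
    },
    "sigmoidal" = {
      if (!non_decreasing) fail("non-decreasing")
      if (abs(f0) > eps_f) fail("f(0)=0")
      if (abs(df0) > 1e-6 * dmax) fail("f'(0)=0")
      if (!finite_limit || f_inf <= eps_f) fail("finite-positive-limit")
      if (!deriv_shape("max")) fail("derivative-unique-maximum")
    },
    "complementary-sigmoidal" = {
      if (!non_increasing) fail("non-increasing")
      if (f0 <= eps_f) fail("f(0)>0")
      if (abs(df0) > 1e-6 * dmax) fail("f'(0)=0")
      if (!null_limit) fail("null-limit")
      if (!deriv_shape("min")) fail("derivative-unique-minimum")
    },
    "constant-sigmoidal" = {
      if (!non_decreasing) fail("non-decreasing")
      if (f0 <= eps_f) fail("f(0)>0")
      if (abs(df0) > 1e-6 * dmax) fail("f'(0)=0")
      if (!finite_limit || f_inf <= f0 + eps_f) fail("finite-limit-above-constant")
      if (!deriv_shape("max")) fail("derivative-unique-maximum")
    },
    "constant-complementary-sigmoidal" = {
      if (!non_increasing) fail("non-increasing")
      if (f0 <= eps_f) fail("f(0)>0")
      if (abs(df0) > 1e-6 * dmax) fail("f'(0)=0")
      if (!finite_limit) fail("finite-limit")
      if (!deriv_shape("min")) fail("derivative-unique-minimum")
    },
    "increasing-asymptotically-constant" = {
      if (!all(dfx > 0)) fail("f'(x)>0")
      if (!finite_limit || f_inf <= eps_f) fail("finite-positive-limit")
      if (!all(diff(dfx) <= 1e-8 * dmax)) fail("derivative-decreasing")
    },
    "decreasing-asymptotically-null" = {
      if (!all(dfx < 0)) fail("f'(x)<0")
      if (!null_limit) fail("null-limit")
      if (!all(diff(dfx) >= -1e-8 * dmax)) fail("derivative-increasing")
    },
    "decreasing-exactly-null" = {
      zero <- abs(fx) <= 1e-12 * (1 + fmax)
      if (abs(f_inf10) > 1e-12 * (1 + fmax) || !any(zero)) fail("exactly-null-above-threshold")
      pos <- which(fx > eps_f)
      if (length(pos) > 1 && !all(diff(fx[pos]) < eps_mon)) fail("strictly-decreasing-below-threshold")
      if (f0 <= eps_f) fail("f(0)>0")
    },
    "increasing-asymptotically-unbounded" = {
      if (!all(dfx > 0)) fail("f'(x)>0")
      if (!unbounded_growth) fail("unbounded-growth")
    }
  )

  list(
    pass = length(violated) == 0,
    violated = violated,
    details = list(
      tag = tag, grid_max = grid_max, n_grid = n_grid,
      f0 = f0, df0 = df0, f_inf = f_inf, f_inf10 = f_inf10
    )
  )
}
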