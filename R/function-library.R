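#' Parametric scalar function families
#'
#' Concrete, nonnegative, continuously differentiable function families that
#' realize the qualitative property tags. Each family carries an analytic
#' derivative; [make_function()] additionally exposes an adaptive
#' central-difference derivative used when only pointwise evaluation is
#' trusted.
#'
#' Families:
#' \describe{
#'   \item{constant}{`c`; constants (nonnegative or strictly positive).}
#'   \item{hill_sigmoid}{`A x^H / (K^H + x^H)`; sigmoidal for `H >= 2`,
#'     saturating increasing (Michaelis-Menten-like) for `H = 1`.}
#'   \item{comp_hill}{`A K^H / (K^H + x^H)`; complementary sigmoid for
#'     `H >= 2`, decreasing asymptotically null for `H = 1`.}
#'   \item{constant_plus_hill}{`c + hill_sigmoid`.}
#'   \item{constant_plus_comp_hill}{`c + comp_hill`.}
#'   \item{mm_saturating}{`V x / (K + x)`; strictly increasing, saturating.}
#'   \item{decreasing_null}{`A K / (K + x)`; strictly decreasing to zero.}
#'   \item{threshold_decreasing}{affine decline `A (1 - x / theta)` blended to
#'     exact zero at `x = theta` by a C1 cubic over `[theta - eps, theta]`,
#'     `eps = theta / 20`, so smoothness holds while the function is exactly
#'     null above the threshold.}
#'   \item{linear_unbounded}{`slope * x`; increasing and unbounded.}
#' }
#' @name function_families
NULL

fam_registry <- function() {
  list(
    constant = list(
      defaults = list(c = 1),
      check = function(p) {
        if (!is.numeric(p$c) || p$c < 0) stop("constant: c must be >= 0", call. = FALSE)
      },
      tag = function(p) if (p$c > 0) "positive-constant" else "nonnegative-constant",
      scale = function(p) 1,
      f = function(p) function(x) rep(p$c, length(x)),
      df = function(p) function(x) rep(0, length(x))
    ),
    hill_sigmoid = list(
      defaults = list(K = 1, H = 2, A = 1),
      check = function(p) {
        if (p$K <= 0) stop("hill_sigmoid: K must be > 0", call. = FALSE)
        if (p$H < 1) stop("hill_sigmoid: H must be >= 1", call. = FALSE)
        if (p$A < 0) stop("hill_sigmoid: amplitude must be >= 0", call. = FALSE)
      },
      tag = function(p) if (p$H >= 2) "sigmoidal" else "increasing-asymptotically-constant",
      scale = function(p) p$K,
      f = function(p) function(x) {
        r <- (x / p$K)^p$H
        p$A * r / (1 + r)
      },
      df = function(p) function(x) {
        r <- (x / p$K)^p$H
        out <- p$A * p$H * r / (x * (1 + r)^2)
        out[x == 0] <- if (p$H > 1) 0 else p$A / p$K
        out
      }
    ),
    comp_hill = list(
      defaults = list(K = 1, H = 2, A = 1),
      check = function(p) {
        if (p$K <= 0) stop("comp_hill: K must be > 0", call. = FALSE)
        if (p$H < 1) stop("comp_hill: H must be >= 1", call. = FALSE)
        if (p$A < 0) stop("comp_hill: amplitude must be >= 0", call. = FALSE)
      },
      tag = function(p) if (p$H >= 2) "complementary-sigmoidal" else "decreasing-asymptotically-null",
      scale = function(p) p$K,
      f = function(p) function(x) {
        r <- (x / p$K)^p$H
        p$A / (1 + r)
      },
      df = function(p) function(x) {
        r <- (x / p$K)^p$H
        out <- -p$A * p$H * r / (x * (1 + r)^2)
        out[x == 0] <- if (p$H > 1) 0 else -p$A / p$K
        out
      }
    ),
    constant_plus_hill = list(
      defaults = list(c = 1, K = 1, H = 2, A = 1),
      check = function(p) {
        if (p$c <= 0) stop("constant_plus_hill: c must be > 0", call. = FALSE)
        if (p$K <= 0 || p$H < 2 || p$A < 0) {
          stop("constant_plus_hill: need K > 0, H >= 2, amplitude >= 0", call. = FALSE)
        }
      },
      tag = function(p) "constant-sigmoidal",
      scale = function(p) p$K,
      f = function(p) function(x) {
        r <- (x / p$K)^p$H
        p$c + p$A * r / (1 + r)
      },
      df = function(p) function(x) {
        r <- (x / p$K)^p$H
        out <- p$A * p$H * r / (x * (1 + r)^2)
        out[x == 0] <- 0
        out
      }
    ),
    constant_plus_comp_hill = list(
      defaults = list(c = 1, K = 1, H = 2, A = 1),
      check = function(p) {
        if (p$c < 0) stop("constant_plus_comp_hill: c must be >= 0", call. = FALSE)
        if (p$K <= 0 || p$H < 2 || p$A <= 0) {
          stop("constant_plus_comp_hill: need K > 0, H >= 2, amplitude > 0", call. = FALSE)
        }
      },
      tag = function(p) "constant-complementary-sigmoidal",
      scale = function(p) p$K,
      f = function(p) function(x) {
        r <- (x / p$K)^p$H
        p$c + p$A / (1 + r)
      },
      df = function(p) function(x) {
        r <- (x / p$K)^p$H
        out <- -p$A * p$H * r / (x * (1 + r)^2)
        out[x == 0] <- 0
        out
      }
    ),
    mm_saturating = list(
      defaults = list(V = 1, K = 1),
      check = function(p) {
        if (p$V <= 0 || p$K <= 0) stop("mm_saturating: need V > 0, K > 0", call. = FALSE)
      },
      tag = function(p) "increasing-asymptotically-constant",
      scale = function(p) p$K,
      f = function(p) function(x) p$V * x / (p$K + x),
      df = function(p) function(x) p$V * p$K / (p$K + x)^2
    ),
    decreasing_null = list(
      defaults = list(A = 1, K = 1),
      check = function(p) {
        if (p$A <= 0 || p$K <= 0) stop("decreasing_null: need A > 0, K > 0", call. = FALSE)
      },
      tag = function(p) "decreasing-asymptotically-null",
      scale = function(p) p$K,
      f = function(p) function(x) p$A * p$K / (p$K + x),
      df = function(p) function(x) -p$A * p$K / (p$K + x)^2
    ),
    threshold_decreasing = list(
      defaults = list(A = 1, theta = 1),
      check = function(p) {
        if (p$A <= 0 || p$theta <= 0) {
          stop("threshold_decreasing: need A > 0, theta > 0", call. = FALSE)
        }
      },
      tag = function(p) "decreasing-exactly-null",
      scale = function(p) p$theta,
      f = function(p) function(x) hinge_smooth(x, p$A, p$theta)$f,
      df = function(p) function(x) hinge_smooth(x, p$A, p$theta)$df
    ),
    linear_unbounded = list(
      defaults = list(slope = 1),
      check = function(p) {
        if (p$slope <= 0) stop("linear_unbounded: slope must be > 0", call. = FALSE)
      },
      tag = function(p) "increasing-asymptotically-unbounded",
      scale = function(p) 1,
      f = function(p) function(x) p$slope * x,
      df = function(p) function(x) rep(p$slope, length(x))
    )
  )
}

# C1 smoothed hinge: affine A(1 - x/theta) for x <= theta - eps, cubic Hermite
# blend to (0, slope 0) at theta, identically zero beyond.  eps = theta/20.
hinge_smooth <- function(x, A, theta) {
  eps <- theta / 20
  xl <- theta - eps
  f <- numeric(length(x))
  df <- numeric(length(x))
  lin <- x <= xl
  f[lin] <- A * (1 - x[lin] / theta)
  df[lin] <- -A / theta
  mid <- x > xl & x < theta
  if (any(mid)) {
    t <- (x[mid] - xl) / eps
    v0 <- A * eps / theta
    m0 <- -A / theta
    # Hermite basis with right value/slope = 0.
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    f[mid] <- v0 * h00 + eps * m0 * h10
    dh00 <- 6 * t^2 - 6 * t
    dh10 <- 3 * t^2 - 4 * t + 1
    df[mid] <- (v0 * dh00 + eps * m0 * dh10) / eps
  }
  list(f = f, df = df)
}

#' Create a parametric function
#'
#' @param family one of the family ids in [function_families].
#' @param parameters named list of family parameters; omitted entries take the
#'   family defaults.
#' @param tag claimed property tag; defaults to the family's natural tag given
#'   the parameters (e.g. `hill_sigmoid` with `H = 1` is claimed
#'   `increasing-asymptotically-constant`, not `sigmoidal`).
#' @return an object of class `parametric_fn`: callable pieces `$fn(x)`
#'   (vectorized), `$deriv(x)` (analytic), `$num_deriv(x)` (central
#'   differences), with `$family`, `$parameters`, `$tag`, `$scale`.
#' @examples
#' f <- make_function("hill_sigmoid", list(K = 1, H = 2))
#' f$fn(1) # 0.5
#' @export
make_function <- function(family, parameters = list(), tag = NULL) {
  reg <- fam_registry()
  if (!family %in% names(reg)) {
    stop("unknown function family: ", family, call. = FALSE)
  }
  fam <- reg[[family]]
  p <- utils::modifyList(fam$defaults, parameters)
  fam$check(p)
  fn <- fam$f(p)
  structure(
    list(
      family = family,
      parameters = p,
      tag = assert_tag(tag %||% fam$tag(p)),
      scale = fam$scale(p),
      fn = fn,
      deriv = fam$df(p),
      num_deriv = function(x) vapply(x, function(xx) num_deriv(fn, xx), numeric(1))
    ),
    class = "parametric_fn"
  )
}

#' @export
print.parametric_fn <- function(x, ...) {
  cat("<parametric_fn> ", x$family, "(",
      paste(names(x$parameters), unlist(x$parameters), sep = "=", collapse = ", "),
      ") tag: ", x$tag, "\n", sep = "")
  invisible(x)
}

#' Default function family for each property tag
#'
#' Used by the ensemble sampler; each tag maps to one or more families whose
#' admissible parameterizations realize it.
#' @keywords internal
tag_families <- function(tag) {
  switch(tag,
    "nonnegative-constant" = "constant",
    "positive-constant" = "constant",
    "sigmoidal" = "hill_sigmoid",
    "complementary-sigmoidal" = "comp_hill",
    "constant-sigmoidal" = "constant_plus_hill",
    "constant-complementary-sigmoidal" = "constant_plus_comp_hill",
    "increasing-asymptotically-constant" = "mm_saturating",
    "decreasing-asymptotically-null" = "decreasing_null",
    "decreasing-exactly-null" = "threshold_decreasing",
    "increasing-asymptotically-unbounded" = "linear_unbounded",
    stop("unknown property tag: ", tag, call. = FALSE)
  )
}
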