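# Internal numerical helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive an independent sub-seed from a master seed
#'
#' Counter-based splitting: each `(seed, index)` pair maps to its own 31-bit
#' sub-seed, so adding draws for one instance never perturbs another.
#'
#' @param seed master integer seed.
#' @param index nonnegative integer counter.
#' @return an integer seed below 2^31.
#' @export
split_seed <- function(seed, index) {
  # Weyl-style integer mixing kept within double-exact range (< 2^53).
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  k <- (as.numeric(index) %% 2147483647)
  h <- (s * 2654435761 + k * 40503 + 97) %% 2147483629
  h <- (h * 69069 + 1234567) %% 2147483629
  as.integer(h %% 2147483587 + 1)
}

# Halton low-discrepancy sequence in [0,1]^d (bases: first d primes).
halton_seq <- function(n, d, skip = 20) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  stopifnot(d <= length(primes))
  one <- function(i, b) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / b
      r <- r + f * (i %% b)
      i <- i %/% b
    }
    r
  }
  idx <- seq_len(n) + skip
  sapply(seq_len(d), function(j) vapply(idx, one, numeric(1), b = primes[j]))
}

# Central-difference derivative with adaptive step.
num_deriv <- function(f, x, h = NULL) {
  if (is.null(h)) h <- .Machine$double.eps^(1/3) * (1 + abs(x))
  (f(x + h) - f(x - h)) / (2 * h)
}

# Central-difference Jacobian of a vector field at x.
num_jacobian <- function(fn, x, fd_step = NULL) {
  n <- length(x)
  m <- length(fn(x))
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    h <- if (is.null(fd_step)) sqrt(.Machine$double.eps) * (1 + abs(x[j])) else fd_step
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

# Uniform seeded samples in a box given as 2 x n matrix (rows: lower, upper).
# Nested: the first k rows for a given seed are a prefix of the first k' > k.
box_samples <- function(n, box, seed) {
  d <- ncol(box)
  u <- with_seed(seed, matrix(stats::runif(n * d), nrow = n, ncol = d))
  sweep(sweep(u, 2, box[2, ] - box[1, ], "*"), 2, box[1, ], "+")
}

as_box <- function(box, n) {
  if (is.matrix(box)) {
    stopifnot(nrow(box) == 2, ncol(box) == n)
    return(box)
  }
  rbind(rep(0, n), rep(box, length.out = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
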