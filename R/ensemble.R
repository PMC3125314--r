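#' Sampling configuration for random instantiation
#'
#' Ranges are log-uniform over decades (so regimes of qualitatively different
#' scale are equally represented); Hill exponents are integer-uniform, with a
#' minimum of 2 wherever a zero slope at the origin is part of the tag.
#'
#' @param rate range for amplitudes, constants, maximal velocities and slopes.
#' @param threshold range for half-saturation constants and thresholds.
#' @param hill integer range for Hill exponents.
#' @return a `sampling_config` list.
#' @export
sampling_config <- function(rate = c(1e-2, 1e2), threshold = c(1e-2, 1e2),
                            hill = c(1L, 4L)) {
  stopifnot(rate[1] > 0, threshold[1] > 0, hill[1] >= 1)
  structure(list(rate = rate, threshold = threshold, hill = hill),
            class = "sampling_config")
}

r_log_unif <- function(range) exp(stats::runif(1, log(range[1]), log(range[2])))

# Draw a parametric function realizing `tag` under `config`; called inside a
# seeded context.
draw_function <- function(tag, config) {
  fam <- tag_families(tag)
  p <- switch(fam,
    constant = list(c = if (tag == "nonnegative-constant") {
      r_log_unif(config$rate)
    } else r_log_unif(config$rate)),
    hill_sigmoid = list(K = r_log_unif(config$threshold),
                        H = sample(seq(max(2L, config$hill[1]), max(2L, config$hill[2])), 1),
                        A = r_log_unif(config$rate)),
    comp_hill = list(K = r_log_unif(config$threshold),
                     H = sample(seq(max(2L, config$hill[1]), max(2L, config$hill[2])), 1),
                     A = r_log_unif(config$rate)),
    constant_plus_hill = list(c = r_log_unif(config$rate),
                              K = r_log_unif(config$threshold),
                              H = sample(seq(max(2L, config$hill[1]), max(2L, config$hill[2])), 1),
                              A = r_log_unif(config$rate)),
    constant_plus_comp_hill = list(c = r_log_unif(config$rate),
                                   K = r_log_unif(config$threshold),
                                   H = sample(seq(max(2L, config$hill[1]), max(2L, config$hill[2])), 1),
                                   A = r_log_unif(config$rate)),
    mm_saturating = list(V = r_log_unif(config$rate), K = r_log_unif(config$threshold)),
    decreasing_null = list(A = r_log_unif(config$rate), K = r_log_unif(config$threshold)),
    threshold_decreasing = list(A = r_log_unif(config$rate),
                                theta = r_log_unif(config$threshold)),
    linear_unbounded = list(slope = r_log_unif(config$rate))
  )
  make_function(fam, p, tag = tag)
}

#' Randomly instantiate a qualitative model
#'
#' Assigns one concrete parametric function to every tagged slot of every
#' term. Slots of terms sharing a `coupling` label receive the identical
#' function object (same family, same parameters). Instantiation is a pure
#' function of `(model, config, seed)`.
#'
#' @param model a validated [network_model()].
#' @param config a [sampling_config()].
#' @param seed integer seed.
#' @return an object of class `concrete_instance`: `$functions[[term]][[slot]]`
#'   parametric functions, plus `$model`, `$seed`, `$config`.
#' @export
sample_instance <- function(model, config = sampling_config(), seed = 1L) {
  groups <- list() # coupling label -> drawn slot functions
  fns <- vector("list", length(model$terms))
  names(fns) <- names(model$terms)
  counter <- 0L
  for (lab in names(model$terms)) {
    tm <- model$terms[[lab]]
    if (!is.null(tm$coupling) && !is.null(groups[[tm$coupling]])) {
      shared <- groups[[tm$coupling]]
      if (!identical(vapply(shared, function(f) f$tag, character(1)), tm$tags)) {
        stop("coupled terms '", tm$coupling, "' have mismatched tags", call. = FALSE)
      }
      fns[[lab]] <- shared
      next
    }
    counter <- counter + 1L
    slot_fns <- with_seed(split_seed(seed, counter), {
      lapply(tm$tags, draw_function, config = config)
    })
    fns[[lab]] <- slot_fns
    if (!is.null(tm$coupling)) groups[[tm$coupling]] <- slot_fns
  }
  new_instance(model, fns, seed = seed, config = config)
}

new_instance <- function(model, functions, seed = NA_integer_, config = NULL) {
  structure(
    list(model = model, functions = functions, seed = seed, config = config),
    class = "concrete_instance"
  )
}

#' Manually instantiate a model with explicit functions
#'
#' @param model a [network_model()].
#' @param functions named list (by term label) of lists of `parametric_fn`
#'   objects, one per tagged slot; coupled terms may name the same objects.
#' @export
manual_instance <- function(model, functions) {
  missing <- setdiff(names(model$terms), names(functions))
  if (length(missing)) {
    stop("missing functions for terms: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (lab in names(model$terms)) {
    tm <- model$terms[[lab]]
    fl <- functions[[lab]]
    if (!is.list(fl) || length(fl) != length(tm$tags)) {
      stop("term '", lab, "' needs ", length(tm$tags), " slot function(s)", call. = FALSE)
    }
    for (k in seq_along(fl)) {
      if (!inherits(fl[[k]], "parametric_fn")) {
        stop("term '", lab, "' slot ", k, " is not a parametric_fn", call. = FALSE)
      }
      if (fl[[k]]$tag != tm$tags[k]) {
        stop("term '", lab, "' slot ", k, ": function tag '", fl[[k]]$tag,
             "' does not match term tag '", tm$tags[k], "'", call. = FALSE)
      }
    }
  }
  new_instance(model, functions[names(model$terms)])
}

#' @export
print.concrete_instance <- function(x, ...) {
  cat("<concrete_instance> of", x$model$name, "with", length(x$functions),
      "terms; seed:", x$seed, "\n")
  invisible(x)
}

#' Verify every assigned function against its term's tag
#'
#' Also spot-checks the null-at-lower-saturation identity for flagged
#' degradation terms and absorbed products: the coefficient is evaluated at
#' 10 grid values with the target species at zero.
#'
#' @param instance a `concrete_instance`.
#' @return list with `pass` and tibble `report`.
#' @export
validate_instance <- function(instance) {
  model <- instance$model
  rows <- purrr::map(names(model$terms), function(lab) {
    tm <- model$terms[[lab]]
    viol <- character(0)
    for (k in seq_along(tm$tags)) {
      vr <- verify_property(instance$functions[[lab]][[k]], tm$tags[k])
      if (!vr$pass) {
        viol <- c(viol, paste0("slot ", k, " fails tag '", tm$tags[k], "': ",
                               paste(vr$violated, collapse = "; ")))
      }
    }
    if ((tm$a5 || tm$absorbed) && any(tm$args %in% tm$target)) {
      kk <- which(tm$args %in% tm$target)[1]
      f <- instance$functions[[lab]][[kk]]
      if (abs(f$fn(0)) > 1e-9) {
        viol <- c(viol, "A5: coefficient does not vanish when the target is 0")
      }
    }
    tibble::tibble(term = lab, ok = length(viol) == 0, violations = list(viol))
  })
  report <- dplyr::bind_rows(rows)
  list(pass = all(report$ok), report = report)
}

#' Generate a seeded ensemble of concrete instances
#'
#' The computational realization of a family of admissible systems: `n`
#' independent instances with sub-seeds derived from `seed` by counter-based
#' splitting, so the ensemble is a pure function of
#' `(model, config, n, seed)` and inserting extra draws for one member never
#' perturbs the others.
#'
#' @inheritParams sample_instance
#' @param n ensemble size.
#' @return list of `concrete_instance` objects.
#' @export
generate_ensemble <- function(model, n, config = sampling_config(), seed = 1L) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    sample_instance(model, config, seed = split_seed(seed, 1000L + i))
  })
}

#' Extract the flat parameter record of an instance (for replay/serialization)
#' @param instance a `concrete_instance`.
#' @return a tibble with term, slot, family, tag and one row per parameter.
#' @export
instance_parameters <- function(instance) {
  purrr::imap_dfr(instance$functions, function(slots, lab) {
    purrr::imap_dfr(slots, function(f, k) {
      tibble::tibble(term = lab, slot = k, family = f$family, tag = f$tag,
                     parameter = names(f$parameters),
                     value = as.numeric(unlist(f$parameters)))
    })
  })
}
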