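#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a certificate report
#'
#' @param x a `certificate_report`.
#' @param ... unused.
#' @return one-row tibble: `kind`, `holds`, `worst_margin`, `estimated_rate`,
#'   `n_samples`, `seed`.
#' @method tidy certificate_report
#' @export
tidy.certificate_report <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    holds = x$holds,
    worst_margin = x$worst_margin,
    estimated_rate = x$estimated_rate,
    n_samples = x$n_samples,
    seed = x$seed
  )
}

#' @rdname tidy.certificate_report
#' @method glance certificate_report
#' @export
glance.certificate_report <- function(x, ...) tidy.certificate_report(x, ...)

#' Tidy an equilibrium set
#'
#' Expands the eigenvalue list-column into a long tibble of spectral
#' information, one row per (equilibrium, eigenvalue).
#'
#' @param x a `robnet_equilibria` tibble.
#' @param ... unused.
#' @method tidy robnet_equilibria
#' @export
tidy.robnet_equilibria <- function(x, ...) {
  if (!nrow(x)) {
    return(tibble::tibble(equilibrium = integer(0), class = character(0),
                          residual = numeric(0), re = numeric(0), im = numeric(0)))
  }
  purrr::imap_dfr(x$eigenvalues, function(ev, i) {
    tibble::tibble(equilibrium = i, class = x$class[i], residual = x$residual[i],
                   re = Re(ev), im = Im(ev))
  })
}

#' @rdname tidy.robnet_equilibria
#' @method glance robnet_equilibria
#' @export
glance.robnet_equilibria <- function(x, ...) {
  tibble::tibble(
    n_equilibria = nrow(x),
    n_stable = sum(x$class == "stable"),
    n_unstable = sum(x$class == "unstable"),
    n_marginal = sum(x$class == "marginal"),
    max_residual = if (nrow(x)) max(x$residual) else NA_real_
  )
}

#' Plot a simulated trajectory
#'
#' @param object a [simulate()] tibble.
#' @param ... unused.
#' @return a ggplot: one line per state over time.
#' @method autoplot robnet_trajectory
#' @export
autoplot.robnet_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "state", values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$concentration,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration")
}

#' Plot a steady-state response curve
#'
#' @param object a [response_curve()] tibble.
#' @param state state to plot (default: first).
#' @param ... unused.
#' @return a ggplot of the equilibrium branches against the input, with
#'   point shape by stability class.
#' @method autoplot robnet_response
#' @export
autoplot.robnet_response <- function(object, state = NULL, ...) {
  snames <- setdiff(names(object), c("u", "branch", "residual", "class"))
  state <- state %||% snames[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$u, y = .data[[state]],
                                       group = .data$branch,
                                       linetype = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$class)) +
    ggplot2::labs(x = "input", y = paste0(state, "*"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
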