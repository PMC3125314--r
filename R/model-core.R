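#' Build an interaction term of a qualitative network model
#'
#' A model aggregates, for each state `i`, signed contributions of four kinds:
#' production coefficients multiplying a source species (`a`), degradation or
#' conversion coefficients multiplying a species (`b`), saturating production
#' terms (`c`) and decreasing saturating production terms (`d`). The scalar
#' coefficient of a term is a product of tagged unary functions, one per entry
#' of `args`; constant factors are arg-less slots (`args = NA`).
#'
#' @param target name of the state the term contributes to.
#' @param kind one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param mult for `a`/`b` terms, the state or input the coefficient
#'   multiplies.
#' @param args character vector of states/inputs read by the coefficient
#'   (use `NA` for a constant factor); `c`/`d` terms must have at least one.
#' @param tags property tags, one per entry of `args`.
#' @param coupling optional label; terms sharing a label are instantiated with
#'   the identical function and parameters.
#' @param absorbed for self-degradation `b` terms only: the tagged function is
#'   the whole product `g(x_i) = b(x_i) x_i` (it must vanish at 0), and the
#'   term contributes `-g(x_i)` directly. Used when the saturating product,
#'   not the bare coefficient, is the qualitatively characterized object.
#' @param a5 flag a `b` term whose coefficient must be null when the target
#'   species is at zero (checked numerically on instances).
#' @param label optional term label (auto-generated otherwise).
#' @return an object of class `network_term`.
#' @export
term <- function(target, kind, mult = NULL, args = NA_character_, tags,
                 coupling = NULL, absorbed = FALSE, a5 = FALSE, label = NULL) {
  stopifnot(kind %in% c("a", "b", "c", "d"))
  if (kind %in% c("a", "b") && is.null(mult)) {
    stop("a/b terms need a `mult` species", call. = FALSE)
  }
  if (length(args) != length(tags)) {
    stop("one tag per argument is required", call. = FALSE)
  }
  for (tg in tags) assert_tag(tg)
  if (absorbed && kind != "b") stop("absorbed form is only for b terms", call. = FALSE)
  structure(
    list(target = target, kind = kind, mult = mult, args = as.character(args),
         tags = as.character(tags), coupling = coupling, absorbed = absorbed,
         a5 = a5, label = label),
    class = "network_term"
  )
}

#' Build a qualitative network model
#'
#' @param states character vector of state names.
#' @param terms list of [term()] objects.
#' @param inputs character vector of input names (treated as constant
#'   pseudo-states unless a time function is bound at assembly).
#' @param name,notes free-text metadata.
#' @param conserved optional list of conserved-sum descriptors
#'   (`list(states = <names>, label = <chr>)`) recorded as metadata.
#' @return an object of class `network_model`.
#' @export
network_model <- function(states, terms, inputs = character(0),
                          name = "model", notes = "", conserved = NULL) {
  labels <- vapply(seq_along(terms), function(i) {
    tm <- terms[[i]]
    tm$label %||% paste0(tm$kind, "_", tm$target, "_", i)
  }, character(1))
  if (anyDuplicated(labels)) stop("duplicate term labels", call. = FALSE)
  for (i in seq_along(terms)) terms[[i]]$label <- labels[i]
  names(terms) <- labels
  structure(
    list(states = states, inputs = inputs, terms = terms,
         name = name, notes = notes, conserved = conserved),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", x$name, ": ", length(x$states), " states (",
      paste(x$states, collapse = ", "), ")",
      if (length(x$inputs)) paste0(", inputs: ", paste(x$inputs, collapse = ", ")),
      ", ", length(x$terms), " terms\n", sep = "")
  invisible(x)
}

model_vars <- function(model) c(model$states, model$inputs)

#' Validate a qualitative model against the structural assumptions
#'
#' Checks, term by term: that all referenced species exist (structural
#' errors); that tags are compatible with the term kind — saturating
#' production (`c`) terms must be non-decreasing with a positive upper
#' saturation, decreasing production (`d`) terms non-increasing with a
#' positive value at zero; that absorbed degradation products carry an
#' increasing tag vanishing at zero; and that off-target degradation terms
#' are flagged for the null-at-lower-saturation identity. The check is
#' idempotent and side-effect free.
#'
#' @param model a [network_model()].
#' @return a list with `pass` and a tibble `report` (term, ok, violations).
#' @export
validate_model <- function(model) {
  vars <- model_vars(model)
  rows <- purrr::map(model$terms, function(tm) {
    viol <- character(0)
    structural <- character(0)
    if (!tm$target %in% model$states) {
      structural <- c(structural, paste0("unknown target '", tm$target, "'"))
    }
    if (!is.null(tm$mult) && !tm$mult %in% vars) {
      structural <- c(structural, paste0("unknown mult '", tm$mult, "'"))
    }
    for (a in tm$args) {
      if (!is.na(a) && !a %in% vars) {
        structural <- c(structural, paste0("unknown argument '", a, "'"))
      }
    }
    if (length(structural)) {
      return(tibble::tibble(term = tm$label, ok = FALSE,
                            violations = list(structural), structural = TRUE))
    }
    dirs <- vapply(tm$tags, tag_direction, character(1))
    if (tm$kind == "c") {
      if (any(dirs == "non-increasing")) {
        viol <- c(viol, "A4: c-kind terms must be non-decreasing in their arguments")
      }
    }
    if (tm$kind == "d") {
      if (any(dirs == "non-decreasing")) {
        viol <- c(viol, "A4: d-kind terms must be non-increasing in their arguments")
      }
      if (all(is.na(tm$args))) {
        viol <- c(viol, "A4: d-kind terms must read at least one species")
      }
    }
    if (tm$absorbed) {
      if (!identical(tm$mult, tm$target)) {
        viol <- c(viol, "absorbed b terms must multiply their own target")
      }
      if (!any(tm$args %in% tm$target)) {
        viol <- c(viol, "A5: absorbed degradation must read the target (and vanish at 0)")
      }
    }
    if (tm$kind == "b" && !tm$absorbed && !identical(tm$mult, tm$target)) {
      # degradation of another species: must be null when the target is 0
      if (!tm$a5) {
        viol <- c(viol, "A5: off-target b term lacks the null-at-lower-saturation flag")
      } else if (!any(tm$args %in% tm$target)) {
        viol <- c(viol, "A5: flagged b term must read the target species")
      } else {
        tgt_tags <- tm$tags[tm$args %in% tm$target]
        if (!any(vapply(tgt_tags, tag_zero_at_zero, logical(1)) |
                 tgt_tags == "increasing-asymptotically-constant")) {
          viol <- c(viol, "A5: flagged b term needs a zero-at-zero tag on the target argument")
        }
      }
    }
    tibble::tibble(term = tm$label, ok = length(viol) == 0,
                   violations = list(viol), structural = FALSE)
  })
  report <- dplyr::bind_rows(rows)
  orphan <- setdiff(model$states,
                    vapply(model$terms, function(tm) tm$target, character(1)))
  pass <- all(report$ok) && length(orphan) == 0
  list(pass = pass, report = report, orphan_states = orphan)
}
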