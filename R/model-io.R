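#' Typed interaction graph of a qualitative model
#'
#' One solid arc per term (labelled `a`, `b`, `c` or `d`), from the species
#' the term reads or multiplies into its target; additional coefficient
#' arguments become dashed modulation arcs. Inputs form a distinct node
#' class. Aggregate membership (from conserved-pool metadata) is attached as
#' a vertex attribute.
#'
#' @param model a [network_model()].
#' @return an `igraph` with vertex attributes `type` ("state"/"input"),
#'   `aggregate`, and edge attributes `kind`, `dashed`, `term`.
#' @seealso [graph_edges()] for the plain edge-list tibble.
#' @export
build_graph <- function(model) {
  edges <- graph_edges(model)
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "kind", "dashed", "term")],
    directed = TRUE,
    vertices = data.frame(
      name = model_vars(model),
      type = c(rep("state", length(model$states)), rep("input", length(model$inputs)))
    )
  )
  agg <- rep(NA_character_, length(model_vars(model)))
  names(agg) <- model_vars(model)
  for (cs in model$conserved %||% list()) {
    agg[cs$states] <- cs$label %||% paste(cs$states, collapse = "+")
  }
  igraph::V(g)$aggregate <- agg[igraph::V(g)$name]
  g
}

#' Edge list of the typed interaction graph
#' @param model a [network_model()].
#' @return tibble with `source`, `target`, `kind`, `dashed`, `term`.
#' @export
graph_edges <- function(model) {
  rows <- purrr::map(model$terms, function(tm) {
    args <- tm$args[!is.na(tm$args)]
    if (tm$kind %in% c("a", "b")) {
      src <- if (!identical(tm$mult, tm$target)) {
        tm$mult
      } else if (length(setdiff(args, tm$target))) {
        setdiff(args, tm$target)[1]
      } else tm$target
    } else {
      if (!length(args)) return(NULL) # constant production: no arc source
      src <- args[1]
    }
    solid <- tibble::tibble(source = src, target = tm$target, kind = tm$kind,
                            dashed = FALSE, term = tm$label)
    mods <- setdiff(args, c(src, tm$target))
    if (length(mods)) {
      solid <- dplyr::bind_rows(
        solid,
        tibble::tibble(source = mods, target = tm$target, kind = tm$kind,
                       dashed = TRUE, term = tm$label)
      )
    }
    solid
  })
  dplyr::bind_rows(rows)
}

#' Read a qualitative model from YAML
#'
#' Schema: top-level `states`, `inputs`, `name`, `notes`, optional
#' `conserved`, and `terms`, each with `target`, `kind`, optional `mult`,
#' `args` (list; `~` for a constant factor), `tags` (one per arg),
#' optional `coupling`, `absorbed`, `a5`, `label`.
#'
#' @param path YAML file.
#' @param validate run [validate_model()] and stop on failure (default TRUE).
#' @return a [network_model()].
#' @export
read_model <- function(path, validate = TRUE) {
  y <- yaml::read_yaml(path)
  for (k in c("states", "terms")) {
    if (is.null(y[[k]])) stop("model YAML missing field '", k, "'", call. = FALSE)
  }
  terms <- lapply(y$terms, function(tl) {
    if (is.null(tl$target) || is.null(tl$kind)) {
      stop("term missing 'target' or 'kind'", call. = FALSE)
    }
    args <- vapply(tl$args %||% list(NULL),
                   function(a) if (is.null(a)) NA_character_ else as.character(a),
                   character(1))
    tags <- as.character(unlist(tl$tags))
    for (tg in tags) {
      if (!tg %in% property_tags) {
        stop("unknown tag '", tg, "' in term targeting '", tl$target, "'", call. = FALSE)
      }
    }
    term(target = tl$target, kind = tl$kind, mult = tl$mult,
         args = args, tags = tags, coupling = tl$coupling,
         absorbed = isTRUE(tl$absorbed), a5 = isTRUE(tl$a5), label = tl$label)
  })
  conserved <- lapply(y$conserved %||% list(), function(cs) {
    list(states = as.character(unlist(cs$states)), label = cs$label)
  })
  m <- network_model(states = as.character(unlist(y$states)), terms = terms,
                     inputs = as.character(unlist(y$inputs %||% list())),
                     name = y$name %||% "model", notes = y$notes %||% "",
                     conserved = if (length(conserved)) conserved else NULL)
  if (validate) {
    v <- validate_model(m)
    if (!v$pass) {
      bad <- v$report[!v$report$ok, ]
      stop("model fails validation: ",
           paste(unlist(bad$violations), collapse = "; "), call. = FALSE)
    }
  }
  m
}

#' Write a qualitative model to YAML
#' @param model a [network_model()].
#' @param path output file.
#' @export
write_model <- function(model, path) {
  y <- list(
    name = model$name,
    states = as.list(model$states),
    inputs = as.list(model$inputs),
    notes = model$notes,
    terms = unname(lapply(model$terms, function(tm) {
      tl <- list(
        label = tm$label, target = tm$target, kind = tm$kind,
        args = lapply(tm$args, function(a) if (is.na(a)) NULL else a),
        tags = as.list(tm$tags)
      )
      if (!is.null(tm$mult)) tl$mult <- tm$mult
      if (!is.null(tm$coupling)) tl$coupling <- tm$coupling
      if (tm$absorbed) tl$absorbed <- TRUE
      if (tm$a5) tl$a5 <- TRUE
      tl
    }))
  )
  if (!is.null(model$conserved)) {
    y$conserved <- lapply(model$conserved, function(cs) {
      list(states = as.list(cs$states), label = cs$label)
    })
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Serialize a concrete instance to JSON for exact replay
#' @param instance a `concrete_instance`.
#' @param path output file.
#' @export
write_instance_json <- function(instance, path) {
  obj <- list(
    model = instance$model$name,
    seed = instance$seed,
    functions = lapply(instance$functions, function(slots) {
      lapply(slots, function(f) {
        list(family = f$family, tag = f$tag, parameters = f$parameters)
      })
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a concrete instance from its JSON serialization
#' @param model the [network_model()] the instance was built for.
#' @param path JSON file from [write_instance_json()].
#' @export
read_instance_json <- function(model, path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$model, model$name)) {
    stop("instance JSON is for model '", obj$model, "'", call. = FALSE)
  }
  fns <- lapply(obj$functions, function(slots) {
    lapply(slots, function(s) {
      make_function(s$family, lapply(s$parameters, as.numeric), tag = s$tag)
    })
  })
  inst <- manual_instance(model, fns)
  inst$seed <- obj$seed
  inst
}

#' Write a trajectory to RFC-4180 CSV
#' @param trajectory a [simulate()] tibble.
#' @param path output file.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
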