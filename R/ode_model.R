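# Mass-action ODE model description: components with signed product terms
# (rate-constant symbol times species factors, optional Hill/MM
# saturation) plus initial values. This is the input of both the
# influence-graph translator and the reference integrator.

#' Create an ODE term
#'
#' One signed product term of a component's derivative:
#' `sign * rate * prod(factors) * S^n / (km^n + S^n)` where the trailing
#' Hill factor is present only when `saturation` is given.
#'
#' @param sign `+1` or `-1`.
#' @param rate Rate-constant symbol (e.g. `"k1a"`, `"k2basal"`).
#' @param factors Character vector (possibly empty) of species names whose
#'   product multiplies the rate.
#' @param saturation Optional list `list(substrate=, km=, n=)` marking a
#'   saturating factor `S^n / (km^n + S^n)`: `substrate` is a species
#'   name, `km` and `n` are parameter symbols. At most one per term.
#' @return A list of class `ode_term`.
#' @export
ode_term <- function(sign, rate, factors = character(), saturation = NULL) {
  stopifnot(sign %in% c(-1, 1), is.character(rate), length(rate) == 1L,
            is.character(factors))
  if (!is.null(saturation)) {
    stopifnot(is.list(saturation),
              all(c("substrate", "km", "n") %in% names(saturation)))
    saturation <- saturation[c("substrate", "km", "n")]
  }
  structure(list(sign = as.integer(sign), rate = rate,
                 factors = as.character(factors), saturation = saturation),
            class = "ode_term")
}

#' Create an ODE component
#'
#' @param name Species name.
#' @param initial Initial value in `[0, 1]`.
#' @param terms List of [ode_term()] records; empty only for clamped
#'   inputs (species with no update expression).
#' @return A list of class `ode_component`.
#' @export
ode_component <- function(name, initial = 0, terms = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(initial), length(initial) == 1L, is.list(terms))
  terms <- lapply(terms, function(t) {
    if (!inherits(t, "ode_term")) do.call(ode_term, t) else t
  })
  structure(list(name = name, initial = as.numeric(initial), terms = terms),
            class = "ode_component")
}

#' Assemble an ODE model
#'
#' @param components List of [ode_component()] records.
#' @param clamped Character vector naming the clamped inputs (boundary
#'   conditions, never integrated).
#' @param rates Optional named numeric vector of rate/parameter values.
#' @param metadata Named list of provenance strings.
#' @param check Stop on invariant violations (default `TRUE`).
#' @return A list of class `ode_model`.
#' @export
ode_model <- function(components, clamped = character(), rates = numeric(),
                      metadata = list(), check = TRUE) {
  stopifnot(is.list(components), is.character(clamped))
  components <- lapply(components, function(x) {
    if (!inherits(x, "ode_component")) do.call(ode_component, x) else x
  })
  m <- structure(list(components = components, clamped = clamped,
                      rates = rates, metadata = metadata),
                 class = "ode_model")
  if (check) {
    bad <- validate_ode_model(m)
    if (length(bad)) {
      stop("invalid ODE model:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
    }
  }
  m
}

ode_species_names <- function(model) {
  vapply(model$components, `[[`, "", "name")
}

#' Validate an ODE model
#'
#' Checks unique component names, that clamped inputs are declared
#' components, that every term's factors and saturation substrates
#' reference declared components, that each term has at most one
#' saturation descriptor, and that non-clamped components carry at least
#' one term.
#'
#' @param model An `ode_model`.
#' @return Character vector of violations; empty when the model is valid.
#' @export
validate_ode_model <- function(model) {
  v <- character()
  nm <- ode_species_names(model)
  dup <- unique(nm[duplicated(nm)])
  for (d in dup) v <- c(v, sprintf("component '%s': duplicated name", d))
  for (cl in setdiff(model$clamped, nm)) {
    v <- c(v, sprintf("clamped input '%s': not a declared component", cl))
  }
  for (comp in model$components) {
    if (!length(comp$terms) && !comp$name %in% model$clamped) {
      v <- c(v, sprintf("component '%s': no terms and not clamped",
                        comp$name))
    }
    for (t in comp$terms) {
      for (f in setdiff(t$factors, nm)) {
        v <- c(v, sprintf("component '%s', rate %s: unknown factor '%s'",
                          comp$name, t$rate, f))
      }
      if (!is.null(t$saturation) && !t$saturation$substrate %in% nm) {
        v <- c(v, sprintf(
          "component '%s', rate %s: unknown saturation substrate '%s'",
          comp$name, t$rate, t$saturation$substrate))
      }
    }
  }
  v
}

#' Read an ODE model from a JSON file
#'
#' The format mirrors the three columns of a published reaction table:
#' component name, signed product terms and initial value, plus the list
#' of clamped inputs. Exponent/half-max notation is explicit
#' (`saturation: {substrate, km, n}`); ambiguous inline exponent strings
#' are not accepted.
#'
#' @param path Path to an ODE-model JSON file.
#' @return A validated `ode_model`.
#' @export
load_ode_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$components)) {
    stop("ODE model file '", path, "': missing 'components'", call. = FALSE)
  }
  comps <- lapply(doc$components, function(cp) {
    if (is.null(cp$name)) {
      stop("ODE model file '", path, "': component without 'name'",
           call. = FALSE)
    }
    terms <- lapply(cp$terms %||% list(), function(t) {
      for (key in c("sign", "rate")) {
        if (is.null(t[[key]])) {
          stop("ODE model file '", path, "': term in '", cp$name,
               "' has no '", key, "'", call. = FALSE)
        }
      }
      ode_term(sign = t$sign, rate = t$rate,
               factors = as.character(unlist(t$factors)),
               saturation = t$saturation)
    })
    ode_component(cp$name, initial = cp$initial %||% 0, terms = terms)
  })
  ode_model(comps,
            clamped = as.character(unlist(doc$clamped)),
            rates = unlist(doc$rates %||% list()) %||% numeric(),
            metadata = doc$metadata %||% list())
}

#' Write an ODE model to JSON
#' @param model An `ode_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_ode_model <- function(model, path) {
  comps <- lapply(model$components, function(cp) {
    list(name = cp$name, initial = cp$initial,
         terms = lapply(cp$terms, function(t) {
           rec <- list(sign = t$sign, rate = t$rate,
                       factors = as.list(t$factors))
           if (!is.null(t$saturation)) rec$saturation <- t$saturation
           rec
         }))
  })
  doc <- list(schema = "cmap-ode/1", metadata = model$metadata,
              clamped = as.list(model$clamped),
              rates = as.list(model$rates),
              components = comps)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                              digits = NA), path)
  invisible(path)
}

#' Read a rate-assignment file
#'
#' A flat JSON map from parameter symbol (rate constants plus Hill `km`
#' and `n` symbols) to numeric value.
#'
#' @param path Path to a JSON file with a top-level `values` map.
#' @return Named numeric vector.
#' @export
load_rates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$values)) {
    stop("rates file '", path, "': missing 'values'", call. = FALSE)
  }
  unlist(doc$values)
}
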