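# One-to-one translation of mass-action ODE terms into causal influences.
#
# Every signed product term of a derivative becomes exactly one influence
# on that component: the sign carries over, the species factors become the
# (multi-order) source list, the rate constant becomes the influence's
# provenance label, and any Hill/MM saturation factor collapses to its
# bare substrate species (the half-max denominator is dropped and listed
# in the translation report). Numeric rate values are never transferred:
# translated weights are free parameters (placeholder 0.5) to be set by
# search or by hand.

#' Translate a single ODE term into an influence
#'
#' @param term An [ode_term()].
#' @param target Name of the component whose derivative the term belongs
#'   to.
#' @return A [cmap_influence()] with the term's sign, sources equal to the
#'   term's species factors (saturated factor replaced by its substrate,
#'   appended after the plain factors), weight 0.5 and the rate symbol as
#'   label.
#' @examples
#' translate_term(ode_term(-1, "k1a", c("IR", "insulin")), "IR")
#' @export
translate_term <- function(term, target) {
  stopifnot(inherits(term, "ode_term"))
  sources <- term$factors
  if (!is.null(term$saturation)) {
    sources <- c(sources, term$saturation$substrate)
  }
  if (!length(sources)) {
    stop("term with rate '", term$rate, "' on '", target,
         "' has no species factors: not interpretable as an influence",
         call. = FALSE)
  }
  cmap_influence(target = target, sources = sources, weight = 0.5,
                 sign = term$sign, label = term$rate)
}

#' Translate an ODE model into a causal network
#'
#' Produces one influence per ODE term (the counts match exactly), copies
#' initial values, marks components without terms as clamped inputs, and
#' attaches a translation report recording the rate-symbol-to-weight
#' mapping and every dropped saturation denominator. Retrieve the report
#' with [translation_report()].
#'
#' @param model An `ode_model`.
#' @return A `cmap_network` (empty degenerate network for an empty model).
#' @export
translate_model <- function(model) {
  stopifnot(inherits(model, "ode_model"))
  bad <- validate_ode_model(model)
  if (length(bad)) {
    stop("cannot translate invalid model:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  species <- lapply(model$components, function(cp) {
    cmap_species(cp$name, c_init = cp$initial,
                 clamped = cp$name %in% model$clamped ||
                   length(cp$terms) == 0L)
  })
  influences <- list()
  weight_map <- list()
  dropped <- list()
  for (cp in model$components) {
    for (t in cp$terms) {
      inf <- translate_term(t, cp$name)
      influences <- c(influences, list(inf))
      weight_map[[length(weight_map) + 1L]] <- data.frame(
        rate = t$rate, target = cp$name,
        sources = paste(inf$sources, collapse = "*"),
        sign = t$sign, weight = inf$weight)
      if (!is.null(t$saturation)) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          target = cp$name, rate = t$rate,
          substrate = t$saturation$substrate,
          km = t$saturation$km, n = t$saturation$n)
      }
    }
  }
  if (!length(species)) {
    net <- structure(list(species = list(), influences = list(),
                          metadata = list(translated_from = "ode_model")),
                     class = "cmap_network")
  } else {
    net <- cmap_network(species, influences,
                        metadata = list(translated_from = "ode_model"))
  }
  attr(net, "translation_report") <- list(
    weight_map = do.call(rbind, weight_map) %||%
      data.frame(rate = character(), target = character(),
                 sources = character(), sign = integer(),
                 weight = numeric()),
    dropped_saturations = do.call(rbind, dropped) %||%
      data.frame(target = character(), rate = character(),
                 substrate = character(), km = character(),
                 n = character()))
  net
}

#' Retrieve the translation report of a translated network
#'
#' @param net A network returned by [translate_model()].
#' @return List with `weight_map` (one row per translated term: rate
#'   symbol, target, sources, sign, placeholder weight) and
#'   `dropped_saturations` (one row per Hill/MM denominator dropped
#'   during translation).
#' @export
translation_report <- function(net) {
  rep <- attr(net, "translation_report")
  if (is.null(rep)) {
    stop("network carries no translation report", call. = FALSE)
  }
  rep
}

#' Format a translation report as text
#' @param report A report from [translation_report()].
#' @return Character vector of lines.
#' @export
format_translation_report <- function(report) {
  lines <- c("Translation report",
             "==================",
             sprintf("%d term(s) translated to influences.",
                     nrow(report$weight_map)),
             "",
             "rate -> weight mapping (all weights are free parameters):")
  wm <- report$weight_map
  lines <- c(lines, sprintf("  %-10s %s <- %s (%s), weight %.2f",
                            wm$rate, wm$target, wm$sources,
                            ifelse(wm$sign > 0, "+", "-"), wm$weight))
  ds <- report$dropped_saturations
  lines <- c(lines, "",
             sprintf("%d saturation denominator(s) dropped:", nrow(ds)))
  if (nrow(ds)) {
    lines <- c(lines,
               sprintf("  %s (rate %s): %s^%s / (%s^%s + %s^%s) -> %s",
                       ds$target, ds$rate, ds$substrate, ds$n, ds$km,
                       ds$n, ds$substrate, ds$n, ds$substrate))
  }
  lines
}

#' SBML import hook (not implemented)
#'
#' Declared entry point for importing SBML reaction models; this release
#' supports only the native JSON ODE-model format.
#'
#' @param path Path to an SBML file.
#' @export
import_sbml <- function(path) {
  stop("SBML import is unsupported in this release; use the JSON ",
       "ODE-model format (see load_ode_model)", call. = FALSE)
}
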