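#' Create a species record
#'
#' A species (concept) is a node of a causal map. Its value is a
#' dimensionless activity/concentration scaled to `[0, c_max]`.
#'
#' @param name Species name (unique within a network, case-sensitive).
#' @param c_init Initial value, in `[0, c_max]`.
#' @param c_max Upper bound, in `(0, 1]`. Defaults to 1.
#' @param alpha Sensitivity of the causal function for this species, in
#'   `[0.5, 5]`. Larger values give a more switch-like response.
#'   Defaults to 1.2.
#' @param clamped If `TRUE` the species is a boundary condition: it is
#'   never updated by the simulation (e.g. an external input such as
#'   insulin).
#' @param clones Optional character vector of display aliases. Clones are
#'   purely visual labels used by drawing tools to avoid crossing edges;
#'   the dynamics see a single species.
#' @return A list of class `cmap_species`.
#' @seealso [cmap_network()], [validate_network()]
#' @export
cmap_species <- function(name, c_init = 0, c_max = 1, alpha = 1.2,
                         clamped = FALSE, clones = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(c_init), length(c_init) == 1L,
            is.numeric(c_max), length(c_max) == 1L,
            is.numeric(alpha), length(alpha) == 1L,
            is.logical(clamped), length(clamped) == 1L,
            is.character(clones))
  structure(list(name = name, c_init = as.numeric(c_init),
                 c_max = as.numeric(c_max), alpha = as.numeric(alpha),
                 clamped = clamped, clones = clones),
            class = "cmap_species")
}

#' Create an influence record
#'
#' An influence is a directed, signed causal edge. Its order is the number
#' of source species whose values are multiplied together; a length-1
#' source list equal to the target is a self-influence (basal decay or
#' autocatalysis).
#'
#' @param target Name of the species the influence acts on.
#' @param sources Character vector of source species names (length >= 1).
#' @param weight Influence magnitude, in `(0, 1]`; the CMAP analogue of an
#'   ODE rate constant, constant during simulation.
#' @param sign `+1` for activation, `-1` for inhibition.
#' @param label Optional provenance label (e.g. the rate-constant symbol a
#'   translated influence came from); not used by the dynamics.
#' @return A list of class `cmap_influence`.
#' @export
cmap_influence <- function(target, sources, weight = 0.5, sign = 1,
                           label = NULL) {
  stopifnot(is.character(target), length(target) == 1L,
            is.character(sources), length(sources) >= 1L,
            is.numeric(weight), length(weight) == 1L,
            sign %in% c(-1, 1))
  structure(list(target = target, sources = as.character(sources),
                 weight = as.numeric(weight), sign = as.integer(sign),
                 label = if (is.null(label)) NULL else as.character(label)),
            class = "cmap_influence")
}

# Identity of an influence for deduplication and canonical sorting.
# Distinct provenance labels keep otherwise-identical edges apart: a
# derivative may legitimately contain two terms with the same species
# product but different rate constants (two basal dephosphorylation
# routes, say), which translate to two parallel influences.
influence_key <- function(inf) {
  paste(inf$target, paste(inf$sources, collapse = "*"), inf$sign,
        inf$label %||% "", sep = "|")
}

#' Assemble a causal network
#'
#' A causal map is a graph whose nodes are species and whose edges are
#' signed causal influences. Species and influences are stored in a
#' canonical order (species by name; influences by target, source list and
#' sign) so that serialization is deterministic.
#'
#' @param species List of [cmap_species()] records.
#' @param influences List of [cmap_influence()] records (may be empty).
#' @param metadata Named list of free-form provenance strings.
#' @param check If `TRUE` (default), stop on any invariant violation.
#' @return An object of class `cmap_network`.
#' @examples
#' net <- cmap_network(
#'   species = list(cmap_species("A", c_init = 1, clamped = TRUE),
#'                  cmap_species("P")),
#'   influences = list(cmap_influence("P", "A", weight = 0.5, sign = 1)))
#' net
#' @export
cmap_network <- function(species, influences = list(), metadata = list(),
                         check = TRUE) {
  stopifnot(is.list(species), is.list(influences), is.list(metadata))
  species <- lapply(species, function(s) {
    if (!inherits(s, "cmap_species")) do.call(cmap_species, s) else s
  })
  influences <- lapply(influences, function(i) {
    if (!inherits(i, "cmap_influence")) do.call(cmap_influence, i) else i
  })
  species <- species[order(vapply(species, `[[`, "", "name"),
                           method = "radix")]
  if (length(influences)) {
    influences <- influences[order(vapply(influences, influence_key, ""),
                                   method = "radix")]
  }
  net <- structure(list(species = species, influences = influences,
                        metadata = metadata),
                   class = "cmap_network")
  if (check) {
    bad <- validate_network(net)
    if (length(bad)) {
      stop("invalid causal network:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
    }
  }
  net
}

#' @export
print.cmap_network <- function(x, ...) {
  ns <- length(x$species)
  nc <- sum(vapply(x$species, `[[`, FALSE, "clamped"))
  cat(sprintf("cmap_network: %d species (%d clamped), %d influences\n",
              ns, nc, length(x$influences)))
  ords <- vapply(x$influences, function(i) length(i$sources), 0L)
  if (length(ords)) {
    cat("  influence orders: ",
        paste(sprintf("%d x order-%s", tabulate(ords), seq_len(max(ords)))
              [tabulate(ords) > 0], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Species names of a network
#' @param net A `cmap_network`.
#' @return Character vector in canonical (sorted) order.
#' @export
species_names <- function(net) {
  vapply(net$species, `[[`, "", "name")
}

#' Initial state of a network
#' @param net A `cmap_network`.
#' @return Named numeric vector of `c_init` values.
#' @export
initial_state <- function(net) {
  stats::setNames(vapply(net$species, `[[`, 0, "c_init"), species_names(net))
}

#' Validate a causal network
#'
#' Checks every type invariant and reports violations instead of stopping:
#' species bounds `0 <= c_init <= c_max <= 1` (clamped species may take any
#' initial value in `[0, 1]`), sensitivity `0.5 <= alpha <= 5`, influence
#' weights in `(0, 1]`, referential integrity of all source/target names,
#' unique species names and no duplicated (target, sources, sign) triples
#' (influences carrying distinct provenance labels count as distinct
#' edges, since they stand for different rate constants).
#'
#' @param net A `cmap_network` (or a structurally similar list).
#' @return Character vector of human-readable violations; empty if the
#'   network satisfies every invariant.
#' @export
validate_network <- function(net) {
  v <- character()
  if (!length(net$species)) {
    return("network: must contain at least one species")
  }
  nm <- vapply(net$species, `[[`, "", "name")
  dup <- unique(nm[duplicated(nm)])
  for (d in dup) v <- c(v, sprintf("species '%s': duplicated name", d))
  for (s in net$species) {
    if (s$c_max <= 0 || s$c_max > 1) {
      v <- c(v, sprintf("species '%s': c_max %g outside (0, 1]",
                        s$name, s$c_max))
    }
    hi <- if (isTRUE(s$clamped)) 1 else s$c_max
    if (s$c_init < 0 || s$c_init > hi) {
      v <- c(v, sprintf("species '%s': c_init %g outside [0, %g]",
                        s$name, s$c_init, hi))
    }
    if (s$alpha < 0.5 || s$alpha > 5) {
      v <- c(v, sprintf("species '%s': alpha %g outside [0.5, 5]",
                        s$name, s$alpha))
    }
  }
  seen <- character()
  for (inf in net$influences) {
    id <- sprintf("influence %s <- %s (%s)", inf$target,
                  paste(inf$sources, collapse = "*"),
                  if (inf$sign > 0) "+" else "-")
    if (inf$weight <= 0 || inf$weight > 1) {
      v <- c(v, sprintf("%s: weight %g outside (0, 1]", id, inf$weight))
    }
    if (!inf$target %in% nm) {
      v <- c(v, sprintf("%s: unknown target species '%s'", id, inf$target))
    }
    miss <- setdiff(inf$sources, nm)
    for (s in miss) v <- c(v, sprintf("%s: unknown source species '%s'", id, s))
    key <- influence_key(inf)
    if (key %in% seen) v <- c(v, sprintf("%s: duplicated influence", id))
    seen <- c(seen, key)
  }
  v
}

#' Replace initial values and clamped-input settings
#'
#' @param net A `cmap_network`.
#' @param values Named numeric vector of new `c_init` values (any subset of
#'   species).
#' @return The modified network (the input is untouched).
#' @export
set_initial <- function(net, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  unknown <- setdiff(names(values), species_names(net))
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  net$species <- lapply(net$species, function(s) {
    if (s$name %in% names(values)) s$c_init <- as.numeric(values[[s$name]])
    s
  })
  bad <- validate_network(net)
  if (length(bad)) {
    stop("invalid after update:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  net
}
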