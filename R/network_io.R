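# Structured-text (JSON) serialization of causal networks.
#
# Canonical form: species sorted by name, influences sorted by
# (target, sources, sign), fixed field order, two-space pretty printing.
# save_network(load_network(f)) reproduces f byte for byte for files
# written by this package.

NETWORK_SCHEMA <- "cmap-network/1"

#' Read a causal network from a JSON file
#'
#' The file must carry top-level keys `species`, `influences` and
#' `metadata` (see [save_network()] for the field layout). The parsed
#' network is validated; any invariant violation is an error.
#'
#' @param path Path to a network JSON file.
#' @return A validated [cmap_network()].
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot parse '", path, "': ", conditionMessage(e),
                         call. = FALSE)
                  })
  for (key in c("species", "influences")) {
    if (is.null(doc[[key]])) {
      stop("network file '", path, "': missing required field '", key, "'",
           call. = FALSE)
    }
  }
  species <- lapply(seq_along(doc$species), function(i) {
    s <- doc$species[[i]]
    if (is.null(s$name)) {
      stop("network file '", path, "': species[", i, "] has no 'name'",
           call. = FALSE)
    }
    cmap_species(name = s$name,
                 c_init = s$c_init %||% 0,
                 c_max = s$c_max %||% 1,
                 alpha = s$alpha %||% 1.2,
                 clamped = isTRUE(s$clamped),
                 clones = as.character(unlist(s$clones)))
  })
  influences <- lapply(seq_along(doc$influences), function(i) {
    inf <- doc$influences[[i]]
    for (key in c("target", "sources", "weight", "sign")) {
      if (is.null(inf[[key]])) {
        stop("network file '", path, "': influences[", i,
             "] has no '", key, "'", call. = FALSE)
      }
    }
    cmap_influence(target = inf$target,
                   sources = as.character(unlist(inf$sources)),
                   weight = inf$weight, sign = inf$sign,
                   label = inf$label)
  })
  net <- cmap_network(species, influences,
                      metadata = doc$metadata %||% list(), check = FALSE)
  bad <- validate_network(net)
  if (length(bad)) {
    stop("network file '", path, "' is invalid:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  net
}

#' Write a causal network to a JSON file in canonical form
#'
#' @param net A `cmap_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  species <- lapply(net$species, function(s) {
    list(name = s$name, c_init = s$c_init, c_max = s$c_max,
         alpha = s$alpha, clamped = s$clamped,
         clones = as.list(s$clones))
  })
  influences <- lapply(net$influences, function(inf) {
    rec <- list(target = inf$target, sources = as.list(inf$sources),
                weight = inf$weight, sign = inf$sign)
    if (!is.null(inf$label)) rec$label <- inf$label
    rec
  })
  doc <- list(schema = NETWORK_SCHEMA,
              metadata = net$metadata,
              species = species,
              influences = influences)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                              digits = NA, null = "null"), path)
  invisible(path)
}

#' Read a named condition (initial-value scalings and clamp settings)
#'
#' A condition describes a cellular state as multiplicative factors on
#' initial values plus absolute settings for clamped inputs, e.g. the
#' type-2-diabetes variant of the insulin model.
#'
#' @param path Path to a condition JSON file with fields `name`, `scale`
#'   (species -> factor) and `clamp` (clamped species -> value).
#' @return A list of class `cmap_condition`.
#' @export
load_condition <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$name)) {
    stop("condition file '", path, "': missing 'name'", call. = FALSE)
  }
  cmap_condition(name = doc$name,
                 scale = unlist(doc$scale %||% list()),
                 clamp = unlist(doc$clamp %||% list()))
}

#' Construct a condition
#' @param name Condition name.
#' @param scale Named numeric vector of multiplicative factors on initial
#'   values (all factors must be positive).
#' @param clamp Named numeric vector of absolute values for clamped inputs.
#' @return A list of class `cmap_condition`.
#' @export
cmap_condition <- function(name, scale = numeric(), clamp = numeric()) {
  scale <- if (length(scale)) stats::setNames(as.numeric(scale), names(scale))
           else stats::setNames(numeric(), character())
  clamp <- if (length(clamp)) stats::setNames(as.numeric(clamp), names(clamp))
           else stats::setNames(numeric(), character())
  if (any(scale <= 0)) stop("condition factors must be > 0", call. = FALSE)
  structure(list(name = name, scale = scale, clamp = clamp),
            class = "cmap_condition")
}

#' Write a condition file
#' @param cond A `cmap_condition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_condition <- function(cond, path) {
  doc <- list(schema = "cmap-condition/1", name = cond$name,
              scale = as.list(cond$scale), clamp = as.list(cond$clamp))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                              digits = NA), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
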