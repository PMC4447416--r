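#' Elemental two-species motifs
#'
#' Builds the canonical two-species (`A`, `P`) causal motifs that
#' illustrate the elementary behaviors of the update rule. All weights are
#' 0.5 except the `A -> P` edge of the positive self-influence motif,
#' which is 0.01 so that the autocatalytic loop, not the input, dominates
#' the rise.
#'
#' Motifs and their qualitative behavior from the default initial values:
#' \describe{
#'   \item{`positive`}{`A -> P` activation; `P` rises monotonically from 0
#'     toward its bound.}
#'   \item{`negative`}{`A -> P` inhibition; `P` falls monotonically from 1
#'     toward 0.}
#'   \item{`positive_self`}{weak activation `A -> P` (0.01) plus positive
#'     self-influence `P -> P`; self-amplified (sigmoidal) rise.}
#'   \item{`negative_self`}{negative self-influence `P -> P` only;
#'     self-limited decay from `P = 0.8`.}
#'   \item{`combined`}{decaying activator (`A` un-clamped with negative
#'     self-influence) driving `P`, which also decays; `P` shows a
#'     transient rise-then-fall.}
#' }
#'
#' The activator `A` starts at 1 and is clamped except in the `combined`
#' motif, where its decay shapes the transient.
#'
#' @param kind One of `"positive"`, `"negative"`, `"positive_self"`,
#'   `"negative_self"`, `"combined"`.
#' @return A `cmap_network` with species `A` and `P`.
#' @examples
#' traj <- cmap_simulate(build_motif("positive"), n_iter = 50)
#' traj[51, "P"]  # approaches 1
#' @export
build_motif <- function(kind = c("positive", "negative", "positive_self",
                                 "negative_self", "combined")) {
  kind <- match.arg(kind)
  A <- function(c_init = 1, clamped = TRUE) {
    cmap_species("A", c_init = c_init, clamped = clamped)
  }
  net <- switch(kind,
    positive = cmap_network(
      list(A(), cmap_species("P", 0)),
      list(cmap_influence("P", "A", 0.5, +1))),
    negative = cmap_network(
      list(A(), cmap_species("P", 1)),
      list(cmap_influence("P", "A", 0.5, -1))),
    positive_self = cmap_network(
      list(A(), cmap_species("P", 0)),
      list(cmap_influence("P", "A", 0.01, +1),
           cmap_influence("P", "P", 0.5, +1))),
    negative_self = cmap_network(
      list(A(), cmap_species("P", 0.8)),
      list(cmap_influence("P", "P", 0.5, -1))),
    combined = cmap_network(
      list(A(clamped = FALSE), cmap_species("P", 0)),
      list(cmap_influence("A", "A", 0.5, -1),
           cmap_influence("P", "A", 0.5, +1),
           cmap_influence("P", "P", 0.5, -1))))
  net$metadata <- list(motif = kind)
  net
}

#' Random valid causal network
#'
#' Draws a structurally random network satisfying every type invariant:
#' useful for property-style checks such as trajectory boundedness. Edge
#' orders are sampled from {1, 2, 3} (with replacement among species, so
#' self-influences occur), weights uniform on (0, 1], alphas uniform on
#' [0.5, 5], initial values uniform on [0, c_max].
#'
#' @param n_species Number of species (>= 1).
#' @param n_influences Number of influences to draw (duplicates are
#'   discarded, so the realized count may be smaller).
#' @param p_clamped Probability that a species is clamped.
#' @param cmax_range Range to draw `c_max` from.
#' @return A `cmap_network`.
#' @export
random_network <- function(n_species = 5, n_influences = 8,
                           p_clamped = 0.1, cmax_range = c(1, 1)) {
  nm <- sprintf("S%02d", seq_len(n_species))
  species <- lapply(nm, function(x) {
    cmax <- stats::runif(1, cmax_range[1], cmax_range[2])
    cmap_species(x, c_init = stats::runif(1, 0, cmax), c_max = cmax,
                 alpha = stats::runif(1, 0.5, 5),
                 clamped = stats::runif(1) < p_clamped)
  })
  seen <- character()
  influences <- list()
  for (i in seq_len(n_influences)) {
    ord <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    inf <- cmap_influence(target = sample(nm, 1),
                          sources = sample(nm, ord, replace = TRUE),
                          weight = stats::runif(1, 1e-3, 1),
                          sign = sample(c(-1, 1), 1))
    key <- influence_key(inf)
    if (!key %in% seen) {
      influences <- c(influences, list(inf))
      seen <- c(seen, key)
    }
  }
  cmap_network(species, influences)
}
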