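# Random parameter-ensemble generation and rule-based search. Weights are
# drawn uniformly on [w_max / ratio, w_max] (ratio 1000 by default, so the
# largest and smallest admissible weights differ by three orders of
# magnitude) and sensitivities per species uniformly on [0.5, 3]. The
# stream is reproducible from one master seed, and sets are drawn one
# block at a time so the first k sets do not depend on n_sets.

#' Search configuration
#'
#' @param n_sets Number of parameter sets to draw (0 gives a degenerate
#'   empty search).
#' @param w_max Upper weight bound (default 1).
#' @param ratio Bound ratio: lower weight bound is `w_max / ratio`
#'   (default 1000; must be > 1).
#' @param alpha_range Sensitivity range, within `[0.5, 5]` (default
#'   `c(0.5, 3)`).
#' @param seed Master seed (integer).
#' @param mode `"first_hit"` (stop at the first satisfying set) or
#'   `"collect"` (return every hit among `n_sets`).
#' @param log_uniform Draw weights log-uniformly instead of uniformly on
#'   the linear scale (default `FALSE`).
#' @return A list of class `cmap_search_config`.
#' @export
search_config <- function(n_sets, w_max = 1, ratio = 1000,
                          alpha_range = c(0.5, 3), seed = 1,
                          mode = c("first_hit", "collect"),
                          log_uniform = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_sets >= 0, w_max > 0, w_max <= 1, ratio > 1,
            length(alpha_range) == 2L, alpha_range[1] >= 0.5,
            alpha_range[2] <= 5, alpha_range[1] <= alpha_range[2])
  structure(list(n_sets = as.integer(n_sets), w_max = w_max, ratio = ratio,
                 alpha_range = alpha_range, seed = as.integer(seed),
                 mode = mode, log_uniform = isTRUE(log_uniform)),
            class = "cmap_search_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Draw random parameter sets for a network
#'
#' Each set assigns one weight per influence and one sensitivity per
#' species. Draws for set `i` occupy one contiguous block of the random
#' stream, so the first `k` sets are identical for any `n_sets >= k`
#' under the same seed.
#'
#' @param net A `cmap_network`.
#' @param cfg A [search_config()].
#' @return A list of class `cmap_parameter_sets` with `weights`
#'   (`n_sets` x n-influences matrix), `alphas` (`n_sets` x n-species
#'   matrix, columns named by species) and `seed`.
#' @export
sample_parameter_sets <- function(net, cfg) {
  stopifnot(inherits(cfg, "cmap_search_config"))
  m <- length(net$influences)
  n <- length(net$species)
  lo <- cfg$w_max / cfg$ratio
  a <- cfg$alpha_range
  u <- with_seed(cfg$seed,
                 matrix(stats::runif(cfg$n_sets * (m + n)),
                        ncol = m + n, byrow = TRUE))
  uw <- u[, seq_len(m), drop = FALSE]
  w <- if (cfg$log_uniform) {
    exp(log(lo) + uw * (log(cfg$w_max) - log(lo)))
  } else {
    lo + uw * (cfg$w_max - lo)
  }
  alphas <- a[1] + u[, m + seq_len(n), drop = FALSE] * (a[2] - a[1])
  colnames(alphas) <- species_names(net)
  structure(list(weights = w, alphas = alphas, seed = cfg$seed),
            class = "cmap_parameter_sets")
}

nth_parameter_set <- function(sets, i) {
  list(weights = sets$weights[i, ], alphas = sets$alphas[i, ])
}

#' Rule-based random parameter search
#'
#' Draws parameter sets from [sample_parameter_sets()] and, in stream
#' order, simulates each one with `protocol` and tests every rule. In
#' `"first_hit"` mode the search stops at the first satisfying set; in
#' `"collect"` mode all `n_sets` are screened. An empty result is a valid
#' outcome, not an error.
#'
#' @param net A `cmap_network`.
#' @param initial Initial state passed to the default protocol (default:
#'   the network's initial values).
#' @param rules Nonempty list of [cmap_rule()] objects; a hit must satisfy
#'   all of them.
#' @param cfg A [search_config()].
#' @param n_iter Simulation length used by the default protocol
#'   (default 200).
#' @param protocol Optional function `(net, params) -> trajectory`
#'   replacing the default "simulate `n_iter` steps from `initial`"
#'   recipe (e.g. a basal-then-stimulus recipe).
#' @return List of hits, each `list(index, params, trajectory)`.
#' @export
cmap_search <- function(net, initial = NULL, rules, cfg, n_iter = 200,
                        protocol = NULL) {
  stopifnot(length(rules) >= 1)
  if (is.null(protocol)) {
    protocol <- function(net, params) {
      cmap_simulate(net, initial = initial, n_iter = n_iter,
                    params = params)
    }
  }
  sets <- sample_parameter_sets(net, cfg)
  hits <- list()
  for (i in seq_len(cfg$n_sets)) {
    params <- nth_parameter_set(sets, i)
    traj <- protocol(net, params)
    ok <- all(vapply(rules, function(r) evaluate_rule(traj, r), FALSE))
    if (ok) {
      hits[[length(hits) + 1L]] <- list(index = i, params = params,
                                        trajectory = traj)
      if (cfg$mode == "first_hit") break
    }
  }
  hits
}

#' Write a search manifest as TSV
#'
#' One row per screened set with its rule outcomes, suitable for joining
#' against saved per-hit parameter files.
#'
#' @param outcomes Data frame with at least a `set` column and one logical
#'   column per rule.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_search_manifest <- function(outcomes, path) {
  utils::write.table(outcomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
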