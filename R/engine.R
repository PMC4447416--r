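#' The causal function
#'
#' The odd sigmoid \eqn{f(x) = (1 - e^{-\alpha x}) / (1 + e^{-\alpha x})}
#' that maps the aggregate causal input of a species to a bounded update
#' fraction in (-1, 1). `alpha` sets the steepness: the larger it is, the
#' more switch-like the response. Evaluated in an overflow-safe form (for
#' negative arguments the odd symmetry is used), so it is finite for any
#' input.
#'
#' @param x Aggregate causal input (vectorized).
#' @param alpha Sensitivity, > 0. Default 1.2.
#' @return Numeric vector of values in (-1, 1).
#' @examples
#' causal_function(1, alpha = 1.2)  # 0.53705
#' @export
causal_function <- function(x, alpha = 1.2) {
  stopifnot(is.numeric(x), is.numeric(alpha), all(alpha > 0))
  z <- alpha * x
  f <- numeric(length(z))
  pos <- !is.na(z) & z >= 0
  e <- exp(-z[pos])
  f[pos] <- (1 - e) / (1 + e)
  e <- exp(z[!pos])
  f[!pos] <- -(1 - e) / (1 + e)
  f[is.na(z)] <- NA_real_
  f
}

#' Aggregate causal input on one species
#'
#' Sums, over every influence acting on `target`, the signed product of
#' the influence weight and the current values of all its sources:
#' \eqn{x_j = \sum_i C_i W_{ij} + \sum_{i,k} C_i C_k W_{ikj} + \ldots}.
#' Influences of any order are supported.
#'
#' @param net A `cmap_network`.
#' @param state Named numeric vector of current species values.
#' @param target Species name.
#' @return A single number (0 when no influence targets the species).
#' @export
causal_input <- function(net, state, target) {
  if (!target %in% species_names(net)) {
    stop("unknown species: ", target, call. = FALSE)
  }
  x <- 0
  for (inf in net$influences) {
    if (inf$target == target) {
      x <- x + inf$sign * inf$weight * prod(state[inf$sources])
    }
  }
  unname(x)
}

#' Range-restriction factor
#'
#' The headroom term \eqn{\Lambda} that scales the update so a species can
#' never leave `[0, c_max]`: the distance to the upper bound when the
#' causal function is positive, the distance to zero otherwise.
#'
#' @param c Current value, in `[0, c_max]`.
#' @param f Causal-function value.
#' @param c_max Upper bound.
#' @return Nonnegative scalar (vectorized over `c`, `f`).
#' @export
lambda_restrict <- function(c, f, c_max = 1) {
  stopifnot(all(c >= 0), all(c <= c_max))
  ifelse(f > 0, c_max - c, c)
}

# Flatten a network (plus optional parameter overrides) into the vectors
# the compiled stepper consumes. Indices are 0-based.
compile_network <- function(net, params = NULL) {
  nm <- species_names(net)
  idx <- stats::setNames(seq_along(nm) - 1L, nm)
  w <- vapply(net$influences, `[[`, 0, "weight")
  alpha <- vapply(net$species, `[[`, 0, "alpha")
  if (!is.null(params)) {
    if (!is.null(params$weights)) {
      pw <- params$weights
      if (is.null(names(pw))) {
        if (length(pw) != length(w)) {
          stop("weights override must have length ", length(w), call. = FALSE)
        }
        w <- as.numeric(pw)
      } else {
        labels <- vapply(net$influences, function(i) i$label %||% "", "")
        unknown <- setdiff(names(pw), labels)
        if (length(unknown)) {
          stop("unknown influence label(s): ",
               paste(unknown, collapse = ", "), call. = FALSE)
        }
        for (lb in names(pw)) w[labels == lb] <- pw[[lb]]
      }
    }
    if (!is.null(params$alphas)) {
      pa <- params$alphas
      if (is.null(names(pa))) {
        if (length(pa) != length(alpha)) {
          stop("alphas override must have length ", length(alpha),
               call. = FALSE)
        }
        alpha <- as.numeric(pa)
      } else {
        unknown <- setdiff(names(pa), nm)
        if (length(unknown)) {
          stop("unknown species in alpha override: ",
               paste(unknown, collapse = ", "), call. = FALSE)
        }
        alpha[match(names(pa), nm)] <- as.numeric(pa)
      }
    }
  }
  src <- lapply(net$influences, function(i) unname(idx[i$sources]))
  list(names = nm,
       init = unname(vapply(net$species, `[[`, 0, "c_init")),
       clamped = as.integer(vapply(net$species, `[[`, FALSE, "clamped")),
       cmax = unname(vapply(net$species, `[[`, 0, "c_max")),
       alpha = unname(alpha),
       tgt = unname(idx[vapply(net$influences, `[[`, "", "target")]),
       ptr = as.integer(cumsum(c(0L, lengths(src)))),
       src = as.integer(unlist(src, use.names = FALSE)),
       w = unname(w),
       sgn = vapply(net$influences, `[[`, 0L, "sign"))
}

check_state <- function(net, state) {
  nm <- species_names(net)
  if (is.null(state)) return(initial_state(net))
  if (is.null(names(state)) && length(state) == length(nm)) {
    names(state) <- nm
  }
  miss <- setdiff(nm, names(state))
  if (length(miss)) {
    stop("state is missing species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  state <- state[nm]
  cmax <- vapply(net$species, `[[`, 0, "c_max")
  clamped <- vapply(net$species, `[[`, FALSE, "clamped")
  hi <- ifelse(clamped, 1, cmax)
  if (any(!is.finite(state)) || any(state < 0) || any(state > hi + 1e-12)) {
    stop("state values out of bounds", call. = FALSE)
  }
  state
}

#' One synchronous update step
#'
#' Advances every non-clamped species by
#' \eqn{C_j(t) = C_j(t-1) + \Lambda_j f_j}, computing every update from
#' the frozen previous state (Jacobi-style), so the result does not depend
#' on species order. Clamped species are copied unchanged.
#'
#' @param net A `cmap_network`.
#' @param state Named numeric state vector (default: the network's initial
#'   values).
#' @param params Optional overrides: a list with elements `weights`
#'   (numeric vector aligned with the canonical influence order, or named
#'   by influence label) and/or `alphas` (aligned with species order, or
#'   named by species). Unknown names are an error.
#' @return The next state, named.
#' @export
cmap_step <- function(net, state = NULL, params = NULL) {
  state <- check_state(net, state)
  cn <- compile_network(net, params)
  out <- cpp_simulate(unname(state), cn$clamped, cn$cmax, cn$alpha,
                      cn$tgt, cn$ptr, cn$src, cn$w, cn$sgn, 1L)
  stats::setNames(out[2, ], cn$names)
}

#' Simulate a causal network
#'
#' Runs `n_iter` synchronous update steps from an initial state and
#' records the full trajectory. Each iteration is the smallest incremental
#' signal progression through the network ("virtual time"); no mapping to
#' physical time is attempted. The run is deterministic given the network,
#' state and parameters.
#'
#' @inheritParams cmap_step
#' @param initial Named numeric initial state (default: the network's
#'   `c_init` values).
#' @param n_iter Number of iterations (>= 1).
#' @return A `cmap_trajectory`: numeric matrix with `n_iter + 1` rows
#'   (iterations 0..`n_iter` as row names) and one column per species.
#' @examples
#' traj <- cmap_simulate(build_motif("positive"), n_iter = 10)
#' traj[1:3, ]
#' @export
cmap_simulate <- function(net, initial = NULL, n_iter, params = NULL) {
  stopifnot(is.numeric(n_iter), length(n_iter) == 1L, n_iter >= 1)
  initial <- check_state(net, initial)
  cn <- compile_network(net, params)
  out <- cpp_simulate(unname(initial), cn$clamped, cn$cmax, cn$alpha,
                      cn$tgt, cn$ptr, cn$src, cn$w, cn$sgn,
                      as.integer(n_iter))
  dimnames(out) <- list(0:n_iter, cn$names)
  class(out) <- c("cmap_trajectory", class(out))
  out
}

#' Iterate to a steady state
#'
#' Steps the network until the largest single-step change over all species
#' drops below `tol`, or `max_iter` steps have been taken. Non-convergence
#' (e.g. a sustained oscillation) is reported through the `converged`
#' flag, not an error.
#'
#' @inheritParams cmap_simulate
#' @param tol Convergence threshold on the max-norm of the state change
#'   (> 0). Default `1e-6`.
#' @param max_iter Iteration cap. Default 10000.
#' @return A list with `state` (named numeric), `converged` (flag) and
#'   `iterations` (steps taken before the change fell below `tol`).
#' @export
run_to_steady_state <- function(net, initial = NULL, tol = 1e-6,
                                max_iter = 10000, params = NULL) {
  stopifnot(tol > 0, max_iter >= 1)
  initial <- check_state(net, initial)
  cn <- compile_network(net, params)
  res <- cpp_run_to_steady(unname(initial), cn$clamped, cn$cmax, cn$alpha,
                           cn$tgt, cn$ptr, cn$src, cn$w, cn$sgn,
                           tol, as.integer(max_iter))
  res$state <- stats::setNames(res$state, cn$names)
  res
}

#' Evaluate a named observable on a trajectory
#'
#' An observable is a weighted sum of species values, e.g.
#' `measuredIRp = IRp + IRip`. Unweighted sums are given as a character
#' vector of species names; weights as a named numeric vector.
#'
#' @param traj A `cmap_trajectory` (or plain matrix with species columns).
#' @param observable Character vector of species names (summed with unit
#'   weight) or a named numeric vector of coefficients.
#' @return Numeric vector, one value per trajectory row.
#' @export
observable_series <- function(traj, observable) {
  if (is.character(observable)) {
    observable <- stats::setNames(rep(1, length(observable)), observable)
  }
  miss <- setdiff(names(observable), colnames(traj))
  if (length(miss)) {
    stop("observable references unknown species: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  as.vector(traj[, names(observable), drop = FALSE] %*% unname(observable))
}

#' Write a trajectory as TSV
#'
#' Column 1 is the iteration index; one column per species, plus one per
#' observable if given.
#'
#' @param traj A `cmap_trajectory`.
#' @param path Output path.
#' @param observables Optional named list of observables (see
#'   [observable_series()]) appended as extra columns.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, observables = NULL) {
  df <- data.frame(iteration = as.integer(rownames(traj)),
                   unclass(traj), check.names = FALSE)
  for (nm in names(observables)) {
    df[[nm]] <- observable_series(traj, observables[[nm]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
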