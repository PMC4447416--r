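# Fixed-step reference integrator for the ODE side of a model, used for
# qualitative comparison against the causal-map simulation of the same
# pathway. Classical fourth-order Runge-Kutta with a constant step keeps
# runs deterministic and dependency-free; stiff problems and events are
# out of scope.

# Pre-resolve every term of a model against a rate assignment and the
# canonical species order: per term a signed coefficient, integer factor
# indices and an optional (substrate index, km, n) triple. Missing
# symbols are reported here, by name.
compile_ode <- function(model, rates) {
  nm <- ode_species_names(model)
  need <- unique(unlist(lapply(model$components, function(cp) {
    lapply(cp$terms, function(t) {
      c(t$rate, if (!is.null(t$saturation)) c(t$saturation$km,
                                              t$saturation$n))
    })
  })))
  miss <- setdiff(need, names(rates))
  if (length(miss)) {
    stop("missing rate/parameter value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(rates[intersect(need, names(rates))] < 0)) {
    stop("rate values must be nonnegative", call. = FALSE)
  }
  lapply(model$components, function(cp) {
    if (cp$name %in% model$clamped) return(list(idx = NULL, terms = list()))
    list(idx = match(cp$name, nm),
         terms = lapply(cp$terms, function(t) {
           list(coef = t$sign * rates[[t$rate]],
                fidx = match(t$factors, nm),
                sat = if (!is.null(t$saturation)) {
                  list(sidx = match(t$saturation$substrate, nm),
                       km = rates[[t$saturation$km]],
                       n = rates[[t$saturation$n]])
                })
         }))
  })
}

deriv_compiled <- function(compiled, state) {
  d <- numeric(length(state))
  for (cp in compiled) {
    if (is.null(cp$idx)) next
    acc <- 0
    for (t in cp$terms) {
      val <- t$coef * prod(state[t$fidx])
      if (!is.null(t$sat)) {
        s <- state[t$sat$sidx]
        sn <- s^t$sat$n
        val <- val * sn / (t$sat$km^t$sat$n + sn)
      }
      acc <- acc + val
    }
    d[cp$idx] <- acc
  }
  d
}

#' Evaluate the derivatives of an ODE model
#'
#' Each component's derivative is the sum of its signed terms; Hill
#' factors are computed as `S^n / (km^n + S^n)`. Clamped inputs have
#' derivative zero.
#'
#' @param model An `ode_model`.
#' @param rates Named numeric vector covering every rate, `km` and `n`
#'   symbol used by the model (a missing symbol is an error naming it).
#' @param state Named numeric vector of current values for every
#'   component.
#' @return Named numeric vector of time derivatives.
#' @export
evaluate_derivatives <- function(model, rates, state) {
  nm <- ode_species_names(model)
  miss <- setdiff(nm, names(state))
  if (length(miss)) {
    stop("state is missing component(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  compiled <- compile_ode(model, rates)
  stats::setNames(deriv_compiled(compiled, unname(state[nm])), nm)
}

#' Integrate an ODE model with fixed-step fourth-order Runge-Kutta
#'
#' Deterministic classical RK4 with constant step. Small negative
#' undershoots (possible with large steps) are clipped to zero and
#' reported once via a warning.
#'
#' @param model An `ode_model`.
#' @param rates Named numeric parameter vector (see
#'   [evaluate_derivatives()]).
#' @param initial Named numeric initial state; defaults to the model's
#'   initial values.
#' @param step Step size in the model's time units (> 0). Default 0.01.
#' @param duration Total integration time (> 0).
#' @return A numeric matrix (class `cmap_trajectory`) with one row per
#'   step (row names = step index) and a `"time"` attribute holding the
#'   time points.
#' @examples
#' iso <- ode_model(list(
#'   ode_component("A", 1, list(ode_term(-1, "kf", "A"),
#'                              ode_term(+1, "kb", "B"))),
#'   ode_component("B", 0, list(ode_term(+1, "kf", "A"),
#'                              ode_term(-1, "kb", "B")))))
#' traj <- ode_integrate(iso, c(kf = 1, kb = 1), step = 0.01, duration = 20)
#' tail(traj, 1)  # A = B = 0.5 at equilibrium
#' @export
ode_integrate <- function(model, rates, initial = NULL, step = 0.01,
                          duration) {
  stopifnot(step > 0, duration > 0)
  nm <- ode_species_names(model)
  if (is.null(initial)) {
    initial <- stats::setNames(vapply(model$components, `[[`, 0, "initial"),
                               nm)
  }
  miss <- setdiff(nm, names(initial))
  if (length(miss)) {
    stop("initial state is missing component(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  state <- unname(initial[nm])
  compiled <- compile_ode(model, rates)
  n_steps <- ceiling(duration / step)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(nm),
                dimnames = list(0:n_steps, nm))
  out[1L, ] <- state
  clipped <- FALSE
  for (i in seq_len(n_steps)) {
    k1 <- deriv_compiled(compiled, state)
    k2 <- deriv_compiled(compiled, state + step / 2 * k1)
    k3 <- deriv_compiled(compiled, state + step / 2 * k2)
    k4 <- deriv_compiled(compiled, state + step * k3)
    state <- state + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(state))) {
      stop("non-finite state at step ", i, "; reduce the step size",
           call. = FALSE)
    }
    if (any(state < 0)) {
      clipped <- TRUE
      state[state < 0] <- 0
    }
    out[i + 1L, ] <- state
  }
  if (clipped) {
    warning("negative undershoot(s) clipped to 0 during integration")
  }
  attr(out, "time") <- step * (0:n_steps)
  class(out) <- c("cmap_trajectory", class(out))
  out
}
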