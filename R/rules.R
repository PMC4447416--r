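# Qualitative trajectory rules: the operational criteria the parameter
# search screens against. A rule is evaluated on an observable (a named
# weighted sum of species, e.g. measuredIRp = IRp + IRip) over a finite
# trajectory, so each verbal criterion needs explicit thresholds:
#   delta  - minimum excursion that counts as a change (default 0.05);
#   rho    - for transients, the maximum fraction of the peak excursion
#            that may be retained at the end (default 0.5);
#   k_osc  - minimum number of direction alternations that counts as an
#            oscillation (default 4), each leg at least delta/10 deep.

#' Define a trajectory rule
#'
#' @param kind One of `"increase"`, `"decrease"`, `"transient_up"`,
#'   `"transient_down"`, `"oscillation"`.
#' @param observable Observable definition: character vector of species
#'   names (summed) or a named numeric vector of coefficients.
#' @param delta Minimum excursion (> 0).
#' @param rho Maximum retained fraction of the peak excursion for
#'   transient rules (> 0).
#' @param k_osc Minimum direction alternations for the oscillation rule.
#' @return A list of class `cmap_rule`.
#' @export
cmap_rule <- function(kind = c("increase", "decrease", "transient_up",
                               "transient_down", "oscillation"),
                      observable, delta = 0.05, rho = 0.5, k_osc = 4) {
  kind <- match.arg(kind)
  stopifnot(delta > 0, rho > 0, k_osc >= 1)
  structure(list(kind = kind, observable = observable, delta = delta,
                 rho = rho, k_osc = k_osc),
            class = "cmap_rule")
}

#' Evaluate a rule on a trajectory
#'
#' Operational definitions on the observable series `s` with initial
#' value `s0`, final value `s1` and peak/trough `p`/`q`:
#' \describe{
#'   \item{increase}{`s1 - s0 >= delta`}
#'   \item{decrease}{`s0 - s1 >= delta`}
#'   \item{transient_up}{`p - s0 >= delta` and
#'     `s1 - s0 <= rho * (p - s0)`: the series rises substantially and
#'     gives most of the excursion back}
#'   \item{transient_down}{mirror image using the trough}
#'   \item{oscillation}{at least `k_osc` sign alternations among
#'     successive differences of magnitude `>= delta / 10`}
#' }
#'
#' @param traj A `cmap_trajectory`.
#' @param rule A [cmap_rule()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' traj <- cmap_simulate(build_motif("combined"), n_iter = 100)
#' evaluate_rule(traj, cmap_rule("transient_up", "P"))
#' @export
evaluate_rule <- function(traj, rule) {
  stopifnot(inherits(rule, "cmap_rule"))
  s <- observable_series(traj, rule$observable)
  rule_on_series(s, rule)
}

# Shared rule arithmetic on a bare observable series; evaluate_rule and
# the insulin pipeline both go through here.
rule_on_series <- function(s, rule) {
  if (length(s) < 2L) {
    stop("trajectory must contain at least two points", call. = FALSE)
  }
  s0 <- s[1L]
  s1 <- s[length(s)]
  switch(rule$kind,
    increase = (s1 - s0) >= rule$delta,
    decrease = (s0 - s1) >= rule$delta,
    transient_up = {
      exc <- max(s) - s0
      exc >= rule$delta && (s1 - s0) <= rule$rho * exc
    },
    transient_down = {
      exc <- s0 - min(s)
      exc >= rule$delta && (s0 - s1) <= rule$rho * exc
    },
    oscillation = {
      d <- diff(s)
      d <- d[abs(d) >= rule$delta / 10]
      if (length(d) < 2L) FALSE
      else sum(diff(sign(d)) != 0) >= rule$k_osc
    })
}

#' Pointwise dominance of one response curve over another
#'
#' Checks that the observable of `traj_a` lies at or above that of
#' `traj_b` (within `tol`) at every iteration — the criterion used to
#' require that normal-cell response curves lie higher than diseased-cell
#' curves.
#'
#' @param traj_a,traj_b Trajectories of equal length over the same
#'   species.
#' @param observable Observable definition (see [observable_series()]).
#' @param tol Slack allowed at each point (default 0.01).
#' @return `TRUE` iff `obs_a(t) >= obs_b(t) - tol` for all `t`.
#' @export
check_dominance <- function(traj_a, traj_b, observable, tol = 0.01) {
  sa <- observable_series(traj_a, observable)
  sb <- observable_series(traj_b, observable)
  if (length(sa) != length(sb)) {
    stop("trajectories have different lengths (", length(sa), " vs ",
         length(sb), ")", call. = FALSE)
  }
  all(sa >= sb - tol)
}
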