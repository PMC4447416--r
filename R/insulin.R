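# Packaged insulin-signaling case study: a reduced 27-species model of
# insulin receptor (IR) autophosphorylation and internalization, IRS1
# phosphorylation (tyrosine-site IRS1p, serine-307 forms), the PKB /
# mTORC1 / mTORC2 axis, AS160 and GLUT4 membrane translocation, and S6K /
# S6, driven by two clamped inputs: insulin and a lumped "diabetes"
# feedback strength. The ODE side is transcribed component by component
# (signed mass-action terms, two Hill-saturated reactions); the causal-map
# side is produced from it by the one-to-one translator.

insulin_terms <- function() {
  tm <- function(sign, rate, ..., sat = NULL) {
    list(sign = sign, rate = rate, factors = c(...), saturation = sat)
  }
  list(
    IR = list(
      tm(+1, "k1g", "IRp"),
      tm(+1, "k1r", "IRi"),
      tm(-1, "k1a", "IR", "insulin"),
      tm(-1, "k1basal", "IR")),
    IRp = list(
      tm(+1, "k1basal", "IR"),
      tm(+1, "k1c", "IRins"),
      tm(-1, "k1d", "IRp"),
      tm(-1, "k1g", "IRp")),
    IRins = list(
      tm(+1, "k1a", "IR", "insulin"),
      tm(-1, "k1c", "IRins")),
    IRip = list(
      tm(+1, "k1d", "IRp"),
      tm(-1, "k1f", "IRip", "Xp")),
    IRi = list(
      tm(+1, "k1f", "IRip", "Xp"),
      tm(-1, "k1r", "IRi")),
    IRS1 = list(
      tm(+1, "k2b", "IRS1p"),
      tm(+1, "k2g", "IRS1307"),
      tm(-1, "k2a", "IRS1", "IRip"),
      tm(-1, "k2basal", "IRS1")),
    IRS1p = list(
      tm(+1, "k2a", "IRS1", "IRip"),
      tm(+1, "k2d", "IRS1p307"),
      tm(-1, "k2b", "IRS1p"),
      tm(-1, "k2c", "IRS1p", "mTORC1a", "diabetes")),
    IRS1p307 = list(
      tm(+1, "k2c", "IRS1p", "mTORC1a", "diabetes"),
      tm(-1, "k2d", "IRS1p307"),
      tm(-1, "k2f", "IRS1p307")),
    IRS1307 = list(
      tm(+1, "k2f", "IRS1p307"),
      tm(+1, "k2basal", "IRS1"),
      tm(-1, "k2g", "IRS1307")),
    X = list(
      tm(+1, "k3b", "Xp"),
      tm(-1, "k3a", "X", "IRS1p")),
    Xp = list(
      tm(+1, "k3a", "X", "IRS1p"),
      tm(-1, "k3b", "Xp")),
    PKB = list(
      tm(+1, "k4b", "PKB308p"),
      tm(+1, "k4h", "PKB473p"),
      tm(-1, "k4a", "PKB", "IRS1p")),
    PKB308p = list(
      tm(+1, "k4a", "PKB", "IRS1p"),
      tm(-1, "k4b", "PKB308p"),
      tm(-1, "k4c", "PKB308p", "mTORC2a")),
    PKB473p = list(
      tm(+1, "k4f", "PKB308p473p"),
      tm(-1, "k4e", "PKB473p", "IRS1p307"),
      tm(-1, "k4h", "PKB473p")),
    PKB308p473p = list(
      tm(+1, "k4c", "PKB308p", "mTORC2a"),
      tm(+1, "k4e", "PKB473p", "IRS1p307"),
      tm(-1, "k4f", "PKB308p473p")),
    mTORC1 = list(
      tm(+1, "k5b", "mTORC1a"),
      tm(-1, "k5a1", "mTORC1", "PKB308p473p"),
      tm(-1, "k5a2", "mTORC1", "PKB308p")),
    mTORC1a = list(
      tm(+1, "k5a1", "mTORC1", "PKB308p473p"),
      tm(+1, "k5a2", "mTORC1", "PKB308p"),
      tm(-1, "k5b", "mTORC1a")),
    mTORC2 = list(
      tm(+1, "k5d", "mTORC2a"),
      tm(-1, "k5c", "mTORC2", "IRip")),
    mTORC2a = list(
      tm(+1, "k5c", "mTORC2", "IRip"),
      tm(-1, "k5d", "mTORC2a")),
    AS160 = list(
      tm(+1, "k6b", "AS160p"),
      tm(-1, "k6f1", "AS160", "PKB308p473p"),
      tm(-1, "k6f2", "AS160",
         sat = list(substrate = "PKB473p", km = "km6", n = "n6"))),
    AS160p = list(
      tm(+1, "k6f1", "AS160", "PKB308p473p"),
      tm(+1, "k6f2", "AS160",
         sat = list(substrate = "PKB473p", km = "km6", n = "n6")),
      tm(-1, "k6b", "AS160p")),
    GLUT4m = list(
      tm(+1, "k7f", "GLUT4", "AS160p"),
      tm(-1, "k7b", "GLUT4m")),
    GLUT4 = list(
      tm(+1, "k7b", "GLUT4m"),
      tm(-1, "k7f", "GLUT4", "AS160p")),
    S6K = list(
      tm(+1, "k9b1", "S6Kp"),
      tm(-1, "k9f1", "S6K",
         sat = list(substrate = "mTORC1a", km = "km9", n = "n9"))),
    S6Kp = list(
      tm(+1, "k9f1", "S6K",
         sat = list(substrate = "mTORC1a", km = "km9", n = "n9")),
      tm(-1, "k9b1", "S6Kp")),
    S6 = list(
      tm(+1, "k9b2", "S6p"),
      tm(-1, "k9f2", "S6", "S6Kp")),
    S6p = list(
      tm(+1, "k9f2", "S6", "S6Kp"),
      tm(-1, "k9b2", "S6p")),
    insulin = list(),
    diabetes = list())
}

insulin_initials <- c(
  IR = 1, IRp = 0, IRins = 0, IRip = 0, IRi = 0,
  IRS1 = 0.8, IRS1p = 0, IRS1p307 = 0, IRS1307 = 0.2,
  X = 1, Xp = 0,
  PKB = 0.7, PKB308p = 0, PKB473p = 0, PKB308p473p = 0,
  mTORC1 = 0.9, mTORC1a = 0, mTORC2 = 0.9, mTORC2a = 0,
  AS160 = 0.7, AS160p = 0, GLUT4m = 0, GLUT4 = 0.6,
  S6K = 0.9, S6Kp = 0, S6 = 0.9, S6p = 0,
  insulin = 0, diabetes = 1)

#' Build the insulin-signaling model
#'
#' Constructs both representations of the reduced 27-species insulin
#' model: the mass-action ODE side (72 signed terms over 27 dynamic
#' components plus the clamped inputs `insulin` and `diabetes`) and the
#' causal-map side obtained from it by [translate_model()]. Initial
#' values: IR 1, IRS1 0.8, IRS1307 0.2, X 1, PKB 0.7, mTORC1 0.9,
#' mTORC2 0.9, AS160 0.7, GLUT4 0.6, S6K 0.9, S6 0.9, diabetes 1, all
#' other species 0.
#'
#' @return List with elements `ode` (an `ode_model`) and `network` (a
#'   `cmap_network` carrying a translation report).
#' @examples
#' mod <- build_insulin_model()
#' length(mod$network$influences)  # 72
#' @export
build_insulin_model <- function() {
  terms <- insulin_terms()
  comps <- lapply(names(terms), function(nm) {
    ode_component(nm, initial = insulin_initials[[nm]],
                  terms = terms[[nm]])
  })
  ode <- ode_model(comps, clamped = c("insulin", "diabetes"),
                   metadata = list(
                     model = "reduced insulin signaling, normal vs T2D"))
  list(ode = ode, network = translate_model(ode))
}

#' The insulin study observables
#'
#' `measuredIRp = IRp + IRip` (tyrosine-phosphorylated receptor pool) and
#' `measuredIRS1p = IRS1p + IRS1p307` (phosphorylated IRS1 pool): the two
#' quantities whose transient response defines the search rules.
#'
#' @return Named list of observables (see [observable_series()]).
#' @export
insulin_observables <- function() {
  list(measuredIRp = c("IRp", "IRip"),
       measuredIRS1p = c("IRS1p", "IRS1p307"))
}

#' Normal and type-2-diabetes conditions for the insulin model
#'
#' The T2D cell differs from the normal cell by scaled initial values:
#' `IR` at 0.55x, `GLUT4` at 0.5x and the clamped `diabetes` input at
#' 0.15x.
#'
#' @param name `"normal"` or `"t2d"`.
#' @return A [cmap_condition()].
#' @export
insulin_condition <- function(name = c("normal", "t2d")) {
  name <- match.arg(name)
  if (name == "normal") {
    cmap_condition("normal")
  } else {
    cmap_condition("t2d",
                   scale = c(IR = 0.55, GLUT4 = 0.5, diabetes = 0.15))
  }
}

#' Apply a condition to a network
#'
#' Returns a new network whose initial values are multiplied by the
#' condition's factors and whose clamped inputs are set to the
#' condition's absolute values; the input network is untouched. A scaled
#' value exceeding the species bound is an error.
#'
#' @param net A `cmap_network`.
#' @param cond A [cmap_condition()].
#' @return The conditioned network.
#' @examples
#' net <- build_insulin_model()$network
#' t2d <- apply_condition(net, insulin_condition("t2d"))
#' initial_state(t2d)[c("IR", "GLUT4", "diabetes")]
#' @export
apply_condition <- function(net, cond) {
  stopifnot(inherits(cond, "cmap_condition"))
  nm <- species_names(net)
  unknown <- setdiff(c(names(cond$scale), names(cond$clamp)), nm)
  if (length(unknown)) {
    stop("condition references unknown species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  init <- initial_state(net)
  init[names(cond$scale)] <- init[names(cond$scale)] * cond$scale
  init[names(cond$clamp)] <- cond$clamp
  cmax <- stats::setNames(vapply(net$species, `[[`, 0, "c_max"), nm)
  clamped <- stats::setNames(vapply(net$species, `[[`, FALSE, "clamped"), nm)
  over <- init > ifelse(clamped, 1, cmax) + 1e-12
  if (any(over)) {
    stop("condition '", cond$name, "' pushes ",
         paste(nm[over], collapse = ", "), " above its bound",
         call. = FALSE)
  }
  set_initial(net, init)
}

#' Run the insulin parameter-search pipeline
#'
#' The six-stage screen for parameter sets reproducing the transient
#' receptor/IRS1 phosphorylation response in both normal and
#' type-2-diabetes cells:
#' \enumerate{
#'   \item draw `cfg$n_sets` random (weights, alphas) assignments;
#'   \item for each set and each condition, run the basal model
#'     (insulin = 0) to steady state — non-convergent sets are discarded
#'     with a logged reason;
#'   \item restart from the basal steady state with insulin clamped to 1
#'     and simulate `n_post` iterations;
#'   \item require `transient_up` on `measuredIRp` and `measuredIRS1p`
#'     (the default rules) in the normal condition;
#'   \item intersect with the sets passing the same rules under T2D;
#'   \item keep sets whose normal response curves lie pointwise at or
#'     above the T2D curves (within `dominance_tol`) for both
#'     observables.
#' }
#'
#' @param cfg A [search_config()]; `cfg$mode` `"first_hit"` stops at the
#'   first survivor.
#' @param rules List of [cmap_rule()]s applied to the post-stimulus
#'   trajectory in each condition. Default: `transient_up` on the two
#'   insulin observables.
#' @param dominance_tol Pointwise slack for the normal-over-T2D
#'   comparison (default 0.01).
#' @param dominance `"pointwise"` (default) or `"auc"`: with `"auc"` the
#'   comparison is on areas under the response curves instead of every
#'   iteration.
#' @param n_post Post-stimulus simulation length (default 500
#'   iterations).
#' @param basal_tol,basal_max_iter Steady-state threshold and iteration
#'   cap for the basal phase (defaults `1e-4` and 5000). The basal state
#'   only anchors the stimulus response, so its tolerance needs to sit
#'   well below the rule excursion threshold (0.05 by default), not at
#'   the engine's general-purpose default: near their fixed point these
#'   networks contract very slowly and a max-norm change of `1e-4` per
#'   step already bounds the remaining drift far beneath anything the
#'   rules can resolve.
#' @return A `cmap_pipeline_result`: list with `outcomes` (one row per
#'   screened set: convergence and per-rule flags for both conditions,
#'   intersection and dominance), `survivors` (set indices passing all
#'   stages), `sets` (the sampled ensemble), `basal_states`,
#'   `trajectories` and `observables` for the survivors, and the
#'   configuration used.
#' @export
run_insulin_pipeline <- function(cfg, rules = NULL, dominance_tol = 0.01,
                                 dominance = c("pointwise", "auc"),
                                 n_post = 500, basal_tol = 1e-4,
                                 basal_max_iter = 5000) {
  dominance <- match.arg(dominance)
  model <- build_insulin_model()
  net <- model$network
  if (is.null(rules)) {
    obs <- insulin_observables()
    rules <- list(cmap_rule("transient_up", obs$measuredIRp),
                  cmap_rule("transient_up", obs$measuredIRS1p))
  }
  conditions <- list(normal = insulin_condition("normal"),
                     t2d = insulin_condition("t2d"))
  nets <- lapply(conditions, function(cd) apply_condition(net, cd))
  compiled <- lapply(nets, compile_network)
  nm <- species_names(net)
  ins <- match("insulin", nm)
  obs_idx <- lapply(rules, function(r) {
    ob <- r$observable
    if (is.character(ob)) ob <- stats::setNames(rep(1, length(ob)), ob)
    list(idx = match(names(ob), nm), w = unname(ob))
  })
  series_of <- function(traj, oi) {
    as.vector(traj[, oi$idx, drop = FALSE] %*% oi$w)
  }
  sets <- sample_parameter_sets(net, cfg)
  nr <- length(rules)
  cols <- c("converged", paste0("rule", seq_len(nr)))
  outcomes <- data.frame(set = seq_len(cfg$n_sets))
  for (cd in names(conditions)) {
    for (cl in cols) {
      outcomes[[paste(cd, cl, sep = "_")]] <- rep(NA, cfg$n_sets)
    }
  }
  outcomes$both <- rep(FALSE, cfg$n_sets)
  outcomes$dominant <- rep(NA, cfg$n_sets)
  survivors <- integer()
  keep_basal <- list()
  keep_traj <- list()
  keep_series <- list()
  for (i in seq_len(cfg$n_sets)) {
    w <- sets$weights[i, ]
    al <- sets$alphas[i, ]
    trajs <- list()
    pass <- TRUE
    for (cd in names(conditions)) {
      cn <- compiled[[cd]]
      bs <- cpp_run_to_steady(cn$init, cn$clamped, cn$cmax, al, cn$tgt,
                              cn$ptr, cn$src, w, cn$sgn, basal_tol,
                              as.integer(basal_max_iter))
      outcomes[[paste0(cd, "_converged")]][i] <- bs$converged
      if (!bs$converged) { pass <- FALSE; break }
      st <- bs$state
      st[ins] <- 1
      traj <- cpp_simulate(st, cn$clamped, cn$cmax, al, cn$tgt, cn$ptr,
                           cn$src, w, cn$sgn, as.integer(n_post))
      trajs[[cd]] <- list(basal = bs$state, traj = traj)
      for (k in seq_len(nr)) {
        ok <- rule_on_series(series_of(traj, obs_idx[[k]]), rules[[k]])
        outcomes[[paste0(cd, "_rule", k)]][i] <- ok
        if (!ok) pass <- FALSE
      }
      if (!pass) break
    }
    outcomes$both[i] <- pass
    if (!pass) next
    dom <- TRUE
    for (k in seq_len(nr)) {
      sa <- series_of(trajs$normal$traj, obs_idx[[k]])
      sb <- series_of(trajs$t2d$traj, obs_idx[[k]])
      dom_k <- if (dominance == "pointwise") {
        all(sa >= sb - dominance_tol)
      } else {
        sum(sa) >= sum(sb) - dominance_tol * length(sa)
      }
      if (!dom_k) { dom <- FALSE; break }
    }
    outcomes$dominant[i] <- dom
    if (dom) {
      survivors <- c(survivors, i)
      id <- as.character(i)
      dimn <- list(0:n_post, nm)
      for (cd in names(conditions)) {
        dimnames(trajs[[cd]]$traj) <- dimn
        names(trajs[[cd]]$basal) <- nm
      }
      keep_basal[[id]] <- lapply(trajs, `[[`, "basal")
      keep_traj[[id]] <- lapply(trajs, `[[`, "traj")
      keep_series[[id]] <- lapply(trajs, function(tr) {
        sapply(obs_idx, function(oi) series_of(tr$traj, oi))
      })
      if (cfg$mode == "first_hit") break
    }
  }
  structure(list(outcomes = outcomes,
                 survivors = survivors,
                 sets = sets,
                 rules = rules,
                 basal_states = keep_basal,
                 trajectories = keep_traj,
                 observable_series = keep_series,
                 config = cfg,
                 dominance = dominance,
                 dominance_tol = dominance_tol,
                 n_post = n_post,
                 basal_tol = basal_tol,
                 basal_max_iter = basal_max_iter),
            class = "cmap_pipeline_result")
}

#' @export
print.cmap_pipeline_result <- function(x, ...) {
  screened <- sum(!is.na(x$outcomes$normal_converged))
  cat(sprintf(paste0("insulin pipeline: %d set(s) screened, %d passed ",
                     "both conditions, %d survivor(s)\n"),
              screened, sum(x$outcomes$both, na.rm = TRUE),
              length(x$survivors)))
  invisible(x)
}
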