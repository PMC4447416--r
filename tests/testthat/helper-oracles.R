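# Independent pure-R oracle for one synchronous update: aggregates causal
# input by looping over influences directly, evaluates the sigmoid through
# its closed tanh form and applies the range restriction with plain
# if/else. Deliberately shares no code with the package's stepping path.
oracle_step <- function(net, state) {
  nm <- species_names(net)
  state <- state[nm]
  out <- state
  for (s in net$species) {
    if (s$clamped) next
    x <- 0
    for (inf in net$influences) {
      if (inf$target == s$name) {
        x <- x + inf$sign * inf$weight * prod(state[inf$sources])
      }
    }
    f <- tanh(s$alpha * x / 2)
    lam <- if (f > 0) s$c_max - state[[s$name]] else state[[s$name]]
    out[[s$name]] <- state[[s$name]] + lam * f
  }
  out
}

fixture <- function(name) {
  system.file("extdata", name, package = "causalmap", mustWork = TRUE)
}

# Random ODE model over n species: every non-clamped component gets 1-4
# signed mass-action terms; roughly one in five terms carries a Hill
# saturation descriptor.
random_ode_model <- function(n = 5) {
  nm <- sprintf("M%02d", seq_len(n))
  clamped <- nm[n]
  k <- 0
  comps <- lapply(nm, function(x) {
    if (x == clamped) return(ode_component(x, initial = runif(1)))
    terms <- lapply(seq_len(sample(1:4, 1)), function(i) {
      k <<- k + 1
      sat <- if (runif(1) < 0.2) {
        list(substrate = sample(nm, 1), km = paste0("km", k),
             n = paste0("n", k))
      }
      ode_term(sample(c(-1, 1), 1), paste0("k", k),
               factors = sample(nm, sample(1:2, 1), replace = TRUE),
               saturation = sat)
    })
    ode_component(x, initial = runif(1), terms = terms)
  })
  ode_model(comps, clamped = clamped)
}
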