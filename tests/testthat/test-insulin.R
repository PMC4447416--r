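test_that("the insulin model matches its printed composition", {
  mod <- build_insulin_model()
  net <- mod$network
  clamped <- vapply(net$species, `[[`, FALSE, "clamped")
  expect_equal(sum(!clamped), 27)
  expect_setequal(species_names(net)[clamped], c("insulin", "diabetes"))
  init <- initial_state(net)
  expect_equal(init[["insulin"]], 0)
  expect_equal(init[["diabetes"]], 1)
  # the IRS1 pool is a complete moiety: its printed initials sum to 1
  expect_equal(sum(init[c("IRS1", "IRS1p", "IRS1p307", "IRS1307")]), 1)
  expect_length(net$influences, 72)
  # serine-307 phosphorylation is third order: IRS1p * mTORC1a * diabetes
  third <- Filter(function(i) length(i$sources) == 3, net$influences)
  expect_length(third, 2)
  expect_setequal(vapply(third, `[[`, "", "target"),
                  c("IRS1p", "IRS1p307"))
  for (i in third) {
    expect_setequal(i$sources, c("IRS1p", "mTORC1a", "diabetes"))
  }
  expect_length(validate_ode_model(mod$ode), 0)
})

test_that("conditions rescale initial values exactly as specified", {
  net <- build_insulin_model()$network
  normal <- apply_condition(net, insulin_condition("normal"))
  expect_equal(initial_state(normal), initial_state(net))
  t2d <- apply_condition(net, insulin_condition("t2d"))
  init <- initial_state(t2d)
  expect_equal(init[["IR"]], 0.55)
  expect_equal(init[["GLUT4"]], 0.30)
  expect_equal(init[["diabetes"]], 0.15)
  # untouched species keep their values; the input is not mutated
  expect_equal(init[["IRS1"]], 0.8)
  expect_equal(initial_state(net)[["IR"]], 1)
  expect_error(
    apply_condition(net, cmap_condition("over", scale = c(IRS1 = 2))),
    "above its bound")
  expect_error(
    apply_condition(net, cmap_condition("x", scale = c(nope = 0.5))),
    "unknown species")
})

test_that("a converged basal state is a fixed point under zero insulin", {
  net <- apply_condition(build_insulin_model()$network,
                         insulin_condition("normal"))
  tol <- 1e-6
  bs <- run_to_steady_state(net, tol = tol, max_iter = 20000)
  expect_true(bs$converged)
  after <- cmap_step(net, bs$state)
  expect_lt(max(abs(after - bs$state)), tol)
})

test_that("with diabetes at zero its third-order influences vanish", {
  net <- build_insulin_model()$network
  state <- initial_state(net)
  state["diabetes"] <- 0
  state["IRS1p"] <- 0.5
  state["mTORC1a"] <- 0.5
  # the only negative input on IRS1p307 targets would include the
  # diabetes product; compare against the network with those edges removed
  stripped <- net
  stripped$influences <- Filter(function(i) !"diabetes" %in% i$sources,
                                net$influences)
  expect_equal(causal_input(net, state, "IRS1p307"),
               causal_input(stripped, state, "IRS1p307"))
  t_full <- cmap_simulate(net, initial = state, n_iter = 50)
  t_stripped <- cmap_simulate(stripped, initial = state, n_iter = 50)
  expect_equal(unclass(t_full), unclass(t_stripped), tolerance = 1e-15)
})

test_that("a degenerate zero-set pipeline returns an empty valid result", {
  res <- run_insulin_pipeline(search_config(0, seed = 1))
  expect_s3_class(res, "cmap_pipeline_result")
  expect_length(res$survivors, 0)
  expect_equal(nrow(res$outcomes), 0)
  expect_length(res$trajectories, 0)
})

test_that("pipeline stages nest and survivors replay through the public API", {
  cfg <- search_config(3000, seed = 1, mode = "collect")
  res <- run_insulin_pipeline(cfg)
  o <- res$outcomes
  pass_cond <- function(cd) {
    ok <- o[[paste0(cd, "_converged")]] & o[[paste0(cd, "_rule1")]] &
      o[[paste0(cd, "_rule2")]]
    which(!is.na(ok) & ok)
  }
  both <- which(o$both)
  dom <- which(!is.na(o$dominant) & o$dominant)
  # survivors within dominance within intersection within each ensemble
  expect_true(all(res$survivors %in% dom))
  expect_true(all(dom %in% both))
  expect_true(all(both %in% pass_cond("normal")))
  expect_true(all(both %in% pass_cond("t2d")))
  expect_gt(length(res$survivors), 0)

  # independently replay one survivor through the exported operations
  i <- res$survivors[1]
  params <- list(weights = res$sets$weights[i, ],
                 alphas = res$sets$alphas[i, ])
  net <- build_insulin_model()$network
  obs <- insulin_observables()
  trajs <- list()
  for (cd in c("normal", "t2d")) {
    cnet <- apply_condition(net, insulin_condition(cd))
    bs <- run_to_steady_state(cnet, tol = res$basal_tol,
                              max_iter = res$basal_max_iter,
                              params = params)
    expect_true(bs$converged)
    st <- bs$state
    st["insulin"] <- 1
    traj <- cmap_simulate(cnet, initial = st, n_iter = res$n_post,
                          params = params)
    for (ob in obs) {
      expect_true(evaluate_rule(traj, cmap_rule("transient_up", ob)))
    }
    expect_equal(unclass(traj), unclass(res$trajectories[[as.character(i)]][[cd]]),
                 tolerance = 1e-12)
    trajs[[cd]] <- traj
  }
  for (ob in obs) {
    expect_true(check_dominance(trajs$normal, trajs$t2d, ob, tol = 0.01))
  }
})
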