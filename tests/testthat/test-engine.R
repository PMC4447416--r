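test_that("causal input aggregates signed weighted source products", {
  net <- cmap_network(
    list(cmap_species("A"), cmap_species("B"), cmap_species("P"),
         cmap_species("Q")),
    list(cmap_influence("P", "A", 0.5, +1),
         cmap_influence("Q", c("A", "B"), 0.5, +1)))
  state <- c(A = 0.5, B = 0.4, P = 0, Q = 0)
  expect_equal(causal_input(net, state, "B"), 0)      # nothing targets B
  expect_equal(causal_input(net, state, "P"), 0.25)   # 0.5 * 0.5
  expect_equal(causal_input(net, state, "Q"), 0.10)   # 0.5 * 0.5 * 0.4
  expect_error(causal_input(net, state, "Z"), "unknown species")
})

test_that("causal function is an odd, increasing, saturating sigmoid", {
  expect_equal(causal_function(0, 1.2), 0)
  expect_equal(causal_function(1, 1.2), 0.53705, tolerance = 1e-5)
  expect_equal(causal_function(-1, 1.2), -causal_function(1, 1.2))
  x <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(causal_function(x, 2)) > 0))
  expect_true(all(abs(causal_function(x, 2)) < 1))
  # saturates without overflowing for huge inputs
  expect_equal(causal_function(1e6, 5), 1)
  expect_equal(causal_function(-1e6, 5), -1)
  expect_lt(causal_function(30, 1.2), 1)
  # steeper alpha is more responsive
  expect_gt(causal_function(0.5, 4), causal_function(0.5, 1.2))
})

test_that("causal function equals tanh(alpha x / 2) to 1e-12 relative", {
  x <- seq(-50, 50, length.out = 2001)
  for (alpha in c(0.5, 1.2, 3, 5)) {
    f <- causal_function(x, alpha)
    g <- tanh(alpha * x / 2)
    expect_lt(max(abs(f - g) / pmax(abs(g), 1e-300)), 1e-12)
  }
})

test_that("range restriction uses headroom above, current value below", {
  expect_equal(lambda_restrict(0.3, 0.2, 1), 0.7)
  expect_equal(lambda_restrict(0.3, -0.1, 1), 0.3)
  expect_equal(lambda_restrict(0, -0.5, 1), 0)   # cannot go negative
  expect_equal(lambda_restrict(1, 0.9, 1), 0)    # cannot exceed the bound
  expect_equal(lambda_restrict(0.3, 0.2, 0.8), 0.5)
})

test_that("single steps match hand-evaluated updates", {
  # positive motif: x_P = 0.5, f = 0.29131, headroom 1
  s <- cmap_step(build_motif("positive"))
  expect_equal(s[["P"]], 0.29131, tolerance = 1e-5)
  expect_equal(s[["A"]], 1)  # clamped input untouched
  # negative self-influence from P = 0.8: x = -0.4, f = -0.23550
  s <- cmap_step(build_motif("negative_self"))
  expect_equal(s[["P"]], 0.61160, tolerance = 1e-5)
})

test_that("the all-zero state with no active inputs is a fixed point", {
  net <- cmap_network(
    list(cmap_species("A", 0), cmap_species("B", 0)),
    list(cmap_influence("B", "A", 0.9, +1),
         cmap_influence("A", "B", 0.9, -1)))
  expect_equal(cmap_step(net), c(A = 0, B = 0))
})

test_that("compiled stepping agrees with an independent pure-R oracle", {
  set.seed(42)
  for (rep in 1:25) {
    net <- random_network(n_species = sample(2:8, 1),
                          n_influences = sample(1:12, 1))
    state <- initial_state(net)
    for (k in 1:5) {
      expected <- oracle_step(net, state)
      got <- cmap_step(net, state)
      expect_equal(got, expected, tolerance = 1e-12)
      state <- got
    }
  }
})

test_that("simulation is deterministic and composes single steps", {
  net <- build_motif("combined")
  t1 <- cmap_simulate(net, n_iter = 50)
  t2 <- cmap_simulate(net, n_iter = 50)
  expect_identical(unclass(t1), unclass(t2))
  expect_equal(nrow(t1), 51)
  one <- cmap_simulate(net, n_iter = 1)
  expect_equal(one[2, ], cmap_step(net))
  expect_error(cmap_simulate(net, initial = c(A = 2, P = 0), n_iter = 1),
               "out of bounds")
})

test_that("trajectories stay within [0, c_max] for random networks", {
  set.seed(7)
  for (rep in 1:60) {
    net <- random_network(n_species = sample(2:6, 1),
                          n_influences = sample(1:10, 1),
                          cmax_range = c(0.5, 1))
    cmax <- vapply(net$species, `[[`, 0, "c_max")
    clamped <- vapply(net$species, `[[`, FALSE, "clamped")
    hi <- ifelse(clamped, 1, cmax)
    traj <- cmap_simulate(net, n_iter = 100)
    expect_true(all(traj >= 0))
    expect_true(all(t(traj) <= hi + 1e-12))
  }
})

test_that("raising a positive weight never lowers the one-step update", {
  set.seed(11)
  for (rep in 1:20) {
    net <- random_network(n_species = 4, n_influences = 6)
    pos <- which(vapply(net$influences, `[[`, 0L, "sign") > 0)
    if (!length(pos)) next
    i <- pos[1]
    tgt <- net$influences[[i]]$target
    w <- vapply(net$influences, `[[`, 0, "weight")
    w2 <- w
    w2[i] <- min(1, w[i] + 0.3)
    s1 <- cmap_step(net, params = list(weights = w))
    s2 <- cmap_step(net, params = list(weights = w2))
    expect_gte(s2[[tgt]], s1[[tgt]] - 1e-12)
  }
})

test_that("parameter overrides are applied and unknown names rejected", {
  net <- build_motif("positive")
  s <- cmap_step(net, params = list(weights = c(1), alphas = c(P = 5)))
  # x = 1, f = tanh(2.5)
  expect_equal(s[["P"]], tanh(2.5), tolerance = 1e-12)
  expect_error(cmap_step(net, params = list(alphas = c(Q = 2))),
               "unknown species")
  expect_error(cmap_step(net, params = list(weights = c(bogus = 0.1))),
               "unknown influence")
  expect_error(cmap_step(net, params = list(weights = c(0.1, 0.2))),
               "length")
})

test_that("steady-state detection converges, reports, and caps", {
  # no influences: nothing moves, converges immediately
  net0 <- cmap_network(list(cmap_species("A", 0.4)))
  r <- run_to_steady_state(net0)
  expect_true(r$converged)
  expect_equal(r$iterations, 0)
  expect_equal(r$state, c(A = 0.4))
  # self-limited decay ends near zero; the step there is ~0.3 P^2, so
  # step < tol puts P within sqrt(tol / 0.3) of the fixed point
  r <- run_to_steady_state(build_motif("negative_self"), tol = 1e-6)
  expect_true(r$converged)
  expect_lt(r$state[["P"]], sqrt(1e-6 / 0.3) * 1.1)
  # slow negative feedback: flag false at a small cap, no exception
  slow <- cmap_network(
    list(cmap_species("A", 1, alpha = 5), cmap_species("B", 0, alpha = 2)),
    list(cmap_influence("B", "A", 0.05, +1),
         cmap_influence("A", "B", 1, -1),
         cmap_influence("A", "A", 1, +1)))
  r <- run_to_steady_state(slow, tol = 1e-9, max_iter = 30)
  expect_false(r$converged)
  expect_equal(r$iterations, 30)
})

test_that("observables and the TSV writer expose trajectory columns", {
  traj <- cmap_simulate(build_motif("positive"), n_iter = 10)
  s <- observable_series(traj, c("A", "P"))
  expect_equal(s, unname(traj[, "A"] + traj[, "P"]))
  sw <- observable_series(traj, c(A = 0.5, P = 2))
  expect_equal(sw, unname(0.5 * traj[, "A"] + 2 * traj[, "P"]))
  expect_error(observable_series(traj, "nope"), "unknown species")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, tmp, observables = list(total = c("A", "P")))
  tab <- read.delim(tmp)
  expect_equal(dim(tab), c(11, 4))
  expect_equal(tab$iteration, 0:10)
  expect_equal(tab$total, unname(s))
})
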