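# structural properties of the experiment engines; the expensive
# steady-state solves are shared with the acceptance suite via the cache

test_that("deterministic solves converge to a near-stationary tail", {
  ss <- cached_steady_state(0)
  y <- ss$solution$years
  tail10 <- utils::tail(y, 10)
  # the final decade of the optimized horizon is close to stationary
  expect_lt(stats::sd(tail10$herd) / mean(tail10$herd), 0.02)
  expect_lt(stats::sd(tail10$net_revenue) / mean(tail10$net_revenue), 0.05)
  # applying one model year at the converged steady state returns it
  one <- year_step(ss$state, ss$decision, "normal", default_params())
  expect_equal(sum(one$state$females) + sum(one$state$males),
               sum(ss$state$females) + sum(ss$state$males),
               tolerance = 0.02)
  expect_equal(one$state$lichen_biomass, ss$state$lichen_biomass,
               tolerance = 0.02 * ss$state$lichen_biomass)
})

test_that("infeasible initial states are rejected", {
  p <- default_params()
  empty <- population_state(numeric(17), rep(1, 13), 1000, params = p)
  expect_error(solve_deterministic(empty, 0, p), "no adult females")
})

test_that("all-normal feedback reproduces the deterministic solution", {
  ss <- cached_steady_state(0.03)
  fb <- feedback_solve(ss$state, rep("normal", 25), 0.03, ss = ss)
  # certainty-equivalence consistency: under constant expected winters the
  # feedback path stays at the deterministic steady state
  expect_equal(mean(fb$years$net_revenue), ss$net_revenue,
               tolerance = 0.02 * ss$net_revenue)
  expect_lt(max(abs(fb$years$lichen - ss$lichen_biomass)),
            0.03 * ss$lichen_biomass)
})

test_that("stored feedback trajectories re-simulate to the same PV", {
  ss <- cached_steady_state(0.03)
  sc <- c("difficult", rep("normal", 4), "easy", rep("normal", 2))
  fb <- feedback_solve(ss$state, sc, 0.03, ss = ss)
  re <- simulate_trajectory(ss$state, fb$decisions, fb$winters,
                            default_params(), type = "escapement")
  expect_equal(present_value(re$years$net_revenue, 0.03), fb$pv,
               tolerance = 1e-8 * abs(fb$pv))
})

test_that("ensembles are reproducible under a fixed seed", {
  ss <- cached_steady_state(0.03)
  e1 <- stochastic_ensemble(winter_probs(), reps = 2, r = 0.03, horizon = 6,
                            seed = 5, ss = ss)
  e2 <- stochastic_ensemble(winter_probs(), reps = 2, r = 0.03, horizon = 6,
                            seed = 5, ss = ss)
  expect_identical(e1$pv_reps, e2$pv_reps)
  expect_identical(e1$loss, e2$loss)
  # degenerate distribution: no loss relative to constant winters
  e0 <- stochastic_ensemble(winter_probs(0, 1, 0), reps = 1, r = 0.03,
                            horizon = 6, ss = ss)
  expect_equal(e0$loss, 0, tolerance = 1e-9 * abs(e0$pv_constant))
})

test_that("prohibitive feed prices collapse feeding to the no-feeding solution", {
  ss <- cached_steady_state(0.03)
  sc <- c("difficult", "normal", "normal")
  exp_cheap <- feeding_policy_experiment(0.03, sc, params = default_params(),
                                         ss = ss)
  exp_dear <- feeding_policy_experiment(0.03, sc, feed_price = 500, ss = ss)
  expect_lt(max(exp_dear$feed_kg), 1)
  expect_equal(exp_dear$pv_with, exp_dear$pv_without,
               tolerance = 0.001 * abs(exp_dear$pv_without))
  expect_gte(exp_cheap$pv_with, exp_cheap$pv_without -
               1e-4 * abs(exp_cheap$pv_without))
})
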