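# The optimizer strategy (smooth NLP over box-constrained decision
# schedules) is validated against exhaustive backward induction on a
# reduced instance: one aggregated animal stock plus the lichen state.

test_that("NLP solve matches the backward-induction oracle within 1%", {
  mod <- reduced_model()
  dp <- reduced_dp_solve(mod, n0 = 150, x0 = 1200, horizon = 30, r = 0.03)
  nlp <- reduced_nlp_solve(mod, n0 = 150, x0 = 1200, horizon = 30, r = 0.03)
  expect_lt(abs(nlp$pv - dp$pv) / dp$pv, 0.01)
  expect_lt(abs(nlp$pv - dp$value) / dp$value, 0.01)
})

test_that("the optimum dominates a randomized feasible-policy suite", {
  mod <- reduced_model()
  nlp <- reduced_nlp_solve(mod, n0 = 150, x0 = 1200, horizon = 30, r = 0.03)
  set.seed(77)
  rand_pv <- replicate(1000, reduced_simulate(mod, 150, 1200,
                                              runif(30), 0.03)$pv)
  expect_gte(nlp$pv, max(rand_pv))
})

test_that("reduced dynamics respect their bounds", {
  mod <- reduced_model()
  sim <- reduced_simulate(mod, 150, 1200, runif(50), 0.03)
  expect_true(all(sim$years$lichen >= 0 & sim$years$lichen <= mod$K))
  expect_true(all(sim$years$herd >= 0))
})
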