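p0 <- default_params()

test_that("cash-flow components add up", {
  st <- population_state(c(100, rep(10, 16)), c(80, rep(2, 12)), 1000,
                         params = p0)
  dec <- herd_decision(c(0.6, rep(0, 16)), c(0.95, rep(0, 12)),
                       feed_kg = 10000, params = p0)
  sl <- apply_slaughter(st, dec, p0)
  cf <- net_revenue(sl, dec, wintered_stock = 250, econ = p0$econ)
  expect_equal(cf$feeding_cost, 10000 * 0.4)  # EUR 0.4 per kg delivered
  # independent summation of the components
  rev <- sl$meat_calf_kg * p0$econ$meat_price_calf +
    (sl$meat_kg - sl$meat_calf_kg) * p0$econ$meat_price_adult +
    p0$econ$subsidy_per_animal * (sum(sl$state$females) + sum(sl$state$males))
  oth <- p0$econ$herding_cost * 250 + p0$econ$slaughter_cost * sl$n_slaughtered
  expect_equal(cf$revenue, rev, tolerance = 1e-9)
  expect_equal(cf$net_revenue, rev - cf$feeding_cost - oth, tolerance = 1e-9)
})

test_that("zero slaughter and feed leaves subsidies minus herd costs", {
  st <- population_state(rep(10, 17), rep(5, 13), 1000, params = p0)
  dec <- herd_decision(rep(0, 17), rep(0, 13), params = p0)
  sl <- apply_slaughter(st, dec, p0)
  cf <- net_revenue(sl, dec, wintered_stock = 235, econ = p0$econ)
  expect_equal(cf$net_revenue,
               p0$econ$subsidy_per_animal * 235 - p0$econ$herding_cost * 235)
})

test_that("present values follow the discounting conventions", {
  expect_equal(present_value(rep(100, 3), 0), 300)
  expect_equal(present_value(c(0, 103), 0.03), 100)
  # constant flow vs the closed-form annuity (geometric series)
  r <- 0.04; n <- 100
  annuity <- 1000 * (1 - (1 + r)^-n) / r * (1 + r)  # first flow undiscounted
  expect_equal(present_value(rep(1000, n), r), annuity, tolerance = 1e-6)
  expect_error(present_value(1:3, -0.01), "non-negative")
})

test_that("present value is strictly decreasing in the interest rate", {
  flows <- c(100, 120, 90, 150, 200)
  rates <- c(0, 0.01, 0.03, 0.05)
  pv <- sapply(rates, function(r) present_value(flows, r))
  expect_true(all(diff(pv) < 0))
})

test_that("front-loaded costs discount worse than undiscounted", {
  # a loss now with gains later: the discounted total cost exceeds the
  # undiscounted one
  deltas <- c(5000, rep(-300, 10))  # cost in year 1, gains afterwards
  undisc <- sum(deltas)
  disc <- present_value(deltas, 0.03)
  expect_gt(disc, undisc)
})
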