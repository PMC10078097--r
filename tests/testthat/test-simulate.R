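p0 <- default_params()

test_that("the compiled stepper reproduces the R reference step exactly", {
  st <- reference_herd(p0, n_females = 160, lichen_biomass = 700)
  for (lab in c("easy", "normal", "difficult")) {
    for (feed in c(0, 20000)) {
      dec <- poroeco:::canonical_decision(p0, feed_kg = feed)
      ref <- year_step(st, dec, lab, p0)
      tr <- simulate_trajectory(st, dec, lab, p0)
      expect_equal(tr$years$net_revenue, ref$cashflow$net_revenue,
                   tolerance = 1e-10)
      expect_equal(tr$years$calf_pct, ref$diagnostics$calf_pct,
                   tolerance = 1e-10)
      expect_equal(tr$final_state$females, ref$state$females,
                   tolerance = 1e-10)
      expect_equal(tr$final_state$males, ref$state$males, tolerance = 1e-10)
      expect_equal(tr$final_state$lichen_biomass, ref$state$lichen_biomass,
                   tolerance = 1e-10)
    }
  }
})

test_that("R and compiled escapement slaughter agree", {
  st <- reference_herd(p0, n_females = 160, lichen_biomass = 900)
  kappa <- c(st$females * 0.8, st$males * 0.8)
  dec <- herd_decision(kappa[1:17], kappa[18:30], 0, p0, type = "escapement")
  ref <- year_step(st, dec, "normal", p0)
  dm <- matrix(c(kappa, 0), 1, 31)
  tr <- simulate_trajectory(st, dm, "normal", p0, type = "escapement")
  expect_equal(tr$final_state$females, ref$state$females, tolerance = 1e-10)
  expect_equal(tr$years$net_revenue, ref$cashflow$net_revenue,
               tolerance = 1e-10)
})

test_that("stored trajectories re-simulate to themselves", {
  st <- reference_herd(p0, n_females = 200, lichen_biomass = 1000)
  dec <- poroeco:::canonical_decision(p0)
  winters <- rep(c("normal", "difficult", "normal", "easy"), 5)
  t1 <- simulate_trajectory(st, dec, winters, p0)
  t2 <- simulate_trajectory(st, t1$decisions, t1$winters, p0)
  expect_identical(t1$years$net_revenue, t2$years$net_revenue)
  expect_identical(t1$final_state$females, t2$final_state$females)
})

test_that("animal counts stay non-negative under feasible decisions", {
  st <- reference_herd(p0, n_females = 150, lichen_biomass = 600)
  set.seed(4)
  for (i in 1:10) {
    dec <- herd_decision(runif(17), runif(13), runif(1, 0, 5e4), p0)
    winters <- sample(c("easy", "normal", "difficult"), 30, replace = TRUE)
    tr <- simulate_trajectory(st, dec, winters, p0)
    expect_true(all(tr$final_state$females >= 0))
    expect_true(all(tr$final_state$males >= 0))
    expect_true(all(tr$years$herd >= 0))
  }
})

test_that("calf-percentage anchors match the reported calibration", {
  expect_equal(simulate_calf_percentage(500, "normal", p0), 52,
               tolerance = 0.02)
  expect_equal(simulate_calf_percentage(500, "difficult", p0), 30,
               tolerance = 0.02)
})
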