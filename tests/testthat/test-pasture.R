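p0 <- default_params()

test_that("grazing removes biomass with a floor at zero", {
  pa <- lichen_pasture(1000, p0)
  expect_equal(graze(pa, 0)$biomass, 1000)
  # N animals removing m kg/day for d days -> drop N*m*d/area
  expect_equal(graze(pa, 300 * 1.5 * 200)$biomass, 1000 - 90)
  expect_equal(graze(pa, 2e6)$biomass, 0)
  expect_error(graze(pa, -1), "non-negative")
})

test_that("logistic regrowth vanishes at the boundaries with argmax at K/2", {
  K <- p0$pasture$K
  expect_equal(grow(lichen_pasture(K, p0))$biomass, K)
  expect_equal(grow(lichen_pasture(0, p0))$biomass, 0)
  xs <- seq(50, K - 50, by = 50)
  g <- sapply(xs, function(x) grow(lichen_pasture(x, p0))$biomass - x)
  # analytic argmax of r x (1 - x/K) is K/2
  expect_equal(xs[which.max(g)], K / 2)
})

test_that("biomass stays in [0, K] along any feasible trajectory", {
  p <- default_params()
  st <- reference_herd(p, n_females = 300, lichen_biomass = 800)
  dec <- poroeco:::canonical_decision(p)
  set.seed(99)
  winters <- sample(c("easy", "normal", "difficult"), 120, replace = TRUE)
  tr <- simulate_trajectory(st, dec, winters, p)
  expect_true(all(tr$years$lichen >= 0))
  expect_true(all(tr$years$lichen <= p$pasture$K))
})

test_that("difficult winters protect the pasture at the same state", {
  p <- default_params()
  st <- reference_herd(p, n_females = 200, lichen_biomass = 500)
  dec <- poroeco:::canonical_decision(p)
  x_after <- sapply(c("easy", "normal", "difficult"), function(lab)
    year_step(st, dec, lab, p)$state$lichen_biomass)
  # lichen increases (relatively) as winters harden: reduced consumption
  # and wastage under difficult cratering conditions
  expect_true(x_after[["difficult"]] > x_after[["normal"]])
  expect_true(x_after[["normal"]] > x_after[["easy"]])
})
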