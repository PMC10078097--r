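p0 <- default_params()

test_that("winter types map to their cratering area and energy multiplier", {
  expect_equal(winter_parameters("easy")$cratering_area, 34)
  expect_equal(winter_parameters("normal")$cratering_area, 30)
  expect_equal(winter_parameters("difficult")$cratering_area, 26)
  expect_equal(winter_parameters("easy")$energy_multiplier, 0.94)
  expect_equal(winter_parameters("normal")$energy_multiplier, 1.00)
  expect_equal(winter_parameters("difficult")$energy_multiplier, 1.06)
  expect_error(winter_parameters("harsh"), "unknown winter type")
})

test_that("daily energy needs scale with the multiplier and body mass", {
  nf <- daily_energy_need(5, "female", "normal")
  expect_true(abs(nf - 18) < 0.6)  # adult female ~18 MJ/winter day
  expect_equal(daily_energy_need(5, "female", "difficult"), nf * 1.06)
  # multiplier symmetry holds for every class
  for (a in c(0, 3, 9)) {
    e <- daily_energy_need(a, "female", "easy")
    d <- daily_energy_need(a, "female", "difficult")
    expect_equal(e / d, 0.94 / 1.06)
  }
  # needs ordered easy < normal < difficult for all classes
  for (sex in c("female", "male")) {
    n_cl <- if (sex == "female") 17 else 13
    for (a in 0:(n_cl - 1)) {
      v <- sapply(c("easy", "normal", "difficult"),
                  function(l) daily_energy_need(a, sex, l))
      expect_true(all(diff(v) > 0))
    }
  }
})

test_that("diet choice follows lichen availability", {
  wp <- winter_parameters("normal")
  for (x in c(1001, 1500, 2500)) {
    d <- diet_choice(list(lichen_biomass = x), wp, 18, p0)
    expect_gt(d$lichen_share, 0.80)
  }
  for (x in c(100, 200, 299)) {
    d <- diet_choice(list(lichen_biomass = x), wp, 18, p0)
    expect_lt(d$lichen_share, 0.50)  # other cratered food dominates
  }
  d0 <- diet_choice(list(lichen_biomass = 0), wp, 18, p0)
  expect_equal(d0$energy_from_lichen, 0)
  expect_equal(d0$lichen_removed, 0)
  expect_error(diet_choice(list(lichen_biomass = -5), wp, 18, p0),
               "non-negative")
})

test_that("lichen intake is monotone in biomass and cratering area", {
  wp <- winter_parameters("normal")
  xs <- seq(50, 2900, by = 150)
  el <- sapply(xs, function(x)
    diet_choice(list(lichen_biomass = x), wp, 18, p0)$energy_from_lichen)
  expect_true(all(diff(el) > -1e-9))
  for (x in c(200, 400, 800)) {
    ints <- sapply(c("difficult", "normal", "easy"), function(l)
      diet_choice(list(lichen_biomass = x), winter_parameters(l), 18,
                  p0)$energy_from_lichen +
        diet_choice(list(lichen_biomass = x), winter_parameters(l), 18,
                    p0)$energy_from_other)
    expect_true(all(diff(ints) > -1e-9))
  }
})

test_that("time-budget compensation makes high-biomass intake area-independent", {
  need <- 18
  total <- function(x, lab) {
    d <- diet_choice(list(lichen_biomass = x), winter_parameters(lab), need, p0)
    d$energy_from_lichen + d$energy_from_other
  }
  # abundant lichen: the reduced cratering area is fully compensated
  expect_equal(total(2000, "difficult"), total(2000, "normal"), tolerance = 1e-6)
  # scarce lichen: intake scales with the cratering area
  expect_lt(total(300, "difficult"), total(300, "normal") - 0.3)
})

test_that("supplement fills the deficit and is capped by the offer", {
  wp <- winter_parameters("difficult")
  d <- diet_choice(list(lichen_biomass = 250, supplement_offered = 0.5),
                   wp, 18, p0)
  d0 <- diet_choice(list(lichen_biomass = 250), wp, 18, p0)
  expect_equal(d$energy_from_supplement,
               min(0.5 * p0$energetics$me_supplement, d0$deficit))
  expect_equal(d$deficit, d0$deficit - d$energy_from_supplement)
})

test_that("energy balance converts deficits to weight loss", {
  W <- 200; sm <- 68
  expect_equal(winter_energy_balance(18, 18, W, sm, p0), 0)
  # moderate deficit (inside the linear regime): exact energy conservation
  dw <- winter_energy_balance(0.95 * 18, 18, W, sm, p0)
  expect_equal(-dw * p0$energetics$gamma_tissue / W, 0.05 * 18,
               tolerance = 1e-9)
  # extreme deficit saturates below the physiological cap
  dw2 <- winter_energy_balance(0, 18, W, sm, p0)
  expect_gt(-dw2 / sm, p0$energetics$loss_lin)
  expect_lt(-dw2 / sm, p0$energetics$loss_max)
  # surplus yields a bounded gain
  expect_lte(winter_energy_balance(36, 18, W, sm, p0),
             p0$energetics$gain_cap_kg)
  expect_gt(winter_energy_balance(36, 18, W, sm, p0), 0)
})

test_that("crusted-snow expenditure arithmetic reproduces the 6% increase", {
  pct <- energy_need_increase()
  expect_true(abs(pct - 6) < 1)
  # identical expenditure ranges give zero increase
  expect_equal(energy_need_increase(c(1.2, 1.5), c(1.2, 1.5)), 0)
  # linear in cratering time
  expect_equal(energy_need_increase(cratering_hours = 16), 2 * pct)
})
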