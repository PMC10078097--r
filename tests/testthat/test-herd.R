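p0 <- default_params()

herd_state <- function(f_counts, m_counts, x = 1500, cond = NULL) {
  f <- numeric(17); m <- numeric(13)
  f[seq_along(f_counts)] <- f_counts
  m[seq_along(m_counts)] <- m_counts
  population_state(f, m, x, condition = cond, params = p0)
}

test_that("reproduction vanishes without males and saturates with many", {
  st0 <- herd_state(c(0, 0, 10, 10), c(0, 0, 0))
  expect_equal(reproduce(st0, p0)$births, 0)
  st_many <- herd_state(c(0, 0, 10, 10), c(0, 0, 1e6))
  r <- reproduce(st_many, p0)
  # fecundity ceiling: the classes' maximum rates with certain mating
  ceiling <- sum(c(10, 10) * p0$herd$fec_max[3:4])
  expect_equal(r$births, ceiling, tolerance = 0.01)
  expect_equal(r$mating_probability, 1, tolerance = 0.01)
})

test_that("small herds match a direct harmonic-mean evaluation", {
  # brute-force oracle: births = sum(fec * f) * min(1, 2z/(1+z)),
  # z = harem * effective males / breeding females
  h <- p0$herd
  cases <- list(list(f = c(3, 5), m = 2), list(f = c(1, 2), m = 1),
                list(f = c(2, 1), m = 0.3))
  for (cs in cases) {
    st <- herd_state(c(0, 0, cs$f), c(0, 0, 0, cs$m))
    got <- reproduce(st, p0)$births
    z <- h$harem_size * (cs$m * h$male_weight[4]) / sum(cs$f)
    p_oracle <- min(1, 2 * z / (1 + z))
    want <- sum(cs$f * h$fec_max[3:4]) * p_oracle
    expect_equal(got, want, tolerance = 0.02 * want + 1e-8)
  }
})

test_that("reproduction is monotone in male and female counts", {
  males <- seq(0, 20, by = 1)
  b_m <- sapply(males, function(m)
    reproduce(herd_state(c(0, 0, 50, 50), c(0, 0, m)), p0)$births)
  expect_true(all(diff(b_m) > -1e-9))
  females <- seq(10, 200, by = 10)
  b_f <- sapply(females, function(fem)
    reproduce(herd_state(c(0, 0, fem), c(0, 0, 5)), p0)$births)
  expect_true(all(diff(b_f) > 0))
})

test_that("survival is the baseline without weight loss and declines with it", {
  st <- herd_state(rep(10, 17), rep(5, 13))
  zero <- list(f = numeric(17), m = numeric(13))
  out <- survive_and_age(st, zero, p0)
  expect_equal(out$survival$f, p0$herd$s_base_f, tolerance = 1e-9)
  # survival monotone in the deficit over a grid of losses
  losses <- seq(0, 40, by = 5)
  s <- sapply(losses, function(L) {
    dw <- list(f = rep(-L, 17), m = rep(-L, 13))
    survive_and_age(st, dw, p0)$survival$f[5]
  })
  expect_true(all(diff(s) < 1e-12))
  expect_lt(s[length(s)], s[1])
})

test_that("aging conserves or reduces animals and shifts classes", {
  st <- herd_state(rep(10, 17), rep(5, 13))
  zero <- list(f = numeric(17), m = numeric(13))
  out <- survive_and_age(st, zero, p0)$state
  expect_lte(sum(out$females) + sum(out$males),
             sum(st$females) + sum(st$males))
  expect_equal(out$females[1], 0)  # calf class filled by reproduction
  expect_equal(out$females[2], 10 * p0$herd$s_base_f[1])
})

test_that("slaughter conserves animals and supports both policy forms", {
  st <- herd_state(rep(10, 17), rep(5, 13))
  dec <- herd_decision(rep(0.3, 17), rep(0.5, 13), params = p0)
  out <- apply_slaughter(st, dec, p0)
  expect_equal_vec(out$slaughtered$f + out$state$females, st$females)
  expect_equal_vec(out$slaughtered$m + out$state$males, st$males)
  # zero fractions leave the state unchanged; ones empty the herd
  z <- apply_slaughter(st, herd_decision(rep(0, 17), rep(0, 13), params = p0), p0)
  expect_equal_vec(z$state$females, st$females)
  expect_equal(z$meat_kg, 0)
  all1 <- apply_slaughter(st, herd_decision(rep(1, 17), rep(1, 13),
                                            params = p0), p0)
  expect_equal(sum(all1$state$females) + sum(all1$state$males), 0)
  # escapement: everything above the per-class target is slaughtered
  esc <- herd_decision(rep(4, 17), rep(2, 13), params = p0,
                       type = "escapement")
  oe <- apply_slaughter(st, esc, p0)
  expect_equal(oe$state$females, rep(4, 17), tolerance = 0.1)
  expect_equal_vec(oe$slaughtered$f + oe$state$females, st$females)
  expect_error(herd_decision(rep(1.2, 17), rep(0, 13), params = p0),
               "\\[0, 1\\]")
})

test_that("calf percentage is calves per 100 adult females", {
  st <- herd_state(c(30, 20, 40), c(28, 0, 0))
  expect_equal(calf_percentage(st), 100 * (30 + 28) / 60)
  no_calves <- herd_state(c(0, 50), c(0, 5))
  expect_equal(calf_percentage(no_calves), 0)
  no_females <- herd_state(c(10, 0), c(10, 5))
  expect_error(calf_percentage(no_females), "undefined")
})

test_that("calf percentage declines as winters harden at fixed biomass", {
  v <- sapply(c("easy", "normal", "difficult"), function(lab)
    simulate_calf_percentage(500, lab, p0))
  expect_true(all(diff(v) < 0))
  # abundant lichen: the upper-limit cap binds, easy ~ normal
  v2 <- sapply(c("easy", "normal"), function(lab)
    simulate_calf_percentage(2000, lab, p0))
  expect_equal(v2[["easy"]], v2[["normal"]], tolerance = 0.01)
})
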