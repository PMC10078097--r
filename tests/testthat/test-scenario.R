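test_that("winter probabilities are validated", {
  p <- winter_probs()
  expect_equal(p$p_easy, 0.10)
  expect_equal(p$p_normal, 0.80)
  expect_equal(p$p_difficult, 0.10)
  expect_error(winter_probs(0.2, 0.2, 0.2), "sum to 1")
  expect_error(winter_probs(-0.1, 1.0, 0.1), "\\[0, 1\\]")
  expect_error(winter_probs(0.5, 0.6, -0.1), "\\[0, 1\\]")
})

test_that("degenerate distribution yields all-normal sequences", {
  s <- generate_winter_sequence(winter_probs(0, 1, 0), horizon = 50, seed = 7)
  expect_length(s$labels, 50)
  expect_true(all(s$labels == "normal"))
})

test_that("winter draws are reproducible and leave the caller's RNG alone", {
  set.seed(123)
  before <- runif(1)
  set.seed(123); runif(1)
  s1 <- generate_winter_sequence(winter_probs(), 200, seed = 42)
  after <- runif(1)
  s2 <- generate_winter_sequence(winter_probs(), 200, seed = 42)
  expect_identical(s1$labels, s2$labels)
  # caller RNG stream unaffected by the scenario generator
  set.seed(123); runif(1)
  expect_identical(after, runif(1))
  # different seeds give different sequences
  s3 <- generate_winter_sequence(winter_probs(), 200, seed = 43)
  expect_false(identical(s1$labels, s3$labels))
})

test_that("empirical class frequencies converge to the probabilities", {
  s <- generate_winter_sequence(winter_probs(0.1, 0.8, 0.1), 1e5, seed = 1)
  freq <- table(factor(s$labels, c("easy", "normal", "difficult"))) / 1e5
  expect_true(all(abs(freq - c(0.1, 0.8, 0.1)) < 0.005))
})

test_that("expected winter is normal for symmetric distributions", {
  expect_identical(expected_winter(winter_probs(0.1, 0.8, 0.1)), "normal")
  expect_identical(expected_winter(winter_probs(0, 1, 0)), "normal")
  expect_identical(expected_winter(winter_probs(0.4, 0.2, 0.4)), "normal")
  expect_identical(expected_winter(winter_probs(0.2, 0.6, 0.2)), "normal")
})

test_that("report frequencies reproduce direct ratios", {
  tbl <- data.frame(district = "D01", year = 1981:2010,
                    difficult_any = c(rep(1, 3), rep(0, 27)))
  out <- tabulate_report_frequencies(tbl)
  expect_equal(out$mean_pct, 10)
  expect_equal(out$mean_count, 3)
  expect_equal(out$min_pct, out$max_pct)
  # all years flagged in all districts -> 100 everywhere
  tbl2 <- expand.grid(year = 1981:2010, district = c("A", "B"))
  tbl2$flag <- 1
  out2 <- tabulate_report_frequencies(tbl2[, c("district", "year", "flag")])
  expect_equal(out2$mean_pct, 100)
  expect_equal(out2$min_pct, 100)
  expect_equal(out2$max_pct, 100)
})

test_that("simulated coded reports round-trip the target frequencies", {
  tbl <- simulate_coded_reports(seed = 11)
  out <- tabulate_report_frequencies(tbl)
  row <- out[out$flag == "difficult_any", ]
  # fixture constructed from target counts (min 3, max 15, mean ~10 of 30)
  expect_equal(row$min_pct, 10)       # 3/30
  expect_equal(row$max_pct, 50)       # 15/30
  expect_true(abs(row$mean_pct - 33.5) < 2)
  expect_equal(row$min_count, 3)
  expect_equal(row$max_count, 15)
  # row order invariance
  perm <- tbl[sample(nrow(tbl)), ]
  expect_equal(tabulate_report_frequencies(perm), out)
})

test_that("winter sequences serialize to CSV and JSON and back", {
  s <- generate_winter_sequence(winter_probs(), 30, seed = 5)
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_winter_sequence(s, fc)
  write_winter_sequence(s, fj)
  expect_identical(read_winter_sequence(fc)$labels, s$labels)
  rj <- read_winter_sequence(fj)
  expect_identical(rj$labels, s$labels)
  expect_equal(rj$probs$p_easy, 0.1)
  expect_equal(rj$seed, 5L)
  unlink(c(fc, fj))
})
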