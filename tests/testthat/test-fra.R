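rect_fra <- function(cf = 10, half_width = 1, max_rate = 100, spont = 5) {
  freqs <- seq(6, 14, by = 0.5)
  levels <- seq(0, 60, by = 10)
  rate <- matrix(spont, length(levels), length(freqs))
  rate[, abs(freqs - cf) <= half_width] <- max_rate
  rate[1, ] <- spont  # lowest row sub-threshold
  new_fra(rate * 0.05, freqs, levels, reps = 1, window_s = 0.05)
}

test_that("significance mask isolates driven bins", {
  flat <- new_fra(matrix(5 * 0.05, 5, 7), seq(4, 16, by = 2),
                  seq(0, 40, by = 10))
  expect_false(any(fra_significant_mask(flat)))
  one <- flat
  one$counts[3, 4] <- 50 * 0.05
  m <- fra_significant_mask(one)
  expect_equal(sum(m), 1)
  expect_true(m[3, 4])
})

test_that("CF and threshold come from the lowest significant level", {
  fra <- rect_fra()
  mask <- fra_significant_mask(fra)
  ct <- fra_cf_threshold(mask, fra)
  expect_equal(ct$threshold_db, 10)
  expect_equal(ct$cf_khz, 9)  # tie among equal responses -> lower frequency
  expect_error(fra_cf_threshold(matrix(FALSE, 2, 2), fra), "no significant")
})

test_that("ties at threshold break by larger response first", {
  fra <- rect_fra()
  fra$counts[2, ] <- 5 * 0.05
  fra$counts[2, fra$freqs_khz == 10] <- 80 * 0.05
  fra$counts[2, fra$freqs_khz == 11] <- 100 * 0.05
  mask <- fra_significant_mask(fra)
  ct <- fra_cf_threshold(mask, fra)
  expect_equal(ct$cf_khz, 11)
})

test_that("a rectangular response region gives constant Q = CF/width", {
  fra <- rect_fra(cf = 10, half_width = 1)
  mask <- fra_significant_mask(fra)
  ct <- fra_cf_threshold(mask, fra)
  q <- fra_q_factors(mask, fra, 10, ct$threshold_db)
  expect_equal(q$bw_khz, rep(2, 3))
  expect_equal(q$q, rep(5, 3))
})

test_that("noiseless synthetic FRAs are recovered exactly at grid resolution", {
  for (seed in 1:6) {
    sim <- simulate_fra(fra_preset("wt"), seed, noise = FALSE)
    m <- fra_metrics(sim$fra)
    expect_equal(m$cf_khz, sim$truth$cf_khz)
    expect_equal(m$threshold_db, sim$truth$threshold_db)
    expect_equal(m$bw10_khz, sim$truth$bw10_khz, tolerance = 1e-9)
    expect_equal(m$q10, sim$truth$q10, tolerance = 1e-9)
    expect_equal(m$q30, sim$truth$q30, tolerance = 1e-9)
    # single-lobed V: sharpness decreases with level
    expect_gte(m$q10, m$q20)
    expect_gte(m$q20, m$q30)
  }
})

test_that("a target Q10 is recovered on a fine grid", {
  p <- fra_preset("wt", q_jitter_sdlog = 0, threshold_db = 4.99,
                  freqs_khz = list(from = 4, to = 48, per_octave = 96),
                  q10 = 6.4)
  sim <- simulate_fra(p, seed = 1, cf_khz = 24, noise = FALSE)
  m <- fra_metrics(sim$fra)
  expect_equal(m$cf_khz, 24, tolerance = 0.01)
  expect_equal(m$q10, 6.4, tolerance = 0.05)
})

test_that("tuning metrics are invariant to count rescaling", {
  sim <- simulate_fra(fra_preset("wt"), seed = 3)
  m1 <- suppressWarnings(fra_metrics(sim$fra, c_sd = 4))
  scaled <- sim$fra
  scaled$counts <- scaled$counts * 7
  m2 <- suppressWarnings(fra_metrics(scaled, c_sd = 4))
  expect_equal(m2$cf_khz, m1$cf_khz)
  expect_equal(m2$threshold_db, m1$threshold_db)
  expect_equal(m2$q10, m1$q10)
  expect_equal(m2$max_rate_hz, 7 * m1$max_rate_hz)
})

test_that("rate-level at CF is returned by ascending level", {
  sim <- simulate_fra(fra_preset("wt"), seed = 2, noise = FALSE)
  rl <- fra_rate_level(sim$fra, sim$truth$cf_khz)
  expect_equal(rl$rate_level$level_db, sort(rl$rate_level$level_db))
  expect_true(all(diff(rl$rate_level$rate_hz) >= -1e-9))  # monotone drive
  expect_equal(rl$max_rate_hz, max(fra_rates(sim$fra)))
})

test_that("a flat FRA has undefined ground-truth CF", {
  sim <- simulate_fra(fra_preset("wt", max_rate_hz = 5, spont_rate_hz = 5),
                      seed = 1, noise = FALSE)
  expect_true(is.na(sim$truth$cf_khz))
})

test_that("FRA matrices round-trip through CSV", {
  sim <- simulate_fra(fra_preset("wt"), seed = 8)
  path <- tempfile(fileext = ".csv")
  write_fra_csv(sim$fra, path)
  back <- read_fra_csv(path, reps = sim$fra$reps, window_s = sim$fra$window_s)
  expect_equal(back$counts, unname(sim$fra$counts), ignore_attr = TRUE)
  expect_equal(back$freqs_khz, sim$fra$freqs_khz)
  expect_equal(back$levels_db, sim$fra$levels_db)
})
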