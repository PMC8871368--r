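test_that("trains too short for the minimum run yield no bursts", {
  # k >= 10 needs 11 spikes
  short <- cumsum(stats::rexp(10, 50))
  b <- detect_bursts(short, duration = 10)
  expect_equal(nrow(b$bursts), 0)
  expect_equal(b$units$n_bursts, 0L)
})

test_that("a dense run in a sparse background is found exactly once", {
  times <- make_embedded_burst_train()
  b <- detect_bursts(times, duration = 100)
  expect_equal(nrow(b$bursts), 1)
  # the detected burst covers the dense run; expected indices frozen from the
  # naive oracle re-evaluation of the p-sequence
  lam <- length(times) / 100
  oracle <- oracle_bursts(times, lam)
  expect_equal(b$bursts$start_index, oracle$start)
  expect_equal(b$bursts$end_index, oracle$end)
  dense_start <- which(diff(times) < 0.001)[1]
  expect_equal(b$bursts$start_index, dense_start)
  expect_gte(b$bursts$n_spikes, 51)
})

test_that("detector agrees exactly with the naive oracle on random trains", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(20:200, 1)
    kind <- rep %% 4
    times <- if (kind == 0) {
      sort(stats::runif(n, 0, 50))                 # uniform clutter
    } else if (kind == 1) {
      cumsum(stats::rexp(n, 5))                    # homogeneous Poisson
    } else if (kind == 2) {                        # bursty: dense patches
      sort(c(cumsum(stats::rexp(n %/% 2, 2)),
             10 + cumsum(stats::rexp(n - n %/% 2, 200))))
    } else {                                       # near-degenerate dense
      cumsum(stats::rexp(n, 100))
    }
    times <- times + seq_along(times) * 1e-9       # guard against ties
    dur <- max(times) + 0.1
    lam <- length(times) / dur
    got <- detect_bursts(times, dur)$bursts
    want <- oracle_bursts(times, lam)
    expect_equal(got$start_index, want$start)
    expect_equal(got$end_index, want$end)
  }
})

test_that("bursts are disjoint, ordered, and satisfy their invariants", {
  co <- simulate_spike_trains(spike_preset("wt"), 5, seed = 11)
  b <- detect_bursts(co$spikes, co$duration)
  for (uid in unique(b$bursts$unit_id)) {
    bu <- b$bursts[b$bursts$unit_id == uid, ]
    expect_true(all(diff(bu$start_index) > 0))
    expect_true(all(bu$start_index[-1] > bu$end_index[-nrow(bu)]))
  }
  expect_true(all(b$bursts$k >= 10))
  expect_equal(b$bursts$n_spikes, b$bursts$k + 1L)
  expect_equal(b$bursts$duration_s, b$bursts$end_s - b$bursts$start_s)
  expect_equal(b$bursts$rate_hz, b$bursts$n_spikes / b$bursts$duration_s)
})

test_that("an edge-truncated run still counts when long enough", {
  # dense run right at the end of the recording
  times <- c(seq(1, 90, by = 1), 99 + cumsum(c(0, 0.0008, rep(0.02, 19))))
  b <- detect_bursts(times, duration = 100)
  expect_equal(nrow(b$bursts), 1)
  expect_equal(b$bursts$end_index, length(times))
})

test_that("burst metrics report the per-unit quantities", {
  co <- simulate_spike_trains(spike_preset("wt"), 3, seed = 5)
  b <- detect_bursts(co$spikes, co$duration)
  m <- burst_metrics(b)
  expect_equal(nrow(m), 3)
  expect_equal(m$bursts_per_100s, m$n_bursts)  # 100 s recordings
  one <- b$bursts[b$bursts$unit_id == m$unit_id[1], ]
  expect_equal(m$median_spikes_per_burst[1], stats::median(one$n_spikes))
  # arithmetic on the canonical example: 45 spikes in 1.6 s
  expect_equal(45 / 1.6, 28.125)
})

test_that("tidy and glance expose the burst tables", {
  co <- simulate_spike_trains(spike_preset("wt"), 3, seed = 5)
  b <- detect_bursts(co$spikes, co$duration)
  expect_identical(tidy(b), b$bursts)
  g <- glance(b)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_units, 3L)
})
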