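make_const_stack <- function(value = 100, dims = c(10, 10), n = 12, px = 1) {
  new_stack(array(value, c(dims, n)), px, 1, "dic")
}

test_that("ratio stack divides channels and masks zero denominators", {
  a <- make_const_stack(200)
  b <- make_const_stack(100)
  r <- compute_ratio(a, b)
  expect_true(all(r$frames == 2))
  same <- compute_ratio(a, a)
  expect_true(all(same$frames == 1))
  z <- make_const_stack(0)
  masked <- compute_ratio(a, z)
  expect_true(all(is.na(masked$frames)))
  small <- make_const_stack(100, dims = c(5, 5))
  expect_error(compute_ratio(a, small), "identical dimensions")
})

test_that("moving-average subtraction follows the window arithmetic", {
  s <- make_const_stack(50)
  d <- subtract_moving_average(s, 5)
  expect_true(all(is.na(d$frames[, , 1:5])))
  expect_true(all(d$frames[, , 6:12] == 0))

  # step of +s at frame m: delta jumps to +s, decays, and vanishes after the
  # step has filled the whole window
  step <- make_const_stack(100, n = 20)
  step$frames[, , 10:20] <- 107
  ds <- subtract_moving_average(step, 5)
  expect_equal(ds$frames[1, 1, 10], 7)
  expect_equal(ds$frames[1, 1, 11], 7 - 7 / 5)
  expect_true(all(abs(ds$frames[, , 15:20]) < 1e-12))

  # single-frame impulse: +s at the impulse, -s/window just after
  imp <- make_const_stack(100, n = 20)
  imp$frames[, , 10] <- 105
  di <- subtract_moving_average(imp, 5)
  expect_equal(di$frames[1, 1, 10], 5)
  expect_equal(di$frames[1, 1, 11], -1)
  expect_equal(di$frames[1, 1, 16], 0)

  expect_error(subtract_moving_average(make_const_stack(1, n = 6), 6),
               "more frames")
})

test_that("subtraction is linear and offsets cancel", {
  set.seed(1)
  s <- make_const_stack(0, n = 15)
  s$frames[] <- stats::rnorm(length(s$frames))
  scaled <- s
  scaled$frames <- 3 * s$frames + 17
  d1 <- subtract_moving_average(s, 5)$frames
  d2 <- subtract_moving_average(scaled, 5)$frames
  expect_equal(d2[, , 6:15], 3 * d1[, , 6:15], tolerance = 1e-10)
})

test_that("baseline is the spatio-temporal mean of the quiet region", {
  s <- make_const_stack(100)
  expect_equal(measure_baseline(s, roi_rect(c(1, 5), c(1, 5))), 100)
  set.seed(2)
  noisy <- make_const_stack(0, dims = c(30, 30), n = 50)
  noisy$frames[] <- 50 + stats::rnorm(length(noisy$frames), 0, 5)
  expect_equal(measure_baseline(noisy, roi_rect(c(1, 30), c(1, 30))), 50,
               tolerance = 0.1)
  expect_error(measure_baseline(s, roi_rect(c(1, 50), c(1, 5))), "outside")
  expect_error(roi_rect(c(5, 1), c(1, 5)), "ROI")
})

test_that("an injected blob is detected with its area", {
  inj <- make_injected_stack(area_um2 = 200, amplitude = 0.3, noise_sd = 3)
  res <- analyze_stack(inj$stack,
                       detection_config(min_area_um2 = 50,
                                        analysis_roi_um2 = 3000))
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$area_um2, inj$area_um2, tolerance = 0.15)
  expect_equal(res$events$onset_frame, inj$onset)
  expect_true(res$events$in_roi)
})

test_that("blobs below the minimum area are rejected", {
  small <- make_injected_stack(area_um2 = 30, amplitude = 0.5)
  res <- analyze_stack(small$stack, detection_config(min_area_um2 = 50))
  expect_equal(nrow(res$events), 0)
  s <- summarize_events(res$events, 30)
  expect_equal(s$n_events, 0)
  expect_equal(s$event_frequency_hz, 0)
  expect_equal(s$mean_event_area_um2, 0)
})

test_that("pure noise below threshold produces no events", {
  set.seed(12)
  noise <- make_injected_stack(area_um2 = 0, amplitude = 0, noise_sd = 10,
                               n_frames = 60)
  res <- analyze_stack(noise$stack, detection_config(min_area_um2 = 50))
  expect_equal(nrow(res$events), 0)
})

test_that("detection is monotone in amplitude", {
  base <- make_injected_stack(area_um2 = 200, amplitude = 0.15, noise_sd = 2)
  n_low <- nrow(analyze_stack(base$stack)$events)
  boosted <- make_injected_stack(area_um2 = 200, amplitude = 0.6, noise_sd = 2)
  n_high <- nrow(analyze_stack(boosted$stack)$events)
  expect_gte(n_high, n_low)
  expect_equal(n_high, 1)
})

test_that("components are linked across frames and one-frame gaps", {
  s <- make_const_stack(100, dims = c(20, 20), n = 25, px = 1)
  blob <- function(f) s$frames[8:13, 8:13, f] <<- 130
  # active at 10, 11, missing at 12 (flicker), back at 13
  blob(10); blob(11); blob(13)
  res <- detect_events(subtract_moving_average(s, 5), 100,
                       detection_config(min_area_um2 = 10))
  expect_equal(nrow(res), 1)
  expect_equal(res$onset_frame, 10)
  expect_gte(res$offset_frame, 13)
})

test_that("8-connected labelling joins diagonals", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- m[2, 2] <- m[3, 3] <- TRUE
  m[5, 5] <- TRUE
  lab <- prehear:::label_components8(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[3, 3])
  expect_false(lab[5, 5] == lab[1, 1])
})

test_that("event frequency is events per second", {
  ev <- tibble::tibble(event_id = 1:4, onset_frame = 1:4, offset_frame = 2:5,
                       area_um2 = c(100, 200, 300, 400),
                       centroid_x_um = 0, centroid_y_um = 0,
                       peak_rel_amplitude = 0.3, in_roi = TRUE)
  s <- summarize_events(ev, 400)
  expect_equal(s$event_frequency_hz, 0.01)
  expect_equal(s$mean_event_area_um2, 250)
})
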