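small_ca_preset <- function(...) {
  imaging_preset("wt_ca", n_frames = 60, ...)
}

test_that("imaging generation is deterministic per preset and seed", {
  a <- simulate_imaging_stack(small_ca_preset(), seed = 4)
  b <- simulate_imaging_stack(small_ca_preset(), seed = 4)
  expect_identical(a$ch340$frames, b$ch340$frames)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_imaging_stack(small_ca_preset(), seed = 5)
  expect_false(identical(a$ch340$frames, c2$ch340$frames))
})

test_that("zero event rate yields a noise-only stack with empty truth", {
  sim <- simulate_imaging_stack(small_ca_preset(event_rate_hz = 0), seed = 1)
  expect_equal(nrow(sim$truth), 0)
  r <- compute_ratio(sim$ch340, sim$ch380)
  expect_equal(mean(r$frames), 1, tolerance = 0.01)
})

test_that("an explicitly injected event appears in the truth at its size", {
  ev <- tibble::tibble(onset_frame = 20, x_um = 112, y_um = 72,
                       area_um2 = 200, amplitude = 0.3)
  sim <- simulate_imaging_stack(imaging_preset("wt_dic", n_frames = 60,
                                               noise_sd = 0),
                                seed = 1, events = ev)
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$area_um2, 200, tolerance = 0.15)
  # brute-force pixel scan: every above-baseline pixel belongs to the event
  peak <- sim$stack$frames[, , 22]
  hot <- which(peak > 1000 * 1.1, arr.ind = TRUE)
  expect_equal(nrow(hot) * 4, sim$truth$area_um2, tolerance = 1e-9)
  d <- sqrt(((hot[, 2] - 0.5) * 2 - 112)^2 + ((hot[, 1] - 0.5) * 2 - 72)^2)
  expect_lt(max(d), 25)
})

test_that("the fura event signal travels on the 340 channel only", {
  ev <- tibble::tibble(onset_frame = 20, x_um = 112, y_um = 72,
                       area_um2 = 400, amplitude = 0.4)
  sim <- simulate_imaging_stack(small_ca_preset(noise_sd = 0), seed = 1,
                                events = ev)
  expect_gt(max(sim$ch340$frames[, , 22]), 2000 * 1.3)
  expect_equal(max(sim$ch380$frames[, , 22]), 2000)
})

test_that("a field too small for the band is rejected", {
  expect_error(imaging_preset("wt_ca", field_px = list(8, 20)),
               "band geometry")
})

test_that("wildtype stacks dominate knockout stacks for matched seeds", {
  for (seed in 1:3) {
    wt <- simulate_imaging_stack(imaging_preset("wt_ca", n_frames = 120), seed)
    ck <- simulate_imaging_stack(imaging_preset("cko_ca", n_frames = 120), seed)
    expect_gte(sum(wt$truth$area_um2), sum(ck$truth$area_um2))
  }
})

test_that("stacks round-trip through TIFF with their metadata", {
  sim <- simulate_imaging_stack(imaging_preset("wt_dic", n_frames = 25,
                                               field_px = list(24, 30),
                                               band_rows_um = list(10, 40)),
                                seed = 2)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(sim$stack, path)
  back <- read_stack_tiff(path)
  expect_equal(back$frames, sim$stack$frames)
  expect_equal(back$pixel_size_um, 2)
  expect_equal(back$modality, "dic")
})
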