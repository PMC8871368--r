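test_that("PSP extraction measures peak depolarization from baseline", {
  t <- seq(0, 0.2, by = 0.001)
  flat <- rep(-70, length(t))
  r0 <- extract_psp(flat, t, onset_s = 0.1)
  expect_equal(r0$amplitude_mv, 0)
  expect_false(r0$ap_flag)

  epsp <- flat + 8 * exp(-((t - 0.105) / 0.004)^2) * (t >= 0.1)
  r8 <- extract_psp(epsp, t, onset_s = 0.1)
  expect_equal(r8$amplitude_mv, 8, tolerance = 0.01)
  expect_false(r8$ap_flag)

  spike <- flat + 90 * exp(-((t - 0.104) / 0.0015)^2) * (t >= 0.1)
  rs <- extract_psp(spike, t, onset_s = 0.1)
  expect_true(rs$ap_flag)
  expect_error(extract_psp(flat, t, onset_s = 0.19, window_s = 0.02),
               "outside")
})

test_that("site classes follow the strict colour-code thresholds", {
  expect_equal(as.character(classify_site(2.0)), "unresponsive")
  expect_equal(as.character(classify_site(2.01)), "responsive_2mV")
  expect_equal(as.character(classify_site(10)), "responsive_2mV")
  expect_equal(as.character(classify_site(11)), "responsive_10mV")
  expect_equal(as.character(classify_site(5, ap_flag = TRUE)),
               "action_potential")
  expect_equal(as.character(classify_site(-3)), "unresponsive")
  cls <- classify_site(c(1, 5, 15), c(FALSE, FALSE, FALSE))
  expect_true(cls[1] < cls[2] & cls[2] < cls[3])
})

square_polygon <- function(w, h) {
  tibble::tibble(x_um = c(0, w, w, 0), y_um = c(0, 0, h, h))
}

test_that("input area is responsive sites times site area over outline area", {
  poly <- square_polygon(300, 210)  # 63,000 um2
  sites <- tibble::tibble(
    x_um = rep(seq(20, 320, by = 20), 2)[1:40],
    y_um = rep(c(50, 70), each = 20),
    amplitude_mv = c(rep(5, 16), rep(0, 24)),
    ap_flag = FALSE)
  sites <- classify_sites(sites)
  expect_equal(input_area(sites, poly), 16 * 400 / 63000 * 100,
               tolerance = 1e-12)
  expect_equal(input_area(sites, poly), 10.16, tolerance = 0.01)
  none <- dplyr::mutate(sites, amplitude_mv = 0,
                        class = classify_site(0, FALSE))
  expect_equal(input_area(none, poly), 0)
  expect_error(input_area(sites, square_polygon(0, 0)), "degenerate")
})

test_that("input width is the mediolateral span of strong sites", {
  poly <- square_polygon(250, 100)
  sites <- classify_sites(tibble::tibble(
    x_um = c(100, 190, 150, 40), y_um = 50,
    amplitude_mv = c(12, 15, 5, 1), ap_flag = FALSE))
  expect_equal(input_width(sites, poly), 100 * 90 / 250)
  one <- classify_sites(tibble::tibble(x_um = 100, y_um = 50,
                                       amplitude_mv = 20, ap_flag = FALSE))
  expect_equal(input_width(one, poly), 0)
  # AP sites qualify even with modest amplitude
  ap <- classify_sites(tibble::tibble(x_um = c(0, 250), y_um = 50,
                                      amplitude_mv = 5,
                                      ap_flag = c(TRUE, TRUE)))
  expect_equal(input_width(ap, poly), 100)
})

test_that("adding responsive sites never shrinks the metrics", {
  poly <- square_polygon(300, 210)
  base <- classify_sites(tibble::tibble(
    x_um = c(100, 140), y_um = 100, amplitude_mv = c(12, 12),
    ap_flag = FALSE))
  m0 <- input_map_metrics(base, poly)
  more <- classify_sites(dplyr::bind_rows(
    base[, c("x_um", "y_um", "amplitude_mv", "ap_flag")],
    tibble::tibble(x_um = 260, y_um = 100, amplitude_mv = 12,
                   ap_flag = FALSE)))
  m1 <- input_map_metrics(more, poly)
  expect_gte(m1$input_area_pct, m0$input_area_pct)
  expect_gte(m1$input_width_pct, m0$input_width_pct)
  expect_lte(m1$n_strong, m1$n_responsive)
})

test_that("a zero amplitude profile leaves every site unresponsive", {
  sim <- simulate_input_map(map_preset("wt", amp_max_mv = 0,
                                       noise_sd_mv = 0), seed = 1)
  cls <- classify_sites(sim$sites)
  expect_true(all(cls$class == "unresponsive"))
  expect_equal(length(sim$truth$responsive_ids), 0)
})

test_that("noiseless maps recover the preset geometry within one grid cell", {
  for (seed in 1:5) {
    sim <- simulate_input_map(map_preset("wt", noise_sd_mv = 0,
                                         polygon_scale_jitter_sd = 0),
                              seed = seed)
    cls <- classify_sites(sim$sites)
    m <- input_map_metrics(cls, sim$polygon,
                           sim$preset$grid_spacing_um^2)
    # noiseless classification agrees with the generator's intended sets
    expect_setequal(cls$site_id[cls$class >= "responsive_2mV"],
                    sim$truth$responsive_ids)
    # fractional area within the grid-discretization margin (3 sites)
    expect_lte(abs(m$n_responsive * 400 / sim$truth$polygon_area_um2 -
                     sim$truth$area_frac_target),
               3 * 400 / sim$truth$polygon_area_um2)
  }
})

test_that("maps are deterministic and round-trip through CSV", {
  a <- simulate_input_map(map_preset("cko"), seed = 6)
  b <- simulate_input_map(map_preset("cko"), seed = 6)
  expect_identical(a$sites, b$sites)
  sp <- tempfile(fileext = ".csv"); pp <- tempfile(fileext = ".csv")
  write_map_csv(a$sites, a$polygon, sp, pp)
  back <- read_map_csv(sp, pp)
  expect_equal(back$sites$amplitude_mv, a$sites$amplitude_mv)
  expect_equal(back$polygon$x_um, a$polygon$x_um)
})
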