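#' Simulate a V-shaped frequency response area
#'
#' The noiseless response surface is a classic V: the unit responds wherever
#' the stimulus level exceeds a threshold curve that rises linearly (in dB
#' per octave) away from the characteristic frequency, with a shallower slope
#' on the low-frequency side. Above threshold the rate saturates linearly
#' toward `max_rate_hz` over `sat_range_db`. Spike counts are Poisson per
#' frequency/level bin (`noise = TRUE`) or the exact expected counts
#' (`noise = FALSE`). The per-unit sharpness (Q10) is the preset target with
#' lognormal jitter; the threshold slopes are solved from it.
#'
#' @param preset An FRA preset from [fra_preset()].
#' @param seed Integer seed.
#' @param cf_khz Optional CF; by default drawn log-uniformly from the
#'   preset's range and snapped to the frequency grid.
#' @param noise Draw Poisson counts (default) or emit the noiseless surface.
#' @return A list of class `fra_sim` with `fra` (a `prehear_fra`) and `truth`
#'   (one-row tibble: analytic and grid-snapped CF, threshold, BW_n, Q_n).
#' @export
simulate_fra <- function(preset, seed, cf_khz = NULL, noise = TRUE) {
  with_seed(seed, {
    freqs <- fra_freq_grid(preset)
    levels <- seq(preset$levels_db$from, preset$levels_db$to,
                  by = preset$levels_db$by)
    if (is.null(cf_khz)) {
      cf_khz <- exp(stats::runif(1, log(preset$cf_range_khz[1]),
                                 log(preset$cf_range_khz[2])))
    }
    cf_khz <- freqs[which.min(abs(log(freqs) - log(cf_khz)))]
    q10 <- preset$q10 * stats::rlnorm(1, 0, preset$q_jitter_sdlog)
    s_high <- solve_slope(q10, preset$slope_asymmetry)
    s_low <- s_high / preset$slope_asymmetry
    thr_cf <- preset$threshold_db

    max_rate <- preset$max_rate_hz
    spont <- preset$spont_rate_hz
    thr_f <- ifelse(freqs < cf_khz,
                    thr_cf + s_low * log2(cf_khz / freqs),
                    thr_cf + s_high * log2(freqs / cf_khz))
    excess <- outer(levels, thr_f, `-`)
    drive <- pmin(pmax(excess / preset$sat_range_db, 0), 1)
    rate <- spont + (max_rate - spont) * drive
    lam <- rate * preset$reps * preset$window_s
    counts <- if (noise) {
      matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    } else {
      lam
    }
    fra <- new_fra(counts, freqs, levels, preset$reps, preset$window_s)
    truth <- fra_truth(cf_khz, thr_cf, s_low, s_high, freqs, levels,
                       no_response = max_rate <= spont)
    structure(list(fra = fra, truth = truth, preset = preset,
                   slopes = c(low = s_low, high = s_high)),
              class = "fra_sim")
  })
}

fra_freq_grid <- function(preset) {
  f <- preset$freqs_khz
  n_oct <- log2(f$to / f$from)
  f$from * 2^seq(0, n_oct, by = 1 / f$per_octave)
}

# solve the high-side slope (dB/octave) giving the requested Q10 when the
# low side is `asym` times shallower: 1/q10 = 2^(10/s) - 2^(-10*asym/s)
solve_slope <- function(q10, asym) {
  stats::uniroot(function(s) 2^(10 / s) - 2^(-10 * asym / s) - 1 / q10,
                 interval = c(1, 5000))$root
}

fra_truth <- function(cf, thr_cf, s_low, s_high, freqs, levels, no_response) {
  if (no_response) {
    return(tibble::tibble(cf_khz = NA_real_, threshold_db = NA_real_,
                          q10 = NA_real_, q20 = NA_real_, q30 = NA_real_,
                          bw10_khz = NA_real_, bw20_khz = NA_real_,
                          bw30_khz = NA_real_))
  }
  # the response is strictly above the threshold curve, so the detected
  # threshold is the first grid level strictly above thr_cf, and a grid
  # frequency is inside the span only when its threshold lies strictly below
  # the row level
  thr_grid <- levels[which(levels > thr_cf + 1e-9)[1]]
  thr_f <- ifelse(freqs < cf, thr_cf + s_low * log2(cf / freqs),
                  thr_cf + s_high * log2(freqs / cf))
  bw_grid <- function(n) {
    row_level <- levels[which.min(abs(levels - (thr_grid + n)))]
    in_span <- freqs[thr_f < row_level - 1e-9]
    if (!length(in_span)) return(NA_real_)
    max(in_span) - min(in_span)
  }
  bw <- vapply(c(10, 20, 30), bw_grid, numeric(1))
  tibble::tibble(cf_khz = cf, threshold_db = thr_grid,
                 bw10_khz = bw[1], bw20_khz = bw[2], bw30_khz = bw[3],
                 q10 = ifelse(bw[1] > 0, cf / bw[1], NA_real_),
                 q20 = ifelse(bw[2] > 0, cf / bw[2], NA_real_),
                 q30 = ifelse(bw[3] > 0, cf / bw[3], NA_real_))
}
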