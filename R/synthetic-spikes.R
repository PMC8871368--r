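#' Simulate a cohort of spontaneously bursting spike trains
#'
#' Emulates the spontaneous discharge of developing auditory brainstem (MNTB)
#' neurons before hearing onset. Each train is the superposition of a
#' homogeneous Poisson background and burst epochs. A burst is a train of
#' mini-bursts (2-4 spikes each, a few ms apart inside a mini-burst) recurring
#' at roughly 100 ms intervals; every burst opens with a brief high-frequency
#' onset volley and is followed by a suppressed (adaptation) period whose
#' length scales with the size of the burst, as seen in burst-pause firing of
#' immature auditory neurons. The wildtype preset produces long bursts and
#' strongly patterned ISIs; the knockout preset produces rare, short bursts on
#' a more Poisson-like background.
#'
#' @param preset A spike preset from [spike_preset()].
#' @param n_units Number of units to simulate (>= 1).
#' @param seed Integer root seed; unit `i` uses the derived substream
#'   `substream_seed(seed, i)`, so identical `(preset, seed)` give identical
#'   output.
#' @return A list of class `spike_cohort` with `spikes` (tibble `unit_id`,
#'   `time_s`), `truth` (tibble `unit_id`, `burst_id`, `start_s`, `end_s`,
#'   `n_spikes`, one row per scheduled burst), `duration` and `preset`.
#' @export
simulate_spike_trains <- function(preset, n_units, seed) {
  abort_if(n_units < 1, "`n_units` must be >= 1")
  validate_spike_preset(preset)
  units <- purrr::map(seq_len(n_units), function(i) {
    with_seed(substream_seed(seed, i),
              simulate_one_train(preset, sprintf("u%02d", i)))
  })
  out <- list(
    spikes = dplyr::bind_rows(purrr::map(units, "spikes")),
    truth = dplyr::bind_rows(purrr::map(units, "truth")),
    duration = preset$duration_s,
    preset = preset)
  class(out) <- "spike_cohort"
  out
}

#' @export
print.spike_cohort <- function(x, ...) {
  cat(sprintf("<spike_cohort> %s: %d units, %d spikes, %d true bursts over %g s\n",
              x$preset$label, length(unique(x$spikes$unit_id)),
              nrow(x$spikes), nrow(x$truth), x$duration))
  invisible(x)
}

# Build one burst as spike times relative to its first spike.
build_burst <- function(p) {
  m <- round(stats::rlnorm(1, p$minibursts_meanlog, p$minibursts_sdlog))
  m <- min(max(m, p$minibursts_min), p$minibursts_max)
  mu <- stats::runif(1, p$spikes_per_miniburst_mean[1], p$spikes_per_miniburst_mean[2])
  interval <- stats::runif(1, p$miniburst_interval_s[1], p$miniburst_interval_s[2])
  gaps <- interval + stats::rnorm(m - 1, 0, p$miniburst_interval_jitter_s)
  gaps <- pmax(gaps, 0.05)
  onsets <- c(0, cumsum(gaps))

  intra_isi <- function(n) {
    pmin(pmax(stats::rexp(n, 1 / p$intra_isi_mean_s), p$intra_isi_range_s[1]),
         p$intra_isi_range_s[2])
  }
  # onset volley: fixed-size mini-burst opening with a sub-ms doublet
  first_isi <- stats::runif(1, p$onset_first_isi_s[1], p$onset_first_isi_s[2])
  volley <- c(0, cumsum(c(first_isi, intra_isi(p$onset_spikes - 2))))
  spikes <- onsets[1] + volley
  if (m > 1) {
    for (j in 2:m) {
      # the burst head stays dense (>= 3 spikes per mini-burst) so that the
      # elevated rate is unambiguous from the very first intervals on
      s_min <- if (j <= 3) 3 else 2
      s <- max(s_min, 2 + stats::rbinom(1, 2, (mu - 2) / 2))
      spikes <- c(spikes, onsets[j] + c(0, cumsum(intra_isi(s - 1))))
    }
  }
  sort(spikes)
}

simulate_one_train <- function(p, uid) {
  dur <- p$duration_s
  # per-unit multiplicative spread of the background excitability
  p$background_rate_hz <- p$background_rate_hz *
    stats::rlnorm(1, 0, p$unit_jitter_sdlog)
  # number of bursts drawn per 100 s, scaled to the requested duration
  vals <- unlist(p$bursts_per_100s_values)
  probs <- unlist(p$bursts_per_100s_probs)
  n_target <- round(sample(length(vals), 1, prob = probs) |>
                      (\(i) vals[i])() * dur / 100)
  bursts <- if (n_target > 0) replicate(n_target, build_burst(p),
                                        simplify = FALSE) else list()
  # post-burst suppressed (adaptation) period scales with burst size
  supp <- vapply(bursts, function(b) {
    max(p$suppression_min_s, p$suppression_per_spike_s * length(b))
  }, numeric(1))
  occupied <- vapply(bursts, max, numeric(1)) + supp
  while (length(bursts) && sum(occupied) > dur - 2 * (length(bursts) + 1)) {
    bursts <- bursts[-length(bursts)]
    occupied <- occupied[-length(occupied)]
    supp <- supp[-length(supp)]
  }
  n_b <- length(bursts)
  free <- dur - sum(occupied)
  w <- stats::rexp(n_b + 1)
  waits <- free * w / sum(w)

  spikes <- numeric(0)
  truth <- list()
  t <- 0
  bg_in <- function(from, to) {
    if (p$background_rate_hz <= 0 || to <= from) return(numeric(0))
    n_bg <- stats::rpois(1, p$background_rate_hz * (to - from))
    if (n_bg > 0) stats::runif(n_bg, from, to) else numeric(0)
  }
  for (i in seq_len(n_b)) {
    spikes <- c(spikes, bg_in(t, t + waits[i]))
    onset <- t + waits[i]
    b <- onset + bursts[[i]]
    spikes <- c(spikes, b)
    truth[[i]] <- tibble::tibble(
      unit_id = uid, burst_id = i,
      start_s = b[1], end_s = b[length(b)], n_spikes = length(b))
    t <- b[length(b)] + supp[i]
  }
  spikes <- c(spikes, bg_in(t, t + waits[n_b + 1]))
  spikes <- sort(spikes)
  # refractory clean-up: drop spikes closer than 0.25 ms to their predecessor
  if (length(spikes) > 1) {
    keep <- c(TRUE, diff(spikes) > 2.5e-4)
    spikes <- spikes[keep]
  }
  list(spikes = tibble::tibble(unit_id = uid, time_s = spikes),
       truth = if (length(truth)) dplyr::bind_rows(truth) else
         tibble::tibble(unit_id = character(), burst_id = integer(),
                        start_s = numeric(), end_s = numeric(),
                        n_spikes = integer()))
}

#' Overlap between detected bursts and ground-truth burst windows
#'
#' For each unit, spikes are labelled as burst spikes by the detector and by
#' the ground-truth windows; the Jaccard index of the two spike sets measures
#' how faithfully detection recovers the scheduled bursts.
#'
#' @param cohort A `spike_cohort` from [simulate_spike_trains()].
#' @param bursts A `prehear_bursts` object from [detect_bursts()] run on
#'   `cohort$spikes`.
#' @return Tibble `unit_id`, `jaccard`.
#' @export
burst_recovery <- function(cohort, bursts) {
  stopifnot(inherits(cohort, "spike_cohort"), inherits(bursts, "prehear_bursts"))
  per_unit <- split(cohort$spikes$time_s, cohort$spikes$unit_id)
  purrr::imap_dfr(per_unit, function(times, uid) {
    tw <- cohort$truth[cohort$truth$unit_id == uid, ]
    dw <- bursts$bursts[bursts$bursts$unit_id == uid, ]
    in_windows <- function(w) {
      if (!nrow(w)) return(rep(FALSE, length(times)))
      Reduce(`|`, purrr::map2(w$start_s, w$end_s,
                              function(s, e) times >= s - 1e-9 & times <= e + 1e-9))
    }
    a <- in_windows(tw); b <- in_windows(dw)
    u <- sum(a | b)
    tibble::tibble(unit_id = uid,
                   jaccard = if (u == 0) NA_real_ else sum(a & b) / u)
  })
}
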