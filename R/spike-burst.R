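#' Interspike intervals of one or more spike trains
#'
#' An interspike interval (ISI) is the time that passes between two successive
#' action potentials of one unit. Spike times must be strictly increasing
#' within each unit; ties or out-of-order times indicate a corrupt recording
#' and are rejected.
#'
#' @param spikes A data frame with columns `unit_id` and `time_s`, or a bare
#'   numeric vector of spike times for a single unit.
#' @return A tibble with columns `unit_id` and `isi_s`. Units with fewer than
#'   two spikes contribute no rows.
#' @export
#' @examples
#' compute_isis(c(0, 0.1, 0.3))
compute_isis <- function(spikes) {
  spikes <- as_spike_table(spikes)
  spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::reframe(isi_s = diff(.data$time_s))
}

as_spike_table <- function(spikes) {
  if (is.numeric(spikes)) {
    spikes <- tibble::tibble(unit_id = "u1", time_s = as.numeric(spikes))
  }
  abort_if(!is.data.frame(spikes) || !all(c("unit_id", "time_s") %in% names(spikes)),
           "`spikes` must have columns unit_id and time_s")
  bad <- spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(ok = all(diff(.data$time_s) > 0), .groups = "drop")
  abort_if(any(!bad$ok),
           "spike times must be strictly increasing within each unit (no duplicates)")
  abort_if(any(spikes$time_s < 0), "spike times must be non-negative")
  tibble::as_tibble(spikes[, c("unit_id", "time_s")])
}

#' Coefficient of variation of interspike intervals
#'
#' CV = sd(ISI)/mean(ISI) with the sample (n-1) standard deviation. A value
#' near 1 corresponds to Poisson-like random firing; values well above 1
#' indicate patterned, bursty discharge.
#'
#' @param isis A tibble from [compute_isis()], or a numeric vector of
#'   intervals in seconds.
#' @return A tibble with columns `unit_id`, `n_isi`, `cv` (or a single number
#'   for a numeric input).
#' @export
isi_cv <- function(isis) {
  if (is.numeric(isis)) {
    abort_if(length(isis) < 2, "CV requires at least 2 intervals")
    return(stats::sd(isis) / mean(isis))
  }
  abort_if(!all(c("unit_id", "isi_s") %in% names(isis)),
           "`isis` must have columns unit_id and isi_s")
  out <- isis |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(n_isi = dplyr::n(),
                     cv = stats::sd(.data$isi_s) / mean(.data$isi_s),
                     median_isi_s = stats::median(.data$isi_s),
                     .groups = "drop")
  abort_if(any(out$n_isi < 2), "CV requires at least 2 intervals per unit")
  out
}

#' Gamma waiting-time probability of an ISI run
#'
#' Under the null hypothesis that a unit fires as a homogeneous Poisson
#' process with rate `lambda`, the waiting time for `k` ISIs follows a gamma
#' distribution with shape `k` and rate `lambda`. The probability that `k`
#' ISIs fit into an observed span `tau` is the regularized lower incomplete
#' gamma function, identically the Poisson tail
#' \eqn{P(\mathrm{Pois}(\lambda\tau) \ge k)}. Small values flag spans that are
#' unexpectedly dense, i.e. candidate bursts.
#'
#' @param k Number of ISIs in the run (>= 1). Vectorised.
#' @param tau Span of the run in seconds (>= 0). Vectorised.
#' @param lambda Firing rate in Hz (> 0).
#' @return Probabilities in \[0, 1\].
#' @export
#' @examples
#' gamma_burst_prob(1, log(2), 1)   # 0.5
#' gamma_burst_prob(10, 10, 1)      # ~0.542
gamma_burst_prob <- function(k, tau, lambda) {
  abort_if(any(lambda <= 0), "`lambda` must be positive")
  abort_if(any(k < 1), "`k` must be >= 1")
  abort_if(any(tau < 0), "`tau` must be non-negative")
  stats::pgamma(tau, shape = k, rate = lambda)
}

#' Overall firing rate of spike trains
#'
#' The rate estimate used as the Poisson null rate of the burst test:
#' number of spikes divided by the recording duration.
#'
#' @param spikes Spike table (`unit_id`, `time_s`) or numeric vector.
#' @param duration Recording duration in seconds (scalar, applied to every
#'   unit).
#' @return Tibble with `unit_id`, `n_spikes`, `rate_hz`.
#' @export
estimate_rate <- function(spikes, duration) {
  abort_if(!is.numeric(duration) || duration <= 0, "`duration` must be > 0")
  spikes <- as_spike_table(spikes)
  out <- spikes |>
    dplyr::count(.data$unit_id, name = "n_spikes") |>
    dplyr::mutate(rate_hz = .data$n_spikes / duration)
  abort_if(any(out$n_spikes < 2), "rate estimation requires at least 2 spikes per unit")
  out
}

# Core left-to-right scan for a single train. Returns a data.frame of runs.
# Rule: a candidate run starting at spike i grows k = 1, 2, ... with
# tau = t[i+k] - t[i]; it survives while p(k, tau, lambda) < alpha at EVERY k;
# the first k with p >= alpha ends the run at the previous spike. Runs with
# k >= k_min become bursts and scanning resumes after their last spike.
scan_bursts_one <- function(times, lambda, alpha, k_min) {
  n <- length(times)
  out <- list()
  i <- 1L
  while (i <= n - 1L) {
    # cheap k = 1 gate: p = 1 - exp(-lambda * isi)
    if (stats::pgamma(times[i + 1L] - times[i], 1, rate = lambda) >= alpha) {
      i <- i + 1L
      next
    }
    kk <- seq_len(n - i)
    p <- stats::pgamma(times[i + kk] - times[i], shape = kk, rate = lambda)
    bad <- which(p >= alpha)
    k_run <- if (length(bad)) bad[1L] - 1L else n - i
    if (k_run >= k_min) {
      j <- i + k_run
      out[[length(out) + 1L]] <- data.frame(
        start_index = i, end_index = j,
        start_s = times[i], end_s = times[j],
        k = k_run, n_spikes = k_run + 1L,
        duration_s = times[j] - times[i])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start_index = integer(), end_index = integer(),
                      start_s = numeric(), end_s = numeric(), k = integer(),
                      n_spikes = integer(), duration_s = numeric()))
  }
  do.call(rbind, out)
}

#' Detect bursts with the gamma waiting-time test
#'
#' Scans each spike train left to right. A candidate run starting at spike
#' *i* grows one ISI at a time; at each length *k* the span
#' \eqn{\tau = t_{i+k} - t_i} is scored with [gamma_burst_prob()]. The run
#' survives only while the probability stays below `alpha` at every length,
#' and ends at the last spike for which it did. Surviving runs with
#' `k >= k_min` ISIs are bursts; scanning resumes after a burst so bursts are
#' disjoint and time-ordered. Runs truncated by the end of the recording are
#' kept if they reach `k_min`.
#'
#' @param spikes Spike table (`unit_id`, `time_s`) or numeric vector.
#' @param duration Recording duration in seconds.
#' @param alpha Probability threshold (default 0.01).
#' @param k_min Minimum run length in ISIs (default 10), so a burst has at
#'   least `k_min + 1` spikes.
#' @param rate Optional named numeric vector of per-unit null rates in Hz;
#'   by default the global rate `n_spikes / duration` of each unit.
#' @return An object of class `prehear_bursts`: a list with `bursts` (one row
#'   per burst: indices, times, `k`, `n_spikes`, `duration_s`, `rate_hz`),
#'   `units` (per-unit `lambda_hat`, `cv`, `median_isi_s`, `n_bursts`,
#'   `bursts_per_100s`, `rate_hz`), and the configuration. Use
#'   [generics::tidy()] / [generics::glance()] to extract tibbles.
#' @export
detect_bursts <- function(spikes, duration, alpha = 0.01, k_min = 10,
                          rate = NULL) {
  abort_if(!(alpha > 0 && alpha < 1), "`alpha` must be in (0, 1)")
  abort_if(k_min < 1, "`k_min` must be >= 1")
  spikes <- as_spike_table(spikes)
  rates <- estimate_rate(spikes, duration)
  isics <- isi_cv(compute_isis(spikes))

  per_unit <- split(spikes$time_s, spikes$unit_id)
  bursts <- purrr::imap(per_unit, function(times, uid) {
    lam <- if (!is.null(rate)) unname(rate[[uid]]) else length(times) / duration
    b <- scan_bursts_one(times, lam, alpha, k_min)
    if (nrow(b)) b$unit_id <- uid
    b
  })
  bursts <- dplyr::bind_rows(bursts)
  if (!nrow(bursts)) {
    bursts <- tibble::tibble(unit_id = character(), start_index = integer(),
                             end_index = integer(), start_s = numeric(),
                             end_s = numeric(), k = integer(),
                             n_spikes = integer(), duration_s = numeric(),
                             rate_hz = numeric())
  } else {
    bursts <- tibble::as_tibble(bursts) |>
      dplyr::mutate(rate_hz = .data$n_spikes / .data$duration_s) |>
      dplyr::relocate("unit_id")
  }

  units <- rates |>
    dplyr::left_join(isics, by = "unit_id") |>
    dplyr::left_join(dplyr::count(bursts, .data$unit_id, name = "n_bursts"),
                     by = "unit_id") |>
    dplyr::mutate(n_bursts = dplyr::coalesce(.data$n_bursts, 0L),
                  duration_s = duration,
                  lambda_hat = if (!is.null(rate)) unname(rate[.data$unit_id]) else .data$rate_hz,
                  bursts_per_100s = 100 * .data$n_bursts / duration)

  structure(list(bursts = bursts, units = units,
                 alpha = alpha, k_min = k_min, duration = duration),
            class = "prehear_bursts")
}

#' @export
print.prehear_bursts <- function(x, ...) {
  cat(sprintf("<prehear_bursts> %d units, %d bursts (alpha = %g, k_min = %d)\n",
              nrow(x$units), nrow(x$bursts), x$alpha, x$k_min))
  invisible(x)
}

#' Per-unit burst metrics
#'
#' @param x A `prehear_bursts` object from [detect_bursts()].
#' @return A tibble with one row per unit: `n_bursts`, `bursts_per_100s`,
#'   overall `rate_hz`, `cv`, `median_isi_s`, and per-unit medians of burst
#'   spike count, duration and within-burst rate (NA for burst-free units).
#' @export
burst_metrics <- function(x) {
  stopifnot(inherits(x, "prehear_bursts"))
  per_burst <- x$bursts |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(median_spikes_per_burst = stats::median(.data$n_spikes),
                     median_burst_duration_s = stats::median(.data$duration_s),
                     median_within_burst_rate_hz = stats::median(.data$rate_hz),
                     .groups = "drop")
  x$units |>
    dplyr::left_join(per_burst, by = "unit_id") |>
    dplyr::select("unit_id", "n_spikes", "rate_hz", "cv", "median_isi_s",
                  "n_bursts", "bursts_per_100s",
                  dplyr::starts_with("median_"))
}

#' Pool equal numbers of ISIs per unit
#'
#' To avoid over-weighting high-rate cells when comparing ISI distributions
#' between groups, `n` random ISIs are drawn without replacement from each
#' unit, where `n` is the lowest ISI count of any unit in either group. Units
#' with all their ISIs equal to `n` contribute their full data.
#'
#' @param isis A tibble with columns `group`, `unit_id`, `isi_s`.
#' @param seed Integer seed making the draw reproducible.
#' @return A tibble `group`, `unit_id`, `isi_s` with exactly `n` rows per
#'   unit. Units without ISIs are dropped with a warning.
#' @export
pool_isis <- function(isis, seed) {
  abort_if(!all(c("group", "unit_id", "isi_s") %in% names(isis)),
           "`isis` must have columns group, unit_id and isi_s")
  counts <- isis |> dplyr::count(.data$group, .data$unit_id)
  if (any(counts$n == 0)) {
    warning("units without ISIs excluded from pooling")
    counts <- counts[counts$n > 0, ]
  }
  n_min <- min(counts$n)
  with_seed(seed, {
    isis |>
      dplyr::semi_join(counts, by = c("group", "unit_id")) |>
      dplyr::group_by(.data$group, .data$unit_id) |>
      dplyr::slice_sample(n = n_min) |>
      dplyr::ungroup()
  })
}

#' Shared logarithmic histogram bins for ISIs
#'
#' @param from,to Bin range in seconds.
#' @param per_decade Bins per decade (default 5).
#' @return Vector of bin edges in seconds.
#' @export
log_isi_bins <- function(from = 1e-3, to = 100, per_decade = 5) {
  10^seq(log10(from), log10(to), by = 1 / per_decade)
}

#' Compare pooled ISI distributions between two groups
#'
#' Runs the two-sample Kolmogorov-Smirnov test on the pooled samples and a
#' chi-square test on their shared log-binned histograms. Histogram bins whose
#' expected count falls below 5 are merged with their neighbour before the
#' chi-square test; if everything collapses into one bin the chi-square is
#' reported as NA.
#'
#' @param pooled Tibble from [pool_isis()] with exactly two groups.
#' @param bins Bin edges in seconds, see [log_isi_bins()].
#' @return One-row tibble: `ks_D`, `ks_p`, `chisq_stat`, `chisq_df`,
#'   `chisq_p`, `n_per_group`.
#' @export
compare_isi_distributions <- function(pooled, bins = log_isi_bins()) {
  groups <- unique(pooled$group)
  abort_if(length(groups) != 2, "`pooled` must contain exactly two groups")
  a <- pooled$isi_s[pooled$group == groups[1]]
  b <- pooled$isi_s[pooled$group == groups[2]]
  abort_if(!length(a) || !length(b), "both groups must be non-empty")
  ks <- suppressWarnings(stats::ks.test(a, b))

  edges <- unique(c(-Inf, bins, Inf))
  ca <- as.vector(table(cut(a, edges)))
  cb <- as.vector(table(cut(b, edges)))
  # merge adjacent bins until every expected count is >= 5
  tab <- rbind(ca, cb)
  repeat {
    tot <- colSums(tab)
    keep <- tot > 0
    tab <- tab[, keep, drop = FALSE]
    if (ncol(tab) < 2) break
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    small <- which(apply(exp_counts, 2, min) < 5)
    if (!length(small)) break
    j <- small[1]
    nb <- if (j == ncol(tab)) j - 1L else j + 1L
    tab[, nb] <- tab[, nb] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
  if (ncol(tab) < 2) {
    chi <- list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
  } else {
    chi <- suppressWarnings(stats::chisq.test(tab))
  }
  tibble::tibble(ks_D = unname(ks$statistic), ks_p = ks$p.value,
                 chisq_stat = unname(chi$statistic),
                 chisq_df = unname(chi$parameter),
                 chisq_p = chi$p.value,
                 n_per_group = length(a))
}
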