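#' Construct a frequency response area matrix
#'
#' @param counts Spike-count matrix, levels (rows, ascending dB SPL) by
#'   frequencies (columns, ascending kHz).
#' @param freqs_khz Stimulus frequencies in kHz, strictly increasing.
#' @param levels_db Stimulus levels in dB SPL, strictly increasing.
#' @param reps Repetitions per frequency/level bin.
#' @param window_s Counting window per stimulus in seconds.
#' @return An object of class `prehear_fra`.
#' @export
new_fra <- function(counts, freqs_khz, levels_db, reps = 1, window_s = 0.05) {
  abort_if(any(diff(freqs_khz) <= 0) || any(diff(levels_db) <= 0),
           "frequency and level grids must be strictly increasing")
  abort_if(!all(dim(counts) == c(length(levels_db), length(freqs_khz))),
           "`counts` must be levels x frequencies")
  abort_if(any(counts < 0), "spike counts must be non-negative")
  structure(list(counts = counts, freqs_khz = freqs_khz,
                 levels_db = levels_db, reps = reps, window_s = window_s),
            class = "prehear_fra")
}

#' @export
print.prehear_fra <- function(x, ...) {
  cat(sprintf("<prehear_fra> %d levels (%g..%g dB SPL) x %d freqs (%g..%g kHz)\n",
              length(x$levels_db), min(x$levels_db), max(x$levels_db),
              length(x$freqs_khz), min(x$freqs_khz), max(x$freqs_khz)))
  invisible(x)
}

#' Firing rates of an FRA
#'
#' @param fra A `prehear_fra`.
#' @return Matrix of rates in AP/s (levels x frequencies).
#' @export
fra_rates <- function(fra) {
  fra$counts / (fra$reps * fra$window_s)
}

#' Significance mask of an FRA
#'
#' A bin is significant when its rate exceeds the spontaneous rate by
#' `c_sd` spontaneous standard deviations. By default spontaneous statistics
#' are estimated from the lowest-level row, which is assumed sub-threshold;
#' supply `spont` explicitly when it is not.
#'
#' @param fra A `prehear_fra`.
#' @param c_sd Criterion in spontaneous SDs (default 3).
#' @param spont Optional list with `mean` and `sd` of the spontaneous rate in
#'   AP/s.
#' @return Logical matrix, levels x frequencies.
#' @export
fra_significant_mask <- function(fra, c_sd = 3, spont = NULL) {
  r <- fra_rates(fra)
  if (is.null(spont)) {
    spont <- list(mean = mean(r[1, ]), sd = stats::sd(r[1, ]))
  }
  abort_if(is.na(spont$mean) || is.na(spont$sd),
           "spontaneous rate not estimable; supply `spont`")
  r > spont$mean + c_sd * spont$sd
}

#' Characteristic frequency and threshold
#'
#' The threshold is the lowest level with any significant bin; the
#' characteristic frequency (CF) is the frequency of the significant bin at
#' that level. Ties between bins at threshold are broken by larger response,
#' then by lower frequency.
#'
#' @param mask Logical matrix from [fra_significant_mask()].
#' @param fra The matching `prehear_fra`.
#' @return A list with `cf_khz`, `threshold_db`.
#' @export
fra_cf_threshold <- function(mask, fra) {
  rows <- which(rowSums(mask) > 0)
  abort_if(!length(rows), "no significant response; CF undefined")
  thr_row <- rows[1]
  cols <- which(mask[thr_row, ])
  if (length(cols) > 1) {
    resp <- fra$counts[thr_row, cols]
    cols <- cols[resp == max(resp)]
  }
  list(cf_khz = fra$freqs_khz[min(cols)], threshold_db = fra$levels_db[thr_row])
}

#' Bandwidths and Q factors above threshold
#'
#' At `n` dB above threshold (nearest grid row) the bandwidth BW_n is the
#' frequency extent of the significant span containing the CF, measured
#' between its outermost significant columns; Q_n = CF / BW_n quantifies
#' sharpness of tuning. Disconnected significant islands away from the CF are
#' ignored with a warning. Levels beyond the grid are reported as NA.
#'
#' @param mask,fra As in [fra_cf_threshold()].
#' @param cf_khz,threshold_db CF and threshold, e.g. from
#'   [fra_cf_threshold()].
#' @param n_db Levels above threshold to evaluate (default 10, 20, 30).
#' @return Tibble with `n_db`, `bw_khz`, `q`.
#' @export
fra_q_factors <- function(mask, fra, cf_khz, threshold_db, n_db = c(10, 20, 30)) {
  cf_col <- which.min(abs(fra$freqs_khz - cf_khz))
  purrr::map_dfr(n_db, function(n) {
    target <- threshold_db + n
    if (target > max(fra$levels_db) + diff(range(fra$levels_db)) * 0 ||
        target > max(fra$levels_db)) {
      return(tibble::tibble(n_db = n, bw_khz = NA_real_, q = NA_real_))
    }
    row <- which.min(abs(fra$levels_db - target))
    sig <- mask[row, ]
    if (!sig[cf_col]) {
      return(tibble::tibble(n_db = n, bw_khz = NA_real_, q = NA_real_))
    }
    # span of contiguous significant columns containing the CF column
    lo <- cf_col
    while (lo > 1 && sig[lo - 1]) lo <- lo - 1
    hi <- cf_col
    while (hi < length(sig) && sig[hi + 1]) hi <- hi + 1
    if (sum(sig) > hi - lo + 1) {
      warning("significant islands away from CF ignored for bandwidth")
    }
    bw <- fra$freqs_khz[hi] - fra$freqs_khz[lo]
    tibble::tibble(n_db = n, bw_khz = bw,
                   q = if (bw > 0) cf_khz / bw else NA_real_)
  })
}

#' Rate-level function at CF and maximum evoked rate
#'
#' @param fra A `prehear_fra`.
#' @param cf_khz Characteristic frequency (matched to the nearest grid
#'   column).
#' @return List with `rate_level` (tibble `level_db`, `rate_hz`, ascending
#'   levels) and `max_rate_hz` (maximum over the whole matrix).
#' @export
fra_rate_level <- function(fra, cf_khz) {
  r <- fra_rates(fra)
  col <- which.min(abs(fra$freqs_khz - cf_khz))
  list(rate_level = tibble::tibble(level_db = fra$levels_db,
                                   rate_hz = r[, col]),
       max_rate_hz = max(r))
}

#' All tuning metrics of one FRA
#'
#' @param fra A `prehear_fra`.
#' @param c_sd Significance criterion, see [fra_significant_mask()].
#' @param spont Optional explicit spontaneous statistics.
#' @return One-row tibble: `cf_khz`, `threshold_db`, `bw10/20/30_khz`,
#'   `q10/20/30`, `max_rate_hz`.
#' @export
fra_metrics <- function(fra, c_sd = 3, spont = NULL) {
  mask <- fra_significant_mask(fra, c_sd, spont)
  ct <- fra_cf_threshold(mask, fra)
  q <- fra_q_factors(mask, fra, ct$cf_khz, ct$threshold_db)
  rl <- fra_rate_level(fra, ct$cf_khz)
  tibble::tibble(
    cf_khz = ct$cf_khz, threshold_db = ct$threshold_db,
    bw10_khz = q$bw_khz[q$n_db == 10], bw20_khz = q$bw_khz[q$n_db == 20],
    bw30_khz = q$bw_khz[q$n_db == 30],
    q10 = q$q[q$n_db == 10], q20 = q$q[q$n_db == 20], q30 = q$q[q$n_db == 30],
    max_rate_hz = rl$max_rate_hz)
}
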