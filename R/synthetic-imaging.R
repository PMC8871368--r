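#' Simulate a time-lapse imaging stack with spontaneous events
#'
#' Emulates spontaneous activity of the inner-supporting-cell band
#' (Kölliker's organ) in the prehearing cochlea, for two modalities: DIC
#' volume-change imaging (single intensity channel) and Fura-2 ratiometric
#' Ca2+ imaging (340 and 380 nm channel pair; the event signal is carried
#' multiplicatively on the 340 channel only, so the ratio operation is
#' non-trivial). Events are elliptical footprints confined to a horizontal
#' band standing in for Kölliker's organ; in the wildtype presets they grow
#' and translate along the band (propagating waves), in the knockout presets
#' they are small and stationary. Event onsets follow a renewal process with
#' a hard minimum gap, so events never overlap in time.
#'
#' @param preset An imaging preset from [imaging_preset()].
#' @param seed Integer seed; identical `(preset, seed)` give identical
#'   output.
#' @param events Optional explicit event table (columns `onset_frame`,
#'   `x_um`, `y_um`, `area_um2`, `amplitude`) overriding random placement;
#'   used for injection experiments.
#' @return A list of class `imaging_sim`: for DIC a `$stack`, for Fura a
#'   `$ch340`/`$ch380` pair (all `prehear_stack`), plus `truth` (one row per
#'   event: `event_id`, `onset_frame`, `offset_frame`, `area_um2` = realized
#'   maximal footprint, `x_um`, `y_um` = peak centroid) and `preset`.
#' @export
simulate_imaging_stack <- function(preset, seed, events = NULL) {
  validate_imaging_preset(preset)
  with_seed(seed, simulate_stack_impl(preset, events))
}

simulate_stack_impl <- function(p, explicit_events) {
  nr <- p$field_px[[1]]; nc <- p$field_px[[2]]
  px <- p$pixel_size_um
  n <- p$n_frames
  growth <- unlist(p$growth_profile)
  len <- length(growth)
  peak_idx <- which.max(growth)[1]

  ev <- explicit_events %||% draw_event_schedule(p, len)
  signal <- array(0, c(nr, nc, n))
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px
  band <- unlist(p$band_rows_um)
  band_rows <- ys >= band[1] & ys <= band[2]

  truth <- list()
  if (!is.null(ev) && nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      aspect <- p$event_aspect
      a <- sqrt(e$area_um2 * aspect / pi)
      b <- a / aspect
      dir <- if ("dir" %in% names(e)) e$dir else 0
      max_area_px <- 0L; peak_cx <- NA_real_; peak_cy <- NA_real_
      first_f <- NA_integer_; last_f <- NA_integer_
      for (j in seq_len(len)) {
        f <- e$onset_frame + j - 1L
        if (f > n) break
        g <- growth[j]
        cx <- e$x_um + p$speed_um_per_frame * dir * (j - peak_idx)
        cy <- e$y_um
        aj <- a * sqrt(g); bj <- b * sqrt(g)
        mask <- outer(((ys - cy) / bj)^2, ((xs - cx) / aj)^2, `+`) <= 1
        mask <- mask & band_rows
        npx <- sum(mask)
        if (npx == 0) next
        first_f <- min(first_f, f, na.rm = TRUE)
        last_f <- f
        signal[, , f] <- pmax(signal[, , f], e$amplitude * g * mask)
        if (npx > max_area_px) {
          max_area_px <- npx
          idx <- which(mask, arr.ind = TRUE)
          peak_cx <- mean(xs[idx[, 2]]); peak_cy <- mean(ys[idx[, 1]])
        }
      }
      if (max_area_px > 0) {
        truth[[length(truth) + 1L]] <- tibble::tibble(
          event_id = length(truth) + 1L, onset_frame = first_f,
          offset_frame = last_f, area_um2 = max_area_px * px^2,
          x_um = peak_cx, y_um = peak_cy)
      }
    }
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(event_id = integer(), onset_frame = integer(),
                   offset_frame = integer(), area_um2 = numeric(),
                   x_um = numeric(), y_um = numeric())

  quantize <- function(x) {
    x <- round(x + stats::rnorm(length(x), 0, p$noise_sd))
    array(pmin(pmax(x, 0), 65535), dim(x))
  }
  out <- if (p$modality == "dic") {
    list(stack = new_stack(quantize(p$baseline_level * (1 + signal)),
                           px, p$frame_interval_s, "dic"))
  } else {
    list(ch340 = new_stack(quantize(p$baseline_level * (1 + signal)),
                           px, p$frame_interval_s, "fura_340"),
         ch380 = new_stack(quantize(array(p$baseline_level, dim(signal))),
                           px, p$frame_interval_s, "fura_380"))
  }
  out$truth <- truth
  out$preset <- p
  class(out) <- "imaging_sim"
  out
}

#' @export
print.imaging_sim <- function(x, ...) {
  cat(sprintf("<imaging_sim> %s %s: %d true events\n",
              x$preset$label, x$preset$modality, nrow(x$truth)))
  invisible(x)
}

# Event-onset schedule: the per-stack event count is the expected count with
# only its fractional part randomised, and onsets are placed uniformly over
# the usable frame range under a hard minimum gap, so events never overlap in
# time (active tissue is refractory between waves) and the cohort event
# frequency is tightly controlled.
draw_event_schedule <- function(p, len) {
  if (p$event_rate_hz <= 0) return(NULL)
  n <- p$n_frames
  min_gap <- p$min_onset_gap_frames
  target <- p$event_rate_hz * n * p$frame_interval_s
  k <- floor(target) + stats::rbinom(1, 1, target - floor(target))
  if (k == 0) return(NULL)
  lo <- 7  # first frames carry no valid delta; start events after warm-up
  hi <- n - len - 1
  span <- hi - lo
  while (k > 1 && span - (k - 1) * min_gap <= 0) k <- k - 1
  free <- span - (k - 1) * min_gap
  w <- stats::rexp(k + 1)
  extra <- free * w / sum(w)
  onsets <- round(lo + cumsum(extra[seq_len(k)] +
                                c(0, rep(min_gap, k - 1))))
  if (!length(onsets)) return(NULL)
  nr <- p$field_px[[1]]; nc <- p$field_px[[2]]
  px <- p$pixel_size_um
  # peak centroids stay well inside the analysis region so that clipping and
  # translation cannot push the detected centroid across the ROI border
  half <- sqrt(10000) / 2 - 10
  cx <- nc * px / 2; cy <- nr * px / 2
  band <- unlist(p$band_rows_um)
  ylo <- max(cy - half, band[1] + 4); yhi <- min(cy + half, band[2] - 4)
  tibble::tibble(
    onset_frame = onsets,
    x_um = stats::runif(length(onsets), cx - half, cx + half),
    y_um = stats::runif(length(onsets), ylo, yhi),
    area_um2 = stats::rlnorm(length(onsets),
                             log(p$event_area_mean_um2) - p$event_area_sdlog^2 / 2,
                             p$event_area_sdlog),
    amplitude = p$event_amplitude,
    dir = sample(c(-1, 1), length(onsets), replace = TRUE))
}
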