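# Independent oracles used across test files. They deliberately avoid the
# package's own code paths: Poisson tail sums instead of pgamma, a naive
# O(n^2) re-scan instead of the production burst scan, and a pixel-level
# brute-force scan for injected imaging events.

# Poisson tail P(Pois(lambda*tau) >= k) by explicit summation.
poisson_tail_p <- function(k, tau, lambda) {
  mu <- lambda * tau
  1 - sum(exp(-mu + (0:(k - 1)) * log(mu) - lgamma(1:k)) * (mu > 0)) -
    (mu == 0) * 0
}

# Naive burst scan: at every candidate start re-evaluate the whole p-sequence
# with the Poisson-tail identity; a run survives while p < alpha at every k.
oracle_bursts <- function(times, lambda, alpha = 0.01, k_min = 10) {
  n <- length(times)
  out <- list()
  i <- 1
  while (i <= n - 1) {
    k_run <- 0
    for (k in seq_len(n - i)) {
      mu <- lambda * (times[i + k] - times[i])
      p <- 1 - stats::ppois(k - 1, mu)
      if (p < alpha) k_run <- k else break
    }
    if (k_run >= k_min) {
      out[[length(out) + 1]] <- c(start = as.integer(i),
                                  end = as.integer(i + k_run))
      i <- i + k_run + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# A dense run embedded in a sparse background, built so the run's p-sequence
# survives from its very first interval (sub-ms onset doublet).
make_embedded_burst_train <- function() {
  dense <- 10 + cumsum(c(0, 0.0008, rep(0.02, 49)))
  background <- setdiff(seq(0.5, 99.5, by = 1), NULL)
  background <- background[background < 9.5 | background > 12]
  sort(c(background, dense))
}

# Small stack with one rectangular injected event, for detector unit tests.
# Returns the stack plus the injected footprint geometry.
make_injected_stack <- function(area_um2 = 200, amplitude = 0.3,
                                n_frames = 30, onset = 15, px = 2,
                                dims = c(40, 40), baseline = 1000,
                                noise_sd = 0, duration_frames = 3,
                                seed = 99) {
  set.seed(seed)
  side_px <- round(sqrt(area_um2) / px)
  frames <- array(baseline, c(dims, n_frames)) +
    array(stats::rnorm(prod(dims) * n_frames, 0, noise_sd),
          c(dims, n_frames))
  r0 <- dims[1] / 2 - floor(side_px / 2)
  c0 <- dims[2] / 2 - floor(side_px / 2)
  rows <- r0:(r0 + side_px - 1)
  cols <- c0:(c0 + side_px - 1)
  for (f in onset:(onset + duration_frames - 1)) {
    frames[rows, cols, f] <- frames[rows, cols, f] + amplitude * baseline
  }
  list(stack = new_stack(frames, px, 1, "dic"),
       rows = rows, cols = cols, area_um2 = side_px^2 * px^2,
       onset = onset)
}

# Greedy matching of detected events to ground-truth events by peak-centroid
# distance and frame overlap; returns recall and precision.
match_events <- function(truth, events, max_dist_um = 40) {
  if (!nrow(truth) || !nrow(events)) {
    return(c(recall = 0, precision = 0))
  }
  used <- rep(FALSE, nrow(events))
  hits <- 0
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((events$centroid_x_um - truth$x_um[i])^2 +
                (events$centroid_y_um - truth$y_um[i])^2)
    overlap <- events$onset_frame <= truth$offset_frame[i] + 2 &
      events$offset_frame >= truth$onset_frame[i] - 2
    j <- which(!used & overlap & d <= max_dist_um)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      hits <- hits + 1
    }
  }
  c(recall = hits / nrow(truth), precision = sum(used) / nrow(events))
}
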