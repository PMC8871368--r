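#' Construct a calibrated imaging stack
#'
#' @param frames Numeric array `[row, col, frame]` of intensities (or ratios).
#' @param pixel_size_um Pixel size in µm per pixel (> 0).
#' @param frame_interval_s Frame interval in seconds.
#' @param modality One of `"dic"`, `"fura_340"`, `"fura_380"`, `"fura_ratio"`.
#' @return An object of class `prehear_stack`.
#' @export
new_stack <- function(frames, pixel_size_um, frame_interval_s = 1,
                      modality = "dic") {
  abort_if(length(dim(frames)) != 3, "`frames` must be a 3-d array [row, col, frame]")
  abort_if(dim(frames)[3] < 6, "a stack needs at least 6 frames")
  abort_if(pixel_size_um <= 0, "`pixel_size_um` must be positive")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s, modality = modality),
            class = "prehear_stack")
}

#' @export
print.prehear_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<prehear_stack> %s: %d x %d px (%g um/px), %d frames @ %g s\n",
              x$modality, d[1], d[2], x$pixel_size_um, d[3], x$frame_interval_s))
  invisible(x)
}

#' Ratiometric Fura-2 stack from the 340/380 nm channel pair
#'
#' The 340 nm channel carries the Ca2+-dependent signal; the per-pixel ratio
#' 340/380 cancels dye loading and illumination inhomogeneity. Pixels whose
#' denominator falls at or below `floor` are masked (NA) rather than
#' producing unbounded ratios.
#'
#' @param stack340,stack380 `prehear_stack` objects with identical geometry.
#' @param floor Denominator floor in intensity counts.
#' @return A `prehear_stack` with modality `"fura_ratio"`.
#' @export
compute_ratio <- function(stack340, stack380, floor = 1) {
  abort_if(!identical(dim(stack340$frames), dim(stack380$frames)),
           "channel stacks must have identical dimensions")
  abort_if(stack340$pixel_size_um != stack380$pixel_size_um ||
             stack340$frame_interval_s != stack380$frame_interval_s,
           "channel stacks must share pixel size and frame interval")
  den <- stack380$frames
  ratio <- stack340$frames / den
  ratio[den <= floor] <- NA_real_
  new_stack(ratio, stack340$pixel_size_um, stack340$frame_interval_s,
            modality = "fura_ratio")
}

#' Moving-average frame subtraction
#'
#' Each frame (time point \eqn{t_n}) is subtracted from the average of the
#' `window` preceding frames, highlighting intensity changes against the slow
#' background: \eqn{\Delta_n = F_n - \mathrm{mean}(F_{n-1}, \dots,
#' F_{n-window})}. The first `window` frames have no valid average and are
#' returned as NA; downstream detection skips them.
#'
#' @param stack A `prehear_stack`.
#' @param window Number of preceding frames to average (default 5).
#' @return A `prehear_stack` of the same geometry holding the delta frames,
#'   with attribute `window`.
#' @export
subtract_moving_average <- function(stack, window = 5) {
  d <- dim(stack$frames)
  abort_if(d[3] <= window, "stack must have more frames than the window")
  delta <- array(NA_real_, d)
  run_sum <- matrix(0, d[1], d[2])
  for (n in seq_len(window)) run_sum <- run_sum + stack$frames[, , n]
  for (n in (window + 1):d[3]) {
    delta[, , n] <- stack$frames[, , n] - run_sum / window
    run_sum <- run_sum + stack$frames[, , n] - stack$frames[, , n - window]
  }
  out <- new_stack(delta, stack$pixel_size_um, stack$frame_interval_s,
                   modality = paste0(stack$modality, "_delta"))
  attr(out, "window") <- window
  out
}

#' Rectangular pixel region of interest
#'
#' @param rows,cols Inclusive pixel index ranges `c(first, last)`.
#' @return A list usable as `baseline_roi` / `analysis_roi`.
#' @export
roi_rect <- function(rows, cols) {
  abort_if(length(rows) != 2 || length(cols) != 2 || any(rows < 1) || any(cols < 1) ||
             rows[2] < rows[1] || cols[2] < cols[1],
           "ROI bounds must be inclusive index pairs with last >= first")
  list(rows = as.integer(rows), cols = as.integer(cols))
}

#' Baseline level from a quiet region
#'
#' The baseline is the spatio-temporal mean intensity (or ratio) inside a
#' region of the field that shows no events, mirroring the practice of
#' measuring baseline outside the active epithelium.
#'
#' @param stack A `prehear_stack` (raw intensities or ratio, not deltas).
#' @param roi A region from [roi_rect()].
#' @return A scalar baseline level.
#' @export
measure_baseline <- function(stack, roi) {
  d <- dim(stack$frames)
  abort_if(roi$rows[2] > d[1] || roi$cols[2] > d[2], "ROI outside field")
  mean(stack$frames[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2], ],
       na.rm = TRUE)
}

#' Event-detection configuration
#'
#' @param window Moving-average window in frames.
#' @param threshold_fraction Detection threshold as a fraction of the
#'   baseline level applied to the delta image (default 0.10).
#' @param min_area_um2 Minimum instantaneous event area; the default 50 µm²
#'   stands for the surface area of one inner supporting cell and is
#'   configurable.
#' @param baseline_roi Quiet region ([roi_rect()]); default: the top 8% rows
#'   of the field, which lie outside the generated band.
#' @param analysis_roi_um2 Area of the centred square analysis region
#'   (default 10,000 µm²).
#' @param analysis_roi Optional explicit [roi_rect()] overriding the centred
#'   square.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(window = 5, threshold_fraction = 0.10,
                             min_area_um2 = 50, baseline_roi = NULL,
                             analysis_roi_um2 = 10000, analysis_roi = NULL) {
  abort_if(!(threshold_fraction > 0 && threshold_fraction < 1),
           "`threshold_fraction` must be in (0, 1)")
  abort_if(min_area_um2 <= 0, "`min_area_um2` must be positive")
  structure(list(window = window, threshold_fraction = threshold_fraction,
                 min_area_um2 = min_area_um2, baseline_roi = baseline_roi,
                 analysis_roi_um2 = analysis_roi_um2,
                 analysis_roi = analysis_roi),
            class = "detection_config")
}

default_baseline_roi <- function(dims) {
  roi_rect(c(1, max(2, floor(dims[1] * 0.08))), c(1, dims[2]))
}

analysis_bounds_um <- function(dims, pixel_size, config) {
  if (!is.null(config$analysis_roi)) {
    r <- config$analysis_roi
    return(c(x = (r$cols[1] - 1) * pixel_size, x2 = r$cols[2] * pixel_size,
             y = (r$rows[1] - 1) * pixel_size, y2 = r$rows[2] * pixel_size))
  }
  half <- sqrt(config$analysis_roi_um2) / 2
  cx <- dims[2] * pixel_size / 2
  cy <- dims[1] * pixel_size / 2
  c(x = cx - half, x2 = cx + half, y = cy - half, y2 = cy + half)
}

# 8-connected labelling of a logical matrix. Returns an integer label matrix
# (0 = background). Connectivity includes the two diagonals, matching the
# event-assembly convention.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  n <- sum(mask)
  lab <- matrix(0L, nr, nc)
  if (n == 0) return(lab)
  id <- matrix(0L, nr, nc)
  id[mask] <- seq_len(n)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    sel <- a > 0L & b > 0L
    if (any(sel)) edges[[length(edges) + 1L]] <- cbind(a[sel], b[sel])
  }
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(n)
  }
  lab[mask] <- as.integer(memb)
  lab
}

#' Detect spatiotemporal events in a delta stack
#'
#' Pixels whose delta exceeds `threshold_fraction x baseline` are active.
#' Active pixels are grouped per frame into 8-connected components, and
#' components are linked across frames into spatiotemporal events when they
#' overlap by at least one pixel; gaps of one frame are bridged so that
#' events flickering near threshold are not split. An event is kept if its
#' maximum instantaneous component area reaches `min_area_um2`; that maximum
#' is the reported event area. Events are assigned to the analysis region if
#' their centroid at the peak frame (largest component) lies inside it.
#'
#' @param delta Delta stack from [subtract_moving_average()].
#' @param baseline Scalar baseline from [measure_baseline()] (> 0).
#' @param config A [detection_config()].
#' @return A tibble with one row per event: `event_id`, `onset_frame`,
#'   `offset_frame`, `area_um2`, `centroid_x_um`, `centroid_y_um`,
#'   `peak_rel_amplitude`, `in_roi`.
#' @export
detect_events <- function(delta, baseline, config = detection_config()) {
  abort_if(!is.numeric(baseline) || baseline <= 0, "`baseline` must be positive")
  d <- dim(delta$frames)
  px <- delta$pixel_size_um
  thr <- config$threshold_fraction * baseline
  window <- attr(delta, "window") %||% config$window

  labs <- vector("list", d[3])
  nodes <- list()  # per (frame, label): area, max delta
  for (f in (window + 1):d[3]) {
    m <- delta$frames[, , f] > thr
    m[is.na(m)] <- FALSE
    if (!any(m)) next
    lab <- label_components8(m)
    labs[[f]] <- lab
    areas <- tabulate(lab[lab > 0L])
    dmax <- tapply(delta$frames[, , f][lab > 0L], lab[lab > 0L], max)
    nodes[[length(nodes) + 1L]] <- data.frame(
      frame = f, label = seq_along(areas), area_px = areas,
      delta_max = as.numeric(dmax))
  }
  empty <- tibble::tibble(event_id = integer(), onset_frame = integer(),
                          offset_frame = integer(), area_um2 = numeric(),
                          centroid_x_um = numeric(), centroid_y_um = numeric(),
                          peak_rel_amplitude = numeric(), in_roi = logical())
  if (!length(nodes)) return(empty)
  nodes <- do.call(rbind, nodes)
  nodes$node_id <- seq_len(nrow(nodes))
  key <- paste(nodes$frame, nodes$label)
  node_of <- stats::setNames(nodes$node_id, key)

  # link overlapping components one and two frames apart (1-frame gap bridge)
  edges <- list()
  for (f in which(!vapply(labs, is.null, TRUE))) {
    for (gap in 1:2) {
      f2 <- f + gap
      if (f2 > d[3] || is.null(labs[[f2]])) next
      l1 <- labs[[f]]; l2 <- labs[[f2]]
      sel <- l1 > 0L & l2 > 0L
      if (!any(sel)) next
      pairs <- unique(cbind(l1[sel], l2[sel]))
      edges[[length(edges) + 1L]] <- cbind(
        node_of[paste(f, pairs[, 1])], node_of[paste(f2, pairs[, 2])])
    }
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(nodes) - igraph::vcount(g)))
    nodes$event <- igraph::components(g)$membership[nodes$node_id]
  } else {
    nodes$event <- nodes$node_id
  }

  bounds <- analysis_bounds_um(d, px, config)
  events <- lapply(split(nodes, nodes$event), function(nd) {
    peak <- nd[which.max(nd$area_px), ]
    lab <- labs[[peak$frame]]
    sel <- which(lab == peak$label, arr.ind = TRUE)
    cx <- (mean(sel[, 2]) - 0.5) * px
    cy <- (mean(sel[, 1]) - 0.5) * px
    data.frame(onset_frame = min(nd$frame), offset_frame = max(nd$frame),
               area_um2 = peak$area_px * px^2,
               centroid_x_um = cx, centroid_y_um = cy,
               peak_rel_amplitude = max(nd$delta_max) / baseline)
  })
  events <- dplyr::bind_rows(events)
  events <- events[events$area_um2 >= config$min_area_um2, , drop = FALSE]
  if (!nrow(events)) return(empty)
  events <- events[order(events$onset_frame), , drop = FALSE]
  tibble::as_tibble(events) |>
    dplyr::mutate(event_id = dplyr::row_number(),
                  in_roi = .data$centroid_x_um >= bounds["x"] &
                    .data$centroid_x_um <= bounds["x2"] &
                    .data$centroid_y_um >= bounds["y"] &
                    .data$centroid_y_um <= bounds["y2"]) |>
    dplyr::relocate("event_id")
}

#' Summarise detected events
#'
#' @param events Event tibble from [detect_events()].
#' @param duration Analysed duration in seconds (> 0).
#' @param roi_only Count only events whose peak centroid lies in the analysis
#'   region (default TRUE).
#' @return One-row tibble: `n_events`, `event_frequency_hz`,
#'   `mean_event_area_um2` (0 when no events), `duration_s`.
#' @export
summarize_events <- function(events, duration, roi_only = TRUE) {
  abort_if(duration <= 0, "`duration` must be positive")
  if (roi_only && nrow(events)) events <- events[events$in_roi, , drop = FALSE]
  tibble::tibble(
    n_events = nrow(events),
    event_frequency_hz = nrow(events) / duration,
    mean_event_area_um2 = if (nrow(events)) mean(events$area_um2) else 0,
    duration_s = duration)
}

#' Run the full event-detection chain on one stack
#'
#' Computes the Fura-2 ratio when given a 340/380 channel pair, subtracts the
#' moving average, measures the baseline in the quiet region, detects events
#' and summarises them.
#'
#' @param x A `prehear_stack` (DIC intensities or precomputed ratio) or a
#'   list with elements `ch340` and `ch380`.
#' @param config A [detection_config()].
#' @return A list with `events`, `summary`, `baseline`.
#' @export
analyze_stack <- function(x, config = detection_config()) {
  if (!inherits(x, "prehear_stack") && is.list(x) &&
      all(c("ch340", "ch380") %in% names(x))) {
    x <- compute_ratio(x$ch340, x$ch380)
  }
  stopifnot(inherits(x, "prehear_stack"))
  d <- dim(x$frames)
  broi <- config$baseline_roi %||% default_baseline_roi(d)
  baseline <- measure_baseline(x, broi)
  delta <- subtract_moving_average(x, config$window)
  events <- detect_events(delta, baseline, config)
  duration <- d[3] * x$frame_interval_s
  list(events = events, summary = summarize_events(events, duration),
       baseline = baseline)
}
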