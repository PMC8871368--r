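#' Peak postsynaptic potential in a response window
#'
#' Measures the peak depolarization from the pre-onset baseline within a
#' fixed window after laser onset, and flags action potentials when the
#' absolute membrane potential crosses the AP criterion.
#'
#' @param trace Membrane potential in mV.
#' @param time_s Sample times in seconds (same length as `trace`).
#' @param onset_s Laser onset time.
#' @param window_s Response window after onset (default 20 ms).
#' @param baseline_s Pre-onset span averaged as baseline (default 50 ms).
#' @param ap_criterion_mv Absolute potential above which the response counts
#'   as an action potential (default 0 mV, i.e. overshoot).
#' @return One-row tibble: `amplitude_mv`, `ap_flag`.
#' @export
extract_psp <- function(trace, time_s, onset_s, window_s = 0.020,
                        baseline_s = 0.050, ap_criterion_mv = 0) {
  abort_if(length(trace) != length(time_s), "trace and time must match")
  abort_if(onset_s + window_s > max(time_s) + 1e-12 || onset_s < min(time_s),
           "response window outside trace")
  pre <- trace[time_s >= onset_s - baseline_s & time_s < onset_s]
  abort_if(!length(pre), "no pre-onset samples for baseline")
  win <- trace[time_s >= onset_s & time_s <= onset_s + window_s]
  tibble::tibble(amplitude_mv = max(win) - mean(pre),
                 ap_flag = any(win > ap_criterion_mv))
}

site_class_levels <- c("unresponsive", "responsive_2mV", "responsive_10mV",
                       "action_potential")

#' Classify an uncaging site from its PSP amplitude
#'
#' Mirrors the map colour code: action potential beats everything; otherwise
#' depolarizations strictly greater than 10 mV are strong responses, strictly
#' greater than 2 mV are functional connections, and the rest (including
#' negative deflections) are unresponsive.
#'
#' @param amplitude_mv PSP amplitude(s) in mV.
#' @param ap_flag Logical action-potential flag(s).
#' @return Ordered factor with levels unresponsive < responsive_2mV <
#'   responsive_10mV < action_potential.
#' @export
classify_site <- function(amplitude_mv, ap_flag = FALSE) {
  cls <- ifelse(ap_flag, "action_potential",
                ifelse(amplitude_mv > 10, "responsive_10mV",
                       ifelse(amplitude_mv > 2, "responsive_2mV",
                              "unresponsive")))
  factor(cls, levels = site_class_levels, ordered = TRUE)
}

#' Add site classes to an uncaging-site table
#'
#' @param sites Tibble with columns `amplitude_mv` and `ap_flag`.
#' @return `sites` with a `class` column appended.
#' @export
classify_sites <- function(sites) {
  abort_if(!all(c("amplitude_mv", "ap_flag") %in% names(sites)),
           "`sites` needs columns amplitude_mv and ap_flag")
  dplyr::mutate(sites, class = classify_site(.data$amplitude_mv, .data$ap_flag))
}

polygon_x_extent <- function(polygon) {
  abort_if(!all(c("x_um", "y_um") %in% names(polygon)),
           "`polygon` needs columns x_um and y_um")
  diff(range(polygon$x_um))
}

#' Normalized input area of an uncaging map
#'
#' The input area is the summed area of all responsive uncaging sites (class
#' at least `responsive_2mV`), one site standing for `site_area_um2`,
#' normalized to the cross-sectional area of the nucleus outline. Responsive
#' sites falling slightly outside the outline are counted.
#'
#' @param sites Classified site table from [classify_sites()].
#' @param polygon Outline tibble with `x_um`, `y_um` (simple, closed
#'   implicitly).
#' @param site_area_um2 Area represented by one uncaging site (default
#'   400 µm², a 20 µm grid).
#' @return Input area as percent of the outline area.
#' @export
input_area <- function(sites, polygon, site_area_um2 = 400) {
  a_poly <- polygon_area(polygon$x_um, polygon$y_um)
  abort_if(a_poly <= 0, "degenerate outline polygon")
  n_resp <- sum(sites$class >= "responsive_2mV")
  100 * n_resp * site_area_um2 / a_poly
}

#' Normalized mediolateral input width
#'
#' The maximal distance along the mediolateral (x) axis between sites that
#' evoked depolarizations greater than 10 mV (action-potential sites
#' included), normalized to the mediolateral length of the outline. Zero when
#' fewer than two qualifying sites exist.
#'
#' @inheritParams input_area
#' @return Input width as percent of the outline's mediolateral length.
#' @export
input_width <- function(sites, polygon) {
  ext <- polygon_x_extent(polygon)
  abort_if(ext <= 0, "outline has no mediolateral extent")
  q <- sites$x_um[sites$class >= "responsive_10mV"]
  if (length(q) < 2) return(0)
  100 * (max(q) - min(q)) / ext
}

#' All input-map metrics of one map
#'
#' @inheritParams input_area
#' @return One-row tibble: `input_area_pct`, `input_width_pct`,
#'   `n_responsive`, `n_strong`, `polygon_area_um2`.
#' @export
input_map_metrics <- function(sites, polygon, site_area_um2 = 400) {
  if (!"class" %in% names(sites)) sites <- classify_sites(sites)
  tibble::tibble(
    input_area_pct = input_area(sites, polygon, site_area_um2),
    input_width_pct = input_width(sites, polygon),
    n_responsive = sum(sites$class >= "responsive_2mV"),
    n_strong = sum(sites$class >= "responsive_10mV"),
    polygon_area_um2 = polygon_area(polygon$x_um, polygon$y_um))
}
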