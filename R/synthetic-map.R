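#' Simulate an uncaging input map
#'
#' Emulates MNTB-to-LSO input mapping by glutamate uncaging: a 20 µm grid of
#' stimulation sites laid over and around an elliptical MNTB outline, with
#' postsynaptic-potential amplitudes following an elliptical Gaussian profile
#' around a presynaptic input centre (elongated along the mediolateral axis
#' in the knockout preset, whose tonotopic refinement has failed). Sites
#' within the AP core radius of the centre fire action potentials. The
#' profile scales are solved per map from the preset's fractional-area and
#' mediolateral-width targets against the realized outline.
#'
#' @param preset A map preset from [map_preset()].
#' @param seed Integer seed.
#' @return A list of class `map_sim` with `sites` (tibble `site_id`, `x_um`,
#'   `y_um`, `amplitude_mv`, `ap_flag`), `polygon` (outline tibble `x_um`,
#'   `y_um`), `truth` (noiseless responsive/strong site ids, centre,
#'   targets) and `preset`.
#' @export
simulate_input_map <- function(preset, seed) {
  with_seed(seed, simulate_map_impl(preset))
}

simulate_map_impl <- function(p) {
  scale <- exp(stats::rnorm(1, 0, p$polygon_scale_jitter_sd))
  ax <- p$polygon_semiaxes_um[1] * scale
  ay <- p$polygon_semiaxes_um[2] * scale
  th <- seq(0, 2 * pi, length.out = p$polygon_vertices + 1)[-1]
  polygon <- tibble::tibble(x_um = ax * cos(th), y_um = ay * sin(th))
  a_poly <- polygon_area(polygon$x_um, polygon$y_um)
  lx <- polygon_x_extent(polygon)

  spacing <- p$grid_spacing_um
  margin <- p$grid_margin_um
  phase <- stats::runif(2, 0, spacing)
  gx <- seq(-ax - margin + phase[1], ax + margin, by = spacing)
  gy <- seq(-ay - margin + phase[2], ay + margin, by = spacing)
  abort_if(!length(gx) || !length(gy), "empty uncaging grid")
  sites <- tidyr::expand_grid(x_um = gx, y_um = gy)

  centre <- stats::runif(2, -p$center_jitter_um, p$center_jitter_um)
  prof <- profile_scales(p, a_poly, lx)
  amp0 <- profile_amplitude(prof, p, sites$x_um - centre[1],
                            sites$y_um - centre[2])
  d_centre <- sqrt((sites$x_um - centre[1])^2 + (sites$y_um - centre[2])^2)
  ap <- d_centre <= p$ap_radius_um & p$amp_max_mv > 0
  amp <- amp0 + stats::rnorm(nrow(sites), 0, p$noise_sd_mv)

  sites <- sites |>
    dplyr::mutate(site_id = dplyr::row_number(),
                  amplitude_mv = amp, ap_flag = ap) |>
    dplyr::relocate("site_id")
  truth <- list(
    responsive_ids = sites$site_id[amp0 > 2 | ap],
    strong_ids = sites$site_id[amp0 > 10 | ap],
    centre = centre, polygon_area_um2 = a_poly, x_extent_um = lx,
    area_frac_target = p$area_frac_target,
    width_frac_target = p$width_frac_target)
  structure(list(sites = sites, polygon = polygon, truth = truth, preset = p),
            class = "map_sim")
}

# Solve the elliptical Gaussian scales so the noiseless >2 mV contour covers
# area_frac_target of the outline and the >10 mV contour spans
# width_frac_target of its mediolateral length.
profile_scales <- function(p, a_poly, lx) {
  a0 <- p$amp_max_mv
  if (a0 <= 2) return(list(sx = NA_real_, sy = NA_real_, a0 = 0))
  if (a0 <= 10) {
    # no strong contour exists; circular profile from the area target alone
    r2 <- sqrt(p$area_frac_target * a_poly / pi)
    s <- r2 / sqrt(2 * log(a0 / 2))
    return(list(sx = s, sy = s, a0 = a0))
  }
  a10 <- p$width_frac_target * lx / 2
  sx <- a10 / sqrt(2 * log(a0 / 10))
  a2 <- sx * sqrt(2 * log(a0 / 2))
  b2 <- p$area_frac_target * a_poly / (pi * a2)
  sy <- b2 / sqrt(2 * log(a0 / 2))
  list(sx = sx, sy = sy, a0 = a0)
}

profile_amplitude <- function(prof, p, dx, dy) {
  if (prof$a0 <= 0) return(rep(0, length(dx)))
  prof$a0 * exp(-0.5 * ((dx / prof$sx)^2 + (dy / prof$sy)^2))
}

#' @export
print.map_sim <- function(x, ...) {
  cat(sprintf("<map_sim> %s: %d sites, %d noiseless-responsive\n",
              x$preset$label, nrow(x$sites), length(x$truth$responsive_ids)))
  invisible(x)
}
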