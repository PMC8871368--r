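#' Load the calibrated generator presets
#'
#' Presets are generative parameter sets for the synthetic-data generators,
#' one per phenotype (wildtype `wt`, conditional knockout `cko`) and modality.
#' They are stored as a versioned YAML file inside the package and were
#' calibrated once, by simulation, so that the analysis pipeline's outputs
#' reproduce the group statistics each preset emulates.
#'
#' @param file Path to a presets YAML file; defaults to the file shipped with
#'   the package.
#' @return A nested named list with elements `spikes`, `imaging`, `fra`,
#'   `maps`.
#' @export
prehear_presets <- function(file = NULL) {
  file <- file %||% system.file("extdata", "presets.yaml", package = "prehear")
  abort_if(!nzchar(file) || !file.exists(file), "presets file not found")
  yaml::read_yaml(file)
}

apply_overrides <- function(preset, overrides) {
  for (nm in names(overrides)) preset[[nm]] <- overrides[[nm]]
  preset
}

#' Retrieve one preset, optionally overriding fields
#'
#' @param genotype `"wt"` or `"cko"` (for imaging, one of `"wt_ca"`,
#'   `"cko_ca"`, `"wt_dic"`, `"cko_dic"`).
#' @param ... Named field overrides.
#' @param presets Preset list from [prehear_presets()].
#' @return A named list of generator parameters.
#' @export
spike_preset <- function(genotype = c("wt", "cko"), ...,
                         presets = prehear_presets()) {
  genotype <- match.arg(genotype)
  p <- apply_overrides(presets$spikes[[genotype]], list(...))
  validate_spike_preset(p)
  p
}

#' @rdname spike_preset
#' @export
imaging_preset <- function(genotype = c("wt_ca", "cko_ca", "wt_dic", "cko_dic"),
                           ..., presets = prehear_presets()) {
  genotype <- match.arg(genotype)
  p <- apply_overrides(presets$imaging[[genotype]], list(...))
  validate_imaging_preset(p)
  p
}

#' @rdname spike_preset
#' @export
fra_preset <- function(genotype = c("wt", "cko"), ...,
                       presets = prehear_presets()) {
  genotype <- match.arg(genotype)
  apply_overrides(presets$fra[[genotype]], list(...))
}

#' @rdname spike_preset
#' @export
map_preset <- function(genotype = c("wt", "cko"), ...,
                       presets = prehear_presets()) {
  genotype <- match.arg(genotype)
  p <- apply_overrides(presets$maps[[genotype]], list(...))
  abort_if(p$grid_spacing_um <= 0, "grid spacing must be positive")
  p
}

validate_spike_preset <- function(p) {
  abort_if(p$duration_s <= 0, "preset duration must be positive")
  abort_if(p$background_rate_hz < 0, "preset rates must be non-negative")
  vals <- unlist(p$bursts_per_100s_values)
  probs <- unlist(p$bursts_per_100s_probs)
  abort_if(any(vals < 0), "preset rates must be non-negative")
  abort_if(length(vals) != length(probs) || abs(sum(probs) - 1) > 1e-8,
           "burst count probabilities must match the values and sum to 1")
  abort_if(any(unlist(p$onset_first_isi_s) <= 0), "onset ISIs must be positive")
  invisible(p)
}

validate_imaging_preset <- function(p) {
  abort_if(p$event_rate_hz < 0 || p$event_amplitude < 0 ||
             p$event_area_mean_um2 < 0,
           "imaging preset rates, amplitudes and areas must be non-negative")
  abort_if(p$n_frames < 20, "imaging preset needs at least 20 frames")
  field_um <- rev(unlist(p$field_px)) * p$pixel_size_um  # cols, rows -> x, y
  band <- unlist(p$band_rows_um)
  abort_if(band[1] < 0 || band[2] > field_um[2] || band[2] <= band[1],
           "field too small to contain the band geometry")
  invisible(p)
}
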