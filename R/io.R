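# Readers and writers for the plain-text and TIFF interchange formats.

#' Read and write spike tables
#'
#' Spike tables are CSV files with columns `unit_id,time_s`; times are
#' validated as strictly increasing per unit on read.
#'
#' @param spikes Tibble `unit_id`, `time_s`.
#' @param path File path.
#' @return `read_spike_csv` returns a validated tibble.
#' @export
write_spike_csv <- function(spikes, path) {
  readr::write_csv(as_spike_table(spikes), path)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  as_spike_table(readr::read_csv(path, show_col_types = FALSE,
                                 col_types = "cd"))
}

#' Read and write imaging stacks as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 16-bit multi-page TIFF; calibration metadata
#' (`pixel_size_um`, `frame_interval_s`, `modality`) lives in a JSON sidecar
#' next to the TIFF.
#'
#' @param stack A `prehear_stack` with integer intensities in 0..65535.
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @return `read_stack_tiff` returns a `prehear_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack$frames)[3]),
                   function(i) stack$frames[, , i] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size_um,
                            frame_interval_s = stack$frame_interval_s,
                            modality = stack$modality),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  arr <- array(0, c(dim(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- round(frames[[i]] * 65535)
  new_stack(arr, meta$pixel_size_um, meta$frame_interval_s, meta$modality)
}

#' Read and write FRA matrices
#'
#' CSV layout: header row holds the stimulus frequencies in kHz, the first
#' column (`level_db`) the levels in dB SPL, cells the spike counts.
#'
#' @param fra A `prehear_fra`.
#' @param path File path.
#' @param reps,window_s Acquisition metadata needed to recover rates on
#'   read.
#' @return `read_fra_csv` returns a `prehear_fra`.
#' @export
write_fra_csv <- function(fra, path) {
  df <- tibble::as_tibble(fra$counts, .name_repair = ~ as.character(fra$freqs_khz))
  df <- dplyr::mutate(df, level_db = fra$levels_db, .before = 1)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_fra_csv
#' @export
read_fra_csv <- function(path, reps = 1, window_s = 0.05) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  levels <- df$level_db
  freqs <- as.numeric(names(df)[-1])
  new_fra(as.matrix(df[, -1]), freqs, levels, reps, window_s)
}

#' Read and write uncaging maps
#'
#' Sites as CSV `site_id,x_um,y_um,amplitude_mv,ap_flag`; the outline
#' polygon as a second CSV `x_um,y_um`.
#'
#' @param sites,polygon Tibbles as produced by [simulate_input_map()].
#' @param sites_path,polygon_path File paths.
#' @return `read_map_csv` returns a list with `sites` and `polygon`.
#' @export
write_map_csv <- function(sites, polygon, sites_path, polygon_path) {
  readr::write_csv(sites, sites_path)
  readr::write_csv(polygon, polygon_path)
  invisible(c(sites_path, polygon_path))
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(sites_path, polygon_path) {
  list(sites = readr::read_csv(sites_path, show_col_types = FALSE),
       polygon = readr::read_csv(polygon_path, show_col_types = FALSE))
}
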