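#' Default cohort sizes
#'
#' Mirrors the group sizes of the emulated study: 14 WT / 15 cKO spike-train
#' units, 14/16 Ca2+ and 7/9 DIC imaging stacks, 25/32 FRA units and 10/10
#' uncaging maps.
#'
#' @return Named list of per-modality `c(wt = ..., cko = ...)` sizes.
#' @export
default_cohorts <- function() {
  list(spikes = c(wt = 14, cko = 15),
       imaging_ca = c(wt = 14, cko = 16),
       imaging_dic = c(wt = 7, cko = 9),
       fra = c(wt = 25, cko = 32),
       maps = c(wt = 10, cko = 10))
}

#' Pooled burst statistics of a cohort
#'
#' Per-unit statistics (CV, overall rate, bursts per 100 s) are summarised
#' across units; per-burst statistics (spikes per burst, duration, within-
#' burst rate) are pooled over all bursts of the cohort, matching how group
#' medians are reported for burst-firing data.
#'
#' @param x A `prehear_bursts` object.
#' @return One-row tibble of cohort-level statistics.
#' @export
pooled_burst_summary <- function(x) {
  stopifnot(inherits(x, "prehear_bursts"))
  tibble::tibble(
    n_units = nrow(x$units),
    n_bursts = nrow(x$bursts),
    median_cv = stats::median(x$units$cv),
    mean_rate_hz = mean(x$units$rate_hz),
    median_bursts_per_100s = stats::median(x$units$bursts_per_100s),
    median_spikes_per_burst = stats::median(x$bursts$n_spikes),
    median_burst_duration_s = stats::median(x$bursts$duration_s),
    median_within_burst_rate_hz = stats::median(x$bursts$rate_hz))
}

#' Generate and analyse an imaging cohort
#'
#' Stacks are generated one at a time from derived substream seeds, run
#' through the detection chain and discarded, keeping memory flat.
#'
#' @param preset Imaging preset.
#' @param n_stacks Number of stacks.
#' @param seed Root seed; stack `i` uses `substream_seed(seed, i)`.
#' @param config A [detection_config()].
#' @return Tibble with one row per stack: `stack`, `n_events`,
#'   `event_frequency_hz`, `mean_event_area_um2`, `duration_s`.
#' @export
analyze_imaging_cohort <- function(preset, n_stacks, seed,
                                   config = detection_config()) {
  purrr::map_dfr(seq_len(n_stacks), function(i) {
    sim <- simulate_imaging_stack(preset, substream_seed(seed, i))
    res <- analyze_stack(if (preset$modality == "dic") sim$stack else sim,
                         config)
    dplyr::mutate(res$summary, stack = i, .before = 1)
  })
}

#' Generate and analyse a spike-train cohort
#'
#' @param preset Spike preset.
#' @param n_units Number of units.
#' @param seed Root seed.
#' @param alpha,k_min Burst-detector settings, see [detect_bursts()].
#' @return List with the generated `cohort`, the `bursts` object, per-unit
#'   `metrics` and the `pooled` one-row summary.
#' @export
analyze_spike_cohort <- function(preset, n_units, seed, alpha = 0.01,
                                 k_min = 10) {
  cohort <- simulate_spike_trains(preset, n_units, seed)
  bursts <- detect_bursts(cohort$spikes, cohort$duration, alpha, k_min)
  list(cohort = cohort, bursts = bursts, metrics = burst_metrics(bursts),
       pooled = pooled_burst_summary(bursts))
}

#' Generate and analyse an FRA cohort
#'
#' @param preset FRA preset.
#' @param n_units Number of units.
#' @param seed Root seed.
#' @param c_sd Significance criterion in spontaneous SDs. The cohort default
#'   (4) is stricter than the single-FRA default (3): with one Poisson count
#'   per bin a 3-SD criterion admits a fraction of a false-significant
#'   sub-threshold bin per FRA, enough to corrupt threshold and CF.
#' @return Tibble with one row of tuning metrics per unit plus the
#'   generator's ground-truth CF and Q10.
#' @export
analyze_fra_cohort <- function(preset, n_units, seed, c_sd = 4) {
  purrr::map_dfr(seq_len(n_units), function(i) {
    sim <- simulate_fra(preset, substream_seed(seed, i))
    m <- fra_metrics(sim$fra, c_sd = c_sd)
    dplyr::mutate(m, unit = i, true_cf_khz = sim$truth$cf_khz,
                  true_q10 = sim$truth$q10, .before = 1)
  })
}

#' Generate and analyse an uncaging-map cohort
#'
#' @param preset Map preset.
#' @param n_maps Number of maps.
#' @param seed Root seed.
#' @return Tibble with one row of input-map metrics per map.
#' @export
analyze_map_cohort <- function(preset, n_maps, seed) {
  purrr::map_dfr(seq_len(n_maps), function(i) {
    sim <- simulate_input_map(preset, substream_seed(seed, i))
    dplyr::mutate(input_map_metrics(classify_sites(sim$sites), sim$polygon,
                                    sim$preset$grid_spacing_um^2),
                  map = i, .before = 1)
  })
}

report_config <- function() {
  tibble::tribble(
    ~metric,                        ~test,    ~style,       ~paired,
    "cv",                           "wilcox", "median_iqr", FALSE,
    "bursts_per_100s",              "wilcox", "median_iqr", FALSE,
    "spikes_per_burst",             "wilcox", "median_iqr", FALSE,
    "burst_duration_s",             "wilcox", "median_iqr", FALSE,
    "within_burst_rate_hz",         "wilcox", "median_iqr", FALSE,
    "mean_rate_hz",                 "t",      "mean_sem",   FALSE,
    "ca_event_area_um2",            "t",      "mean_sem",   FALSE,
    "ca_event_frequency_hz",        "t",      "mean_sem",   FALSE,
    "dic_event_area_um2",           "t",      "mean_sem",   FALSE,
    "dic_event_frequency_hz",       "t",      "mean_sem",   FALSE,
    "q10",                          "wilcox", "median_iqr", FALSE,
    "q20",                          "wilcox", "median_iqr", FALSE,
    "q30",                          "wilcox", "median_iqr", FALSE,
    "cf_threshold_db",              "wilcox", "median_iqr", FALSE,
    "max_rate_hz",                  "t",      "mean_sem",   FALSE,
    "input_area_pct",               "t",      "mean_sem",   FALSE,
    "input_width_pct",              "t",      "mean_sem",   FALSE)
}

#' Run the full synthetic pipeline
#'
#' Generates WT and cKO cohorts for every requested modality, runs the four
#' analyses, compares genotypes and assembles the report table. Each
#' modality is wrapped so a failure aborts that modality only and is
#' recorded in the run log.
#'
#' @param seed Root seed; all randomness derives from it.
#' @param cohorts Cohort sizes, see [default_cohorts()].
#' @param presets Preset list, see [prehear_presets()].
#' @param config Imaging [detection_config()].
#' @param modalities Subset of `c("spikes", "imaging", "fra", "maps")`.
#' @param out_dir Optional directory; when given, the metric table, report
#'   and run log are written there.
#' @return An object of class `prehear_run`: list with `metrics` (long
#'   tibble `modality`, `metric`, `group`, `unit`, `value`), `report`,
#'   `log`, `pooled` (per-genotype pooled burst summaries) and `seed`.
#' @export
run_pipeline <- function(seed, cohorts = default_cohorts(),
                         presets = prehear_presets(),
                         config = detection_config(),
                         modalities = c("spikes", "imaging", "fra", "maps"),
                         out_dir = NULL) {
  metrics <- list()
  log <- list()
  pooled <- list()
  note <- function(modality, status, message = "") {
    log[[length(log) + 1]] <<- tibble::tibble(
      modality = modality, status = status, message = message)
  }
  add_metrics <- function(modality, df) {
    metrics[[length(metrics) + 1]] <<- dplyr::mutate(df, modality = modality,
                                                     .before = 1)
  }
  long <- function(df, id, cols) {
    tidyr::pivot_longer(df[, c(id, cols)], dplyr::all_of(cols),
                        names_to = "metric", values_to = "value") |>
      dplyr::rename(unit = dplyr::all_of(id))
  }

  if ("spikes" %in% modalities) {
    tryCatch({
      for (g in c("wt", "cko")) {
        res <- analyze_spike_cohort(spike_preset(g, presets = presets),
                                    cohorts$spikes[[g]],
                                    substream_seed(seed, match(g, c("wt", "cko"))))
        pooled[[g]] <- res$pooled
        per_unit <- res$metrics |>
          dplyr::transmute(unit = .data$unit_id, cv = .data$cv,
                           bursts_per_100s = .data$bursts_per_100s,
                           mean_rate_hz = .data$rate_hz)
        per_burst <- res$bursts$bursts |>
          dplyr::transmute(unit = .data$unit_id,
                           spikes_per_burst = as.numeric(.data$n_spikes),
                           burst_duration_s = .data$duration_s,
                           within_burst_rate_hz = .data$rate_hz)
        df <- dplyr::bind_rows(
          long(per_unit, "unit", c("cv", "bursts_per_100s", "mean_rate_hz")),
          long(per_burst, "unit", c("spikes_per_burst", "burst_duration_s",
                                    "within_burst_rate_hz")))
        add_metrics("spikes", dplyr::mutate(df, group = g))
      }
      note("spikes", "ok")
    }, error = function(e) note("spikes", "failed", conditionMessage(e)))
  }

  if ("imaging" %in% modalities) {
    tryCatch({
      specs <- list(
        list(key = "imaging_ca", prefix = "ca", wt = "wt_ca", cko = "cko_ca",
             offset = 10),
        list(key = "imaging_dic", prefix = "dic", wt = "wt_dic",
             cko = "cko_dic", offset = 20))
      for (s in specs) {
        for (g in c("wt", "cko")) {
          co <- analyze_imaging_cohort(
            imaging_preset(s[[g]], presets = presets),
            cohorts[[s$key]][[g]],
            substream_seed(seed, s$offset + match(g, c("wt", "cko"))), config)
          df <- co |>
            dplyr::transmute(unit = as.character(.data$stack),
                             area = .data$mean_event_area_um2,
                             freq = .data$event_frequency_hz) |>
            tidyr::pivot_longer(c("area", "freq"), names_to = "metric",
                                values_to = "value") |>
            dplyr::mutate(metric = paste0(
              s$prefix, "_event_",
              ifelse(.data$metric == "area", "area_um2", "frequency_hz")),
              group = g)
          add_metrics("imaging", df)
        }
      }
      note("imaging", "ok")
    }, error = function(e) note("imaging", "failed", conditionMessage(e)))
  }

  if ("fra" %in% modalities) {
    tryCatch({
      for (g in c("wt", "cko")) {
        co <- analyze_fra_cohort(fra_preset(g, presets = presets),
                                 cohorts$fra[[g]],
                                 substream_seed(seed, 30 + match(g, c("wt", "cko"))))
        df <- co |>
          dplyr::transmute(unit = as.character(.data$unit), q10 = .data$q10,
                           q20 = .data$q20, q30 = .data$q30,
                           cf_threshold_db = .data$threshold_db,
                           max_rate_hz = .data$max_rate_hz) |>
          tidyr::pivot_longer(-"unit", names_to = "metric",
                              values_to = "value") |>
          dplyr::mutate(group = g)
        add_metrics("fra", df)
      }
      note("fra", "ok")
    }, error = function(e) note("fra", "failed", conditionMessage(e)))
  }

  if ("maps" %in% modalities) {
    tryCatch({
      for (g in c("wt", "cko")) {
        co <- analyze_map_cohort(map_preset(g, presets = presets),
                                 cohorts$maps[[g]],
                                 substream_seed(seed, 40 + match(g, c("wt", "cko"))))
        df <- co |>
          dplyr::transmute(unit = as.character(.data$map),
                           input_area_pct = .data$input_area_pct,
                           input_width_pct = .data$input_width_pct) |>
          tidyr::pivot_longer(-"unit", names_to = "metric",
                              values_to = "value") |>
          dplyr::mutate(group = g)
        add_metrics("maps", df)
      }
      note("maps", "ok")
    }, error = function(e) note("maps", "failed", conditionMessage(e)))
  }

  metrics <- if (length(metrics)) dplyr::bind_rows(metrics) else
    tibble::tibble(modality = character(), unit = character(),
                   metric = character(), value = numeric(),
                   group = character())
  report <- build_report(metrics, report_config())
  out <- structure(list(metrics = metrics, report = report,
                        log = dplyr::bind_rows(log), pooled = pooled,
                        seed = seed),
                   class = "prehear_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(out$log, file.path(out_dir, "run_log.csv"))
    write_report(report, out_dir)
  }
  out
}

#' @export
print.prehear_run <- function(x, ...) {
  cat(sprintf("<prehear_run> seed %d: %d metric values, %d report rows\n",
              x$seed, nrow(x$metrics), nrow(x$report)))
  print(x$log)
  invisible(x)
}
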