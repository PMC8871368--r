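#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a burst-detection result
#'
#' @param x A `prehear_bursts` object.
#' @param ... Unused.
#' @return The burst table, one row per detected burst.
#' @export
tidy.prehear_bursts <- function(x, ...) {
  x$bursts
}

#' Cohort-level summary of a burst-detection result
#'
#' @param x A `prehear_bursts` object.
#' @param ... Unused.
#' @return One-row tibble, see [pooled_burst_summary()].
#' @export
glance.prehear_bursts <- function(x, ...) {
  pooled_burst_summary(x)
}

#' Tidy a pipeline run
#'
#' @param x A `prehear_run` object.
#' @param ... Unused.
#' @return The report table (one row per metric).
#' @export
tidy.prehear_run <- function(x, ...) {
  x$report
}

#' One-line summary of a pipeline run
#'
#' @param x A `prehear_run` object.
#' @param ... Unused.
#' @return One-row tibble: seed, modality counts, significant comparisons.
#' @export
glance.prehear_run <- function(x, ...) {
  tibble::tibble(
    seed = x$seed,
    n_modalities_ok = sum(x$log$status == "ok"),
    n_modalities_failed = sum(x$log$status == "failed"),
    n_metrics = length(unique(x$metrics$metric)),
    n_significant = sum(x$report$p_value < 0.05, na.rm = TRUE))
}
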