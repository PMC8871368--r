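#' Summarise a metric vector
#'
#' Normally distributed metrics are reported as mean ± standard error of the
#' mean (sample SD / sqrt(n)); others as median with 25% and 75% quartiles
#' (linear interpolation).
#'
#' @param values Numeric vector (NAs dropped).
#' @param style `"mean_sem"` or `"median_iqr"`.
#' @return One-row tibble: `n`, `mean`, `sem`, `median`, `q25`, `q75`,
#'   `style`, and a formatted `label`.
#' @export
group_summary <- function(values, style = c("mean_sem", "median_iqr")) {
  style <- match.arg(style)
  values <- values[!is.na(values)]
  abort_if(!length(values), "cannot summarise an empty vector")
  m <- mean(values)
  sem <- if (length(values) > 1) stats::sd(values) / sqrt(length(values)) else 0
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  label <- if (style == "mean_sem") {
    sprintf("%.3g ± %.3g", m, sem)
  } else {
    sprintf("%.3g [%.3g, %.3g]", q[2], q[1], q[3])
  }
  tibble::tibble(n = length(values), mean = m, sem = sem,
                 median = q[2], q25 = q[1], q75 = q[3],
                 style = style, label = label)
}

#' Compare a metric between two groups
#'
#' A thin, explicit wrapper over the standard tests: unpaired or paired
#' two-tailed Student's t, Mann-Whitney rank-sum (`wilcox`), two-sample
#' Kolmogorov-Smirnov. The test is chosen per metric by configuration, not by
#' automated normality screening, so that report tables are reproducible.
#'
#' @param a,b Numeric vectors.
#' @param test `"t"`, `"wilcox"`, `"ks"`.
#' @param paired Paired design (t test only; requires matched order and equal
#'   length).
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
group_compare <- function(a, b, test = c("wilcox", "t", "ks"), paired = FALSE) {
  test <- match.arg(test)
  abort_if(paired && (test != "t" || length(a) != length(b)),
           "paired comparisons require the t test with equal n")
  abort_if(length(a) < 2 || length(b) < 2, "each group needs n >= 2")
  res <- switch(test,
    t = {
      if (paired && all(a - b == 0)) {
        list(statistic = NA_real_, p.value = 1)  # no effect, not an error
      } else {
        tryCatch(stats::t.test(a, b, paired = paired),
                 error = function(e) {
                   # essentially constant data: no testable difference
                   list(statistic = NA_real_,
                        p.value = if (isTRUE(all.equal(mean(a), mean(b)))) 1
                                  else NA_real_)
                 })
      }
    },
    wilcox = suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)),
    ks = suppressWarnings(stats::ks.test(a, b)))
  tibble::tibble(test = if (paired) "paired_t" else test,
                 statistic = unname(res$statistic %||% NA_real_),
                 p_value = res$p.value, n_a = length(a), n_b = length(b))
}

significance_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "ns")
}

#' Build a group-comparison report table
#'
#' Takes a long metric table and produces one row per metric with the two
#' group summaries, the configured test and significance stars
#' (p < 0.05 *, < 0.01 **, < 0.001 ***).
#'
#' @param metrics Tibble with columns `metric`, `group`, `value`.
#' @param config Optional tibble with columns `metric`, `test`
#'   (wilcox/t/ks), `style` (mean_sem/median_iqr), `paired`; metrics missing
#'   from it default to Mann-Whitney + median/IQR.
#' @return Tibble with one row per metric.
#' @export
build_report <- function(metrics, config = NULL) {
  abort_if(!all(c("metric", "group", "value") %in% names(metrics)),
           "`metrics` needs columns metric, group, value")
  if (!nrow(metrics)) {
    return(tibble::tibble(metric = character(), group_a = character(),
                          group_b = character(), summary_a = character(),
                          summary_b = character(), test = character(),
                          statistic = numeric(), p_value = numeric(),
                          stars = character()))
  }
  purrr::map_dfr(unique(metrics$metric), function(mname) {
    cfg <- if (!is.null(config) && mname %in% config$metric) {
      config[config$metric == mname, ]
    } else {
      tibble::tibble(test = "wilcox", style = "median_iqr", paired = FALSE)
    }
    d <- metrics[metrics$metric == mname & !is.na(metrics$value), ]
    groups <- sort(unique(d$group))
    a <- d$value[d$group == groups[1]]
    b <- if (length(groups) > 1) d$value[d$group == groups[2]] else numeric(0)
    cmp <- if (length(a) >= 2 && length(b) >= 2) {
      group_compare(a, b, cfg$test, cfg$paired)
    } else {
      tibble::tibble(test = "not_applicable", statistic = NA_real_,
                     p_value = NA_real_, n_a = length(a), n_b = length(b))
    }
    tibble::tibble(
      metric = mname,
      group_a = groups[1],
      group_b = if (length(groups) > 1) groups[2] else NA_character_,
      summary_a = group_summary(a, cfg$style)$label,
      summary_b = if (length(b)) group_summary(b, cfg$style)$label else NA_character_,
      test = cmp$test, statistic = cmp$statistic, p_value = cmp$p_value,
      stars = significance_stars(cmp$p_value))
  })
}

#' Write a report as CSV and markdown
#'
#' @param report Tibble from [build_report()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "report.csv")
  md <- file.path(dir, "report.md")
  readr::write_csv(report, csv)
  lines <- c("| metric | group A | group B | test | p | |",
             "|---|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %s | %.2g | %s |",
                     report$metric, report$summary_a, report$summary_b,
                     report$test, report$p_value, report$stars))
  writeLines(lines, md)
  invisible(c(csv, md))
}
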