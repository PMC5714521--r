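#' Box-whisker cohort summary
#'
#' Five-number summary in the box-whisker convention used for cohort
#' reporting: Q1/Q3 as the 25th/75th percentiles (linear interpolation
#' between order statistics), outliers as values beyond 1.5 IQR from the
#' quartiles, whiskers as the minimum and maximum of the remaining values,
#' and the 95% median-notch half-width `delta = 1.57 * IQR / sqrt(n)`
#' (McGill's rule): two groups whose notches do not overlap have medians
#' that differ at roughly the 5% level.
#'
#' @param values numeric vector, `n >= 1`; NAs are dropped.
#' @return list of class `"cohort_summary"`: minimum, q1, median, q3,
#'   maximum (whiskers after outlier removal), `delta`, `outliers`, `n`.
#' @examples
#' s <- summarize(1:9)
#' c(s$q1, s$median, s$q3)  # 3 5 7
#' @export
summarize <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1) stop("summarize needs at least one value", call. = FALSE)
  q <- as.numeric(quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  iqr <- q[3] - q[1]
  fences <- c(q[1] - 1.5 * iqr, q[3] + 1.5 * iqr)
  out <- values[values < fences[1] | values > fences[2]]
  kept <- values[values >= fences[1] & values <= fences[2]]
  structure(list(minimum = min(kept), q1 = q[1], median = q[2], q3 = q[3],
                 maximum = max(kept),
                 delta = 1.57 * iqr / sqrt(length(values)),
                 outliers = out, n = length(values)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("min %.3g | Q1 %.3g | median %.3g +/- %.3g | Q3 %.3g | max %.3g (n=%d, %d outliers)\n",
              x$minimum, x$q1, x$median, x$delta, x$q3, x$maximum, x$n,
              length(x$outliers)))
  invisible(x)
}

#' Cohort table of registration metrics
#'
#' One [summarize()] row per region and metric, in the reporting column
#' order Minimum / 1st Quartile / Median and its notch half-width Delta /
#' 3rd Quartile / Maximum.  Cases where a metric is undefined (e.g. a
#' region missing from one modality) are excluded from that row with a
#' correspondingly reduced `n`.
#'
#' @param records data.frame of per-case records as produced by
#'   [evaluate_case()] (rows stacked over cases), with a `region` column.
#' @param metrics metric columns to report.
#' @return data.frame of class `"cohort_table"` with columns region,
#'   metric, minimum, q1, median, delta, q3, maximum, n, n_outliers.
#'   Attribute `"percentile_convention"` records the quartile definition.
#' @export
cohort_table <- function(records,
                         metrics = c("TO", "DC", "JC", "FN", "FP", "VS",
                                     "HD_mm", "DE_mm")) {
  stopifnot(is.data.frame(records), "region" %in% names(records))
  metrics <- intersect(metrics, names(records))
  if (!length(metrics)) stop("no metric columns found", call. = FALSE)
  rows <- list()
  for (rg in unique(records$region)) {
    sub <- records[records$region == rg, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      s <- summarize(v)
      rows[[length(rows) + 1L]] <-
        data.frame(region = rg, metric = m, minimum = s$minimum, q1 = s$q1,
                   median = s$median, delta = s$delta, q3 = s$q3,
                   maximum = s$maximum, n = s$n,
                   n_outliers = length(s$outliers))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "percentile_convention") <-
    "quartiles: linear interpolation between order statistics (type 7)"
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort summary (Minimum / Q1 / Median+/-Delta / Q3 / Maximum):\n")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Landmark cohort table
#'
#' [summarize()] applied per landmark name over cases: the grouped
#' registration-error presentation for a landmark roster.
#'
#' @param landmark_records stacked `landmarks` data.frames from
#'   [evaluate_case()] (columns `name`, `error_mm`).
#' @return data.frame, one row per landmark.
#' @export
landmark_cohort_table <- function(landmark_records) {
  stopifnot(all(c("name", "error_mm") %in% names(landmark_records)))
  rows <- lapply(split(landmark_records$error_mm, landmark_records$name),
                 function(v) {
                   s <- summarize(v[!is.na(v)])
                   data.frame(minimum = s$minimum, q1 = s$q1, median = s$median,
                              delta = s$delta, q3 = s$q3, maximum = s$maximum,
                              n = s$n)
                 })
  out <- do.call(rbind, rows)
  out <- data.frame(name = names(rows), out)
  rownames(out) <- NULL
  out[match(unique(landmark_records$name), out$name), , drop = FALSE]
}

#' Box-whisker plot of a cohort table (convenience)
#'
#' @param records per-case records as for [cohort_table()].
#' @param metric one metric column.
#' @param ... passed to [graphics::boxplot()].
#' @return the boxplot stats, invisibly.
#' @export
plot_cohort <- function(records, metric = "DC", ...) {
  stopifnot(metric %in% names(records))
  graphics::boxplot(records[[metric]] ~ records$region, notch = TRUE,
                    range = 1.5, xlab = "region", ylab = metric, ...)
}
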