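# XmR (individuals and moving-range) control charts.
#
# Standard individuals-chart constants: the X limits are x_bar +/- 2.66 *
# mean moving range (2.66 = 3/d2 with d2 = 1.128 for subgroups of size 2)
# and the mR upper limit is 3.267 * mean moving range (D4 for n = 2).
XMR_X_CONST <- 2.66
XMR_MR_CONST <- 3.267

#' Build an XmR (individuals / moving-range) control chart
#'
#' Computes the moving ranges `mr[i] = |x[i+1] - x[i]|`, the centre lines and
#' control limits, and the beyond-limit signal indices for a time-ordered
#' series of individual values (here typically monthly percentage measures).
#'
#' By default all points contribute to the centre line and limits
#' (`limit_window = "all_points"`). With `limit_window = "baseline"` only the
#' first `baseline_n` points (and the moving ranges within them) are used,
#' freezing a baseline for prospective monitoring; signals are still
#' evaluated over the whole series.
#'
#' Limits are deliberately not clamped to `[0, 100]` for percentage data: a
#' negative lower limit simply means no lower signal is reachable.
#'
#' @param x Numeric vector of at least 2 finite values, in time order.
#' @param labels Optional period labels (same length as `x`); defaults to
#'   `"1"`, `"2"`, ...
#' @param limit_window `"all_points"` (default) or `"baseline"`.
#' @param baseline_n Number of leading points defining the baseline when
#'   `limit_window = "baseline"` (must be in `[2, length(x)]`).
#' @param annotation Optional event marker: a list with elements `label`
#'   (text) and `period` (index or label of the period the event precedes),
#'   e.g. `list(label = "UI CHANGE", period = "2016-12")`.
#' @return An object of class `xmr_chart`: a list with `x`, `labels`,
#'   `x_bar`, `x_ucl`, `x_lcl`, `mr` (length `length(x) - 1`), `mr_bar`,
#'   `mr_ucl`, signal index vectors `x_signals` and `mr_signals` (1-based),
#'   `limit_window`, `baseline_n` and `annotation`.
#' @examples
#' chart <- build_xmr(c(10, 14, 12))
#' chart$x_ucl # 12 + 2.66 * 3 = 19.98
#' @export
build_xmr <- function(x, labels = NULL,
                      limit_window = c("all_points", "baseline"),
                      baseline_n = NULL, annotation = NULL) {
  limit_window <- rlang::arg_match(limit_window)
  x <- as.numeric(x)
  if (length(x) < 2) {
    abort_insufficient("An XmR chart needs at least 2 points")
  }
  if (any(!is.finite(x))) {
    abort_config("XmR input values must all be finite")
  }
  if (is.null(labels)) labels <- as.character(seq_along(x))
  labels <- as.character(labels)
  if (length(labels) != length(x)) {
    abort_config("`labels` must have the same length as `x`")
  }
  if (limit_window == "baseline") {
    if (is.null(baseline_n) || baseline_n < 2 || baseline_n > length(x)) {
      abort_config("`baseline_n` must be between 2 and length(x)")
    }
  } else {
    baseline_n <- length(x)
  }

  mr <- abs(diff(x))
  x_bar <- mean(x[seq_len(baseline_n)])
  mr_bar <- mean(mr[seq_len(baseline_n - 1)])
  chart <- structure(
    list(
      x = x, labels = labels,
      x_bar = x_bar,
      x_ucl = x_bar + XMR_X_CONST * mr_bar,
      x_lcl = x_bar - XMR_X_CONST * mr_bar,
      mr = mr, mr_bar = mr_bar,
      mr_ucl = XMR_MR_CONST * mr_bar,
      x_signals = integer(), mr_signals = integer(),
      limit_window = limit_window, baseline_n = baseline_n,
      annotation = annotation
    ),
    class = "xmr_chart"
  )
  sig <- detect_signals(chart)
  chart$x_signals <- sig$x_signals
  chart$mr_signals <- sig$mr_signals
  chart
}

#' Detect assignable-cause signals on an XmR chart
#'
#' A point on the X graph is a signal iff it lies strictly outside the
#' control limits (`x > x_ucl` or `x < x_lcl`); a moving-range point is a
#' signal iff it lies strictly above the mR upper limit. Values exactly on a
#' limit are treated as chance variation. Only the beyond-limits rule is
#' applied (no run/zone rules).
#'
#' @param chart An `xmr_chart` from [build_xmr()].
#' @return A list with integer index vectors `x_signals` (into `chart$x`) and
#'   `mr_signals` (into `chart$mr`), both 1-based.
#' @export
detect_signals <- function(chart) {
  stopifnot(inherits(chart, "xmr_chart"))
  list(
    x_signals = which(chart$x > chart$x_ucl | chart$x < chart$x_lcl),
    mr_signals = which(chart$mr > chart$mr_ucl)
  )
}

#' Annotate an XmR chart with an event marker
#'
#' Attaches an event label (drawn as a vertical line on plots and flagged in
#' the exported table) at a given period.
#'
#' @param chart An `xmr_chart`.
#' @param label Event text, e.g. `"UI CHANGE"`.
#' @param period Period index (integer) or period label at which the event
#'   occurred.
#' @return The chart with its `annotation` set.
#' @export
xmr_annotate <- function(chart, label, period) {
  stopifnot(inherits(chart, "xmr_chart"))
  if (is.character(period)) {
    idx <- match(period, chart$labels)
    if (is.na(idx)) abort_config(paste0("Unknown period label: ", period))
  } else {
    idx <- as.integer(period)
    if (idx < 1 || idx > length(chart$x)) {
      abort_config("Annotation period index out of range")
    }
  }
  chart$annotation <- list(label = label, period = idx)
  chart
}

#' Export an XmR chart as a table
#'
#' One row per period: label, x value, centre line and limits, moving range
#' (NA for the first period), mR limit, signal flags and annotation marker.
#' Rebuilding a chart from the exported `x` column reproduces the exported
#' limits (when limits were computed from all points).
#'
#' @param chart An `xmr_chart`.
#' @return A tibble with columns `period`, `label`, `x`, `x_bar`, `x_ucl`,
#'   `x_lcl`, `x_signal`, `mr`, `mr_bar`, `mr_ucl`, `mr_signal`,
#'   `annotation`.
#' @export
xmr_table <- function(chart) {
  stopifnot(inherits(chart, "xmr_chart"))
  n <- length(chart$x)
  ann <- rep(NA_character_, n)
  if (!is.null(chart$annotation)) {
    ann[chart$annotation$period] <- chart$annotation$label
  }
  tibble::tibble(
    period = seq_len(n),
    label = chart$labels,
    x = chart$x,
    x_bar = chart$x_bar,
    x_ucl = chart$x_ucl,
    x_lcl = chart$x_lcl,
    x_signal = seq_len(n) %in% chart$x_signals,
    mr = c(NA_real_, chart$mr),
    mr_bar = chart$mr_bar,
    mr_ucl = chart$mr_ucl,
    mr_signal = seq_len(n) %in% (chart$mr_signals + 1L),
    annotation = ann
  )
}

#' Build a monthly XmR chart from a measure series
#'
#' Convenience wrapper: takes a by-month measure series (from
#' [aggregate_measures()] with `grouping = "by_month"`), selects one of the
#' three quality measures, optionally restricts to a month range, and builds
#' the chart. If `annotation_date` is given, the chart is annotated at that
#' date's month.
#'
#' @param series A by-month measure series.
#' @param measure One of `"same_day"`, `"complete"`, `"valid"`.
#' @param from,to Optional `"YYYY-MM"` strings restricting the charted months
#'   (inclusive).
#' @param annotation_date Optional `Date`; the chart is annotated with
#'   `annotation_label` at that month.
#' @param annotation_label Text for the annotation (default `"UI CHANGE"`).
#' @inheritParams build_xmr
#' @return An `xmr_chart`.
#' @export
xmr_from_measures <- function(series, measure = c("same_day", "complete", "valid"),
                              from = NULL, to = NULL,
                              annotation_date = NULL,
                              annotation_label = "UI CHANGE",
                              limit_window = c("all_points", "baseline"),
                              baseline_n = NULL) {
  measure <- rlang::arg_match(measure)
  if (!identical(attr(series, "grouping"), "by_month") ||
      !"month" %in% names(series)) {
    abort_config("`series` must be a by-month measure series")
  }
  keep <- rep(TRUE, nrow(series))
  if (!is.null(from)) keep <- keep & series$month >= from
  if (!is.null(to)) keep <- keep & series$month <= to
  series <- series[keep, ]
  if (nrow(series) < 2) {
    abort_insufficient("Fewer than 2 monthly points available for the chart")
  }
  chart <- build_xmr(series[[paste0("pct_", measure)]], labels = series$month,
                     limit_window = limit_window, baseline_n = baseline_n)
  if (!is.null(annotation_date)) {
    month_label <- format(as.Date(annotation_date), "%Y-%m")
    if (month_label %in% chart$labels) {
      chart <- xmr_annotate(chart, annotation_label, month_label)
    }
  }
  chart
}

#' @export
print.xmr_chart <- function(x, ...) {
  cat("XmR chart (", length(x$x), " points, limits from ",
      if (x$limit_window == "all_points") "all points"
      else paste0("first ", x$baseline_n, " points"), ")\n", sep = "")
  cat(sprintf("  X : centre %.3f, limits [%.3f, %.3f], %d signal(s)\n",
              x$x_bar, x$x_lcl, x$x_ucl, length(x$x_signals)))
  cat(sprintf("  mR: centre %.3f, upper limit %.3f, %d signal(s)\n",
              x$mr_bar, x$mr_ucl, length(x$mr_signals)))
  if (length(x$x_signals) > 0) {
    cat("  X signals at: ",
        paste(x$labels[x$x_signals], collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$annotation)) {
    cat("  annotation: '", x$annotation$label, "' at ",
        x$labels[x$annotation$period], "\n", sep = "")
  }
  invisible(x)
}
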