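# Paired pre-post comparison of per-user measures: paired t test, Cohen's d
# on the paired differences, and the normal-approximation power
# Phi(|d| sqrt(n) - z_{1 - alpha/2}).

#' Paired t test on per-user differences
#'
#' Computes `t = mean(diffs) / (sd(diffs) / sqrt(n))` (sample sd, `n - 1`
#' denominator) and the two-sided p value from the t distribution with
#' `n - 1` degrees of freedom.
#'
#' @param diffs Numeric vector of paired differences (post minus pre), one
#'   per user; at least 2 values.
#' @return A list with `t_stat`, `p_value`, `df`.
#' @export
paired_t <- function(diffs) {
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 2) abort_insufficient("Paired t test needs at least 2 differences")
  s <- stats::sd(diffs)
  if (!is.finite(s) || s == 0) {
    abort_config("Degenerate paired differences: zero variance")
  }
  t_stat <- mean(diffs) / (s / sqrt(n))
  list(
    t_stat = t_stat,
    p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
    df = n - 1L
  )
}

#' Cohen's d for paired differences
#'
#' The standardised paired difference `mean(diffs) / sd(diffs)` (sample sd).
#' Relates to the paired t statistic by `t = d * sqrt(n)`.
#'
#' @inheritParams paired_t
#' @return A single numeric value.
#' @export
cohen_d_paired <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2) {
    abort_insufficient("Cohen's d needs at least 2 differences")
  }
  s <- stats::sd(diffs)
  if (!is.finite(s) || s == 0) {
    abort_config("Degenerate paired differences: zero variance")
  }
  mean(diffs) / s
}

#' Post hoc power for a paired comparison
#'
#' Default method is the normal approximation
#' `Phi(|d| * sqrt(n) - z_{1 - alpha/2})`, the large-sample power of the
#' two-sided paired test at the observed standardised effect. At `d = 0` it
#' equals `alpha / 2`. A noncentral-t computation
#' (`P(|T| > t_crit)` with noncentrality `|d| * sqrt(n)` and `n - 1` df) is
#' available via `method = "noncentral_t"`.
#'
#' @param d Standardised paired effect size (Cohen's d).
#' @param n Number of pairs (at least 2).
#' @param alpha Two-sided significance level, in (0, 1). Default 0.05.
#' @param method `"normal"` (default) or `"noncentral_t"`.
#' @return Power as a probability in `[0, 1]`; vectorised over `d`.
#' @examples
#' power_paired(0.632, 53) # 0.996
#' @export
power_paired <- function(d, n, alpha = 0.05, method = c("normal", "noncentral_t")) {
  method <- rlang::arg_match(method)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort_config("`alpha` must be a single probability strictly inside (0, 1)")
  }
  if (n < 2) abort_config("`n` must be at least 2")
  ncp <- abs(d) * sqrt(n)
  if (method == "normal") {
    stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
  } else {
    tc <- stats::qt(1 - alpha / 2, df = n - 1)
    1 - stats::pt(tc, df = n - 1, ncp = ncp) +
      stats::pt(-tc, df = n - 1, ncp = ncp)
  }
}

new_prepost_result <- function(measure_name, diffs, mean_pre, mean_post,
                               alpha, n_excluded, power_method) {
  tt <- paired_t(diffs)
  d <- cohen_d_paired(diffs)
  out <- tibble::tibble(
    measure = measure_name,
    n_pairs = length(diffs),
    n_excluded = n_excluded,
    mean_pre = mean_pre,
    mean_post = mean_post,
    mean_change = mean(diffs),
    t_stat = tt$t_stat,
    p_value = tt$p_value,
    cohen_d = d,
    power = power_paired(d, length(diffs), alpha, method = power_method),
    alpha = alpha
  )
  class(out) <- c("prepost_result", class(out))
  out
}

#' Paired pre-post comparison of a quality measure
#'
#' Takes a by-user-and-window measure series (from [aggregate_measures()]
#' with `grouping = "by_user_and_window"`), pairs each user's pre and post
#' percentages, and summarises the paired differences (post minus pre) with
#' a paired t test, Cohen's d and post hoc power at the observed |d|. Users
#' lacking records in either window are excluded and counted.
#'
#' @param series A by-user-and-window measure series.
#' @param measure One of `"same_day"`, `"complete"`, `"valid"`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power_method Passed to [power_paired()].
#' @return A one-row tibble of class `prepost_result`: `measure`, `n_pairs`,
#'   `n_excluded`, `mean_pre`, `mean_post`, `mean_change` (percentage
#'   points), `t_stat`, `p_value`, `cohen_d`, `power`, `alpha`.
#' @export
compare_prepost <- function(series, measure = c("same_day", "complete", "valid"),
                            alpha = 0.05,
                            power_method = c("normal", "noncentral_t")) {
  measure <- rlang::arg_match(measure)
  power_method <- rlang::arg_match(power_method)
  if (!identical(attr(series, "grouping"), "by_user_and_window") ||
      !all(c("user_id", "window") %in% names(series))) {
    abort_config("`series` must use by_user_and_window grouping")
  }
  col <- paste0("pct_", measure)
  wide <- split(series, series$window)
  pre <- wide$pre
  post <- wide$post
  paired_ids <- intersect(pre$user_id, post$user_id)
  n_excluded <- length(union(pre$user_id, post$user_id)) - length(paired_ids)
  if (length(paired_ids) < 2) {
    abort_insufficient("Fewer than 2 users have records in both windows")
  }
  pre_vals <- pre[[col]][match(paired_ids, pre$user_id)]
  post_vals <- post[[col]][match(paired_ids, post$user_id)]
  new_prepost_result(
    measure_name = measure, diffs = post_vals - pre_vals,
    mean_pre = mean(pre_vals), mean_post = mean(post_vals),
    alpha = alpha, n_excluded = n_excluded, power_method = power_method
  )
}

#' Paired pre-post comparison of entry volume
#'
#' Compares the number of encounter entries per user between the 8-week pre
#' and post windows (records assigned to windows by appointment date, as for
#' the quality measures). Used to check that pre and post periods are
#' similar in visit volume before interpreting measure changes.
#'
#' @param records An encounter tibble.
#' @param intervention_date Date of the intervention.
#' @inheritParams compare_prepost
#' @return A one-row `prepost_result` tibble (units: entries per user per
#'   8-week window).
#' @export
compare_volume <- function(records, intervention_date, alpha = 0.05,
                           power_method = c("normal", "noncentral_t")) {
  power_method <- rlang::arg_match(power_method)
  intervention_date <- as.Date(intervention_date)
  window <- assign_window(records$appointment_date, intervention_date)
  dat <- tibble::tibble(user_id = records$user_id, window = window)
  dat <- dat[!is.na(dat$window), ]
  counts <- dplyr::summarise(
    dplyr::group_by(dat, .data$user_id, .data$window),
    n = dplyr::n(), .groups = "drop"
  )
  wide <- split(counts, counts$window)
  paired_ids <- intersect(wide$pre$user_id, wide$post$user_id)
  n_excluded <- length(union(wide$pre$user_id, wide$post$user_id)) -
    length(paired_ids)
  if (length(paired_ids) < 2) {
    abort_insufficient("Fewer than 2 users have entries in both windows")
  }
  pre_vals <- wide$pre$n[match(paired_ids, wide$pre$user_id)]
  post_vals <- wide$post$n[match(paired_ids, wide$post$user_id)]
  new_prepost_result(
    measure_name = "volume", diffs = as.numeric(post_vals - pre_vals),
    mean_pre = mean(pre_vals), mean_post = mean(post_vals),
    alpha = alpha, n_excluded = n_excluded, power_method = power_method
  )
}

#' Full pre-post summary table
#'
#' Convenience wrapper producing one row per quality measure (same-day,
#' complete, valid) plus the entry-volume comparison — the standard
#' pre/post/change/p/power/d report for an intervention study.
#'
#' @inheritParams compare_volume
#' @param required_fields Passed to [score_dataset()].
#' @return A tibble with one `prepost_result` row per comparison.
#' @export
prepost_table <- function(records, intervention_date, alpha = 0.05,
                          required_fields = required_fields_default(),
                          power_method = c("normal", "noncentral_t")) {
  power_method <- rlang::arg_match(power_method)
  flags <- score_dataset(records, required_fields)
  series <- aggregate_measures(flags, records, "by_user_and_window",
                               intervention_date = intervention_date)
  rows <- lapply(c("same_day", "complete", "valid"), function(m) {
    compare_prepost(series, m, alpha = alpha, power_method = power_method)
  })
  rows <- c(rows, list(
    compare_volume(records, intervention_date, alpha = alpha,
                   power_method = power_method)
  ))
  dplyr::bind_rows(rows)
}

#' @export
print.prepost_result <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "%-9s n=%d (excl %d)  pre %7.2f  post %7.2f  change %+7.2f  t=%6.2f  p=%.3g  d=%.3f  power=%.3f\n",
      x$measure[i], x$n_pairs[i], x$n_excluded[i], x$mean_pre[i],
      x$mean_post[i], x$mean_change[i], x$t_stat[i], x$p_value[i],
      x$cohen_d[i], x$power[i]
    ))
  }
  invisible(x)
}
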