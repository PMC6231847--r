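# The three record-level data quality rules (timeliness, completeness,
# validity) and their aggregation to percentage measure series.
#
# Each classifier is a pure, deterministic function of one record: no
# cross-record state, so permuting the dataset permutes the flags.

#' Default required fields for the completeness rule
#'
#' The completeness rule requires "all fields" of the reporting form to have
#' data; the form itself is configurable, so this is the minimal set every
#' encounter must carry: `user_id`, `encounter_type`, `appointment_date`,
#' `entry_date`, `visit_reason`. Referral details are additionally required
#' for initial encounters regardless of this set.
#'
#' @return Character vector of field names.
#' @export
required_fields_default <- function() {
  c("user_id", "encounter_type", "appointment_date", "entry_date",
    "visit_reason")
}

# Strings are trimmed at read time, so "" is the only blank form seen here.
field_missing <- function(x) {
  if (inherits(x, "Date")) return(is.na(x))
  if (is.character(x)) return(is.na(x) | x == "")
  is.na(x)
}

#' Classify same-day entry (timeliness)
#'
#' A record is a same-day entry iff it was entered into the system on the
#' same calendar day as the appointment (`entry_date == appointment_date`).
#'
#' @param records Encounter tibble (see [read_encounters()]).
#' @return Logical vector, one flag per record.
#' @export
classify_same_day <- function(records) {
  as.logical(records$entry_date == records$appointment_date)
}

#' Classify record completeness
#'
#' A record is complete iff (a) every configured required field has data,
#' (b) the visit reason is not the catch-all `"other"`, and (c) for initial
#' encounters, the referral source is present and the referral date is
#' present and not the `1900-01-01` "unknown" sentinel (an unknown referral
#' date counts as missing information).
#'
#' @inheritParams classify_same_day
#' @param required_fields Character vector of encounter field names that must
#'   be non-missing; defaults to [required_fields_default()].
#' @return Logical vector, one flag per record.
#' @export
classify_complete <- function(records, required_fields = required_fields_default()) {
  unknown <- setdiff(required_fields, ENCOUNTER_COLUMNS)
  if (length(unknown) > 0) {
    abort_config(paste0(
      "Unknown required field(s): ", paste(unknown, collapse = ", ")
    ))
  }
  n <- nrow(records)
  ok <- rep(TRUE, n)
  for (f in required_fields) {
    ok <- ok & !field_missing(records[[f]])
  }
  ok <- ok & !(!is.na(records$visit_reason) & records$visit_reason == "other")
  is_initial <- records$encounter_type == "initial"
  referral_ok <- !field_missing(records$referral_source) &
    !is.na(records$referral_date) &
    !is_unknown_referral(records$referral_date)
  ok & (!is_initial | referral_ok)
}

#' Classify date validity
#'
#' A record is valid iff all of:
#' 1. the appointment date is on or before the entry date;
#' 2. the appointment date is strictly after 2008-01-01;
#' 3. the entry date is less than 4 calendar months after the appointment
#'    date (months added with day-of-month clamping);
#' 4. if a referral date is present and is not the unknown sentinel, the
#'    appointment date is at most 6 calendar months after the referral date.
#'
#' Sentinel referral dates skip rule 4 (an unknown date cannot be compared).
#'
#' @inheritParams classify_same_day
#' @return Logical vector, one flag per record.
#' @export
classify_valid <- function(records) {
  appt <- records$appointment_date
  entry <- records$entry_date
  ref <- records$referral_date
  ok <- appt <= entry
  ok <- ok & appt > as.Date("2008-01-01")
  ok <- ok & entry < add_months(appt, 4)
  has_ref <- !is.na(ref) & !is_unknown_referral(ref)
  ref_ok <- !has_ref
  if (any(has_ref)) {
    ref_ok[has_ref] <- appt[has_ref] <= add_months(ref[has_ref], 6)
  }
  as.logical(ok & ref_ok)
}

#' Score a dataset on all three quality measures
#'
#' Applies [classify_same_day()], [classify_complete()] and
#' [classify_valid()] to every record, preserving order.
#'
#' @inheritParams classify_complete
#' @return A tibble with one row per record: `record_id`, `same_day`,
#'   `complete`, `valid`.
#' @export
score_dataset <- function(records, required_fields = required_fields_default()) {
  tibble::tibble(
    record_id = records$record_id,
    same_day = classify_same_day(records),
    complete = classify_complete(records, required_fields),
    valid = classify_valid(records)
  )
}

#' Aggregate quality flags to percentage measure series
#'
#' Groups flagged records by user, by appointment-date calendar month, or by
#' user crossed with the pre/post intervention window, and computes the three
#' percentage measures per group. Windows are 8 weeks each: pre is
#' `[intervention_date - 56, intervention_date)` and post is
#' `[intervention_date, intervention_date + 56)`, with records assigned by
#' appointment date; records outside both windows are excluded. Groups with
#' zero records are omitted, so every percentage has `n_records > 0`.
#'
#' @param flags Flag tibble from [score_dataset()], aligned with `records`.
#' @param records The encounter tibble the flags were computed from.
#' @param grouping One of `"by_user"`, `"by_month"`, `"by_user_and_window"`.
#' @param intervention_date Date of the intervention (required for
#'   `"by_user_and_window"`).
#' @return A tibble with the group key column(s) (`user_id`, `month`, and/or
#'   `window`), `n_records`, and `pct_same_day`, `pct_complete`, `pct_valid`
#'   in percent (0-100). The grouping is recorded in the `grouping` attribute.
#' @export
aggregate_measures <- function(flags, records,
                               grouping = c("by_user", "by_month",
                                            "by_user_and_window"),
                               intervention_date = NULL) {
  grouping <- rlang::arg_match(grouping)
  if (nrow(flags) != nrow(records)) {
    abort_config("`flags` and `records` must have the same number of rows")
  }
  dat <- tibble::tibble(
    user_id = records$user_id,
    appointment_date = records$appointment_date,
    same_day = flags$same_day,
    complete = flags$complete,
    valid = flags$valid
  )
  if (grouping == "by_user") {
    grouped <- dplyr::group_by(dat, .data$user_id)
  } else if (grouping == "by_month") {
    dat$month <- format(dat$appointment_date, "%Y-%m")
    grouped <- dplyr::group_by(dat, .data$month)
  } else {
    if (is.null(intervention_date)) {
      abort_config("`intervention_date` is required for by_user_and_window grouping")
    }
    intervention_date <- as.Date(intervention_date)
    dat$window <- assign_window(dat$appointment_date, intervention_date)
    dat <- dplyr::filter(dat, !is.na(.data$window))
    grouped <- dplyr::group_by(dat, .data$user_id, .data$window)
  }
  out <- dplyr::summarise(
    grouped,
    n_records = dplyr::n(),
    pct_same_day = 100 * mean(.data$same_day),
    pct_complete = 100 * mean(.data$complete),
    pct_valid = 100 * mean(.data$valid),
    .groups = "drop"
  )
  if (grouping == "by_month") out <- dplyr::arrange(out, .data$month)
  attr(out, "grouping") <- grouping
  if (!is.null(intervention_date)) {
    attr(out, "intervention_date") <- intervention_date
  }
  out
}

# Pre window: [intervention - 56 days, intervention); post: [intervention,
# intervention + 56 days). NA outside both.
assign_window <- function(appointment_date, intervention_date) {
  pre_start <- intervention_date - 56L
  post_end <- intervention_date + 56L
  dplyr::case_when(
    appointment_date >= pre_start & appointment_date < intervention_date ~ "pre",
    appointment_date >= intervention_date & appointment_date < post_end ~ "post",
    TRUE ~ NA_character_
  )
}
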