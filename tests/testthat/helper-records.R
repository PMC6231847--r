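# Build small encounter tables in code for unit tests. Length-1 arguments
# are recycled; dates accept strings.
make_records <- function(record_id, user_id = "u1", profession = "nurse",
                         encounter_type = "follow_up",
                         appointment_date, entry_date = appointment_date,
                         referral_date = NA, referral_source = NA_character_,
                         visit_reason = "counseling", no_show = FALSE) {
  n <- length(record_id)
  rec <- function(x) if (n == 0) x[0] else rep_len(x, n)
  dqspc:::new_encounter_tbl(
    record_id = rec(record_id), user_id = rec(user_id),
    profession = rec(profession), encounter_type = rec(encounter_type),
    appointment_date = as.Date(rec(appointment_date)),
    entry_date = as.Date(rec(entry_date)),
    referral_date = as.Date(rec(referral_date)),
    referral_source = rec(referral_source),
    visit_reason = rec(visit_reason), no_show = rec(no_show),
    provenance = "test"
  )
}

# A small, fast cohort config for I/O round-trips and structural checks;
# any cohort_config() argument can be overridden.
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_users = 5, entries_per_user_week = 3,
         start_date = as.Date("2016-10-01"), end_date = as.Date("2016-12-31"),
         intervention_date = as.Date("2016-11-28"), seed = seed),
    list(...)
  )
  do.call(cohort_config, args)
}

# Independent brute-force XmR limits: mean, mean absolute successive
# difference, and the standard individuals-chart scale constants.
brute_force_xmr <- function(x, k = length(x)) {
  mr <- abs(x[-1] - x[-length(x)])
  x_bar <- sum(x[1:k]) / k
  mr_bar <- sum(mr[1:(k - 1)]) / (k - 1)
  list(
    x_bar = x_bar,
    x_ucl = x_bar + 2.66 * mr_bar,
    x_lcl = x_bar - 2.66 * mr_bar,
    mr = mr, mr_bar = mr_bar, mr_ucl = 3.267 * mr_bar,
    x_signals = which(x > x_bar + 2.66 * mr_bar | x < x_bar - 2.66 * mr_bar),
    mr_signals = which(mr > 3.267 * mr_bar)
  )
}
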