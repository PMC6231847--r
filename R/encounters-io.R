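# Encounter-record data model and CSV interchange.
#
# One row per clinical encounter. Interchange format is CSV with ISO-8601
# dates; empty strings denote missing optional values. The referral-date
# sentinel 1900-01-01 is a distinct, preserved value (it means "clinician
# reported the referral date as unknown", not mere missingness).

ENCOUNTER_COLUMNS <- c(
  "record_id", "user_id", "profession", "encounter_type",
  "appointment_date", "entry_date", "referral_date", "referral_source",
  "visit_reason", "no_show"
)

REQUIRED_COLUMNS <- c(
  "record_id", "user_id", "encounter_type",
  "appointment_date", "entry_date", "visit_reason", "no_show"
)

ENCOUNTER_TYPES <- c("initial", "follow_up")

# Strict ISO-8601 calendar-date parser: rejects locale formats and
# impossible dates (e.g. 2016-02-30). Returns Date with NA for failures.
parse_iso_date <- function(x) {
  x <- as.character(x)
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out <- rep(as.Date(NA), length(x))
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y-%m-%d")
    # as.Date with an explicit format returns NA for impossible dates
    out[ok] <- d
  }
  out
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}

# Construct a validated encounter tibble from parallel vectors. Used by the
# reader, the generator and test helpers; recycles length-1 inputs.
new_encounter_tbl <- function(record_id, user_id, profession = NA_character_,
                              encounter_type, appointment_date, entry_date,
                              referral_date = as.Date(NA),
                              referral_source = NA_character_,
                              visit_reason, no_show = FALSE,
                              provenance = "constructed") {
  out <- tibble::tibble(
    record_id = as.character(record_id),
    user_id = as.character(user_id),
    profession = as.character(profession),
    encounter_type = as.character(encounter_type),
    appointment_date = as.Date(appointment_date),
    entry_date = as.Date(entry_date),
    referral_date = as.Date(referral_date),
    referral_source = as.character(referral_source),
    visit_reason = as.character(visit_reason),
    no_show = as.logical(no_show)
  )
  attr(out, "provenance") <- provenance
  attr(out, "n_dropped") <- 0L
  class(out) <- c("encounter_tbl", class(tibble::tibble()))
  out
}

#' Read clinical encounter records from CSV
#'
#' Reads a CSV of encounter records (one row per encounter) into a validated
#' tibble. Dates must be ISO-8601 (`YYYY-MM-DD`); `no_show` must be
#' `"true"`/`"false"`; empty strings are read as missing for the optional
#' columns (`profession`, `referral_date`, `referral_source`). The
#' `1900-01-01` referral-date sentinel is preserved as a real date value
#' (see [is_unknown_referral()]). Input row order is preserved.
#'
#' @param path Path to a CSV file whose header names the encounter columns.
#'   The optional columns may be absent entirely; the required columns
#'   (`record_id`, `user_id`, `encounter_type`, `appointment_date`,
#'   `entry_date`, `visit_reason`, `no_show`) may not.
#' @param strict If `TRUE` (default) any malformed row aborts with a
#'   row-addressed error; if `FALSE` malformed rows are dropped and counted
#'   in the `n_dropped` attribute of the result.
#' @return A tibble of class `encounter_tbl` with attributes `provenance`
#'   (the source path) and `n_dropped` (rows dropped in lenient mode).
#' @seealso [write_encounters()]
#' @export
read_encounters <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort_schema(paste0("Encounter file does not exist: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort_schema(paste0(
      "Missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  for (opt in setdiff(ENCOUNTER_COLUMNS, names(raw))) {
    raw[[opt]] <- NA_character_
  }
  raw <- raw[ENCOUNTER_COLUMNS]
  n_in <- nrow(raw)
  if (n_in == 0) {
    out <- new_encounter_tbl(
      record_id = character(), user_id = character(),
      profession = character(), encounter_type = character(),
      appointment_date = as.Date(character()), entry_date = as.Date(character()),
      referral_date = as.Date(character()), referral_source = character(),
      visit_reason = character(), no_show = logical(),
      provenance = path
    )
    return(out)
  }

  record_id <- blank_to_na(raw$record_id)
  user_id <- blank_to_na(raw$user_id)
  profession <- blank_to_na(raw$profession)
  encounter_type <- blank_to_na(raw$encounter_type)
  appt <- parse_iso_date(blank_to_na(raw$appointment_date))
  entry <- parse_iso_date(blank_to_na(raw$entry_date))
  ref_raw <- blank_to_na(raw$referral_date)
  ref <- parse_iso_date(ref_raw)
  referral_source <- blank_to_na(raw$referral_source)
  visit_reason <- blank_to_na(raw$visit_reason)
  ns_raw <- tolower(trimws(ifelse(is.na(raw$no_show), "", raw$no_show)))
  no_show <- ifelse(ns_raw == "true", TRUE, ifelse(ns_raw == "false", FALSE, NA))

  problems <- character(n_in)
  add_problem <- function(problems, bad, what) {
    ifelse(bad, ifelse(problems == "", what, paste(problems, what, sep = "; ")),
           problems)
  }
  problems <- add_problem(problems, is.na(record_id), "missing record_id")
  problems <- add_problem(problems, is.na(user_id), "missing user_id")
  problems <- add_problem(
    problems, is.na(encounter_type) | !(encounter_type %in% ENCOUNTER_TYPES),
    "encounter_type not one of initial/follow_up"
  )
  problems <- add_problem(problems, is.na(appt), "unparseable appointment_date")
  problems <- add_problem(problems, is.na(entry), "unparseable entry_date")
  problems <- add_problem(problems, !is.na(ref_raw) & is.na(ref),
                          "unparseable referral_date")
  problems <- add_problem(problems, is.na(visit_reason), "missing visit_reason")
  problems <- add_problem(problems, is.na(no_show), "no_show not true/false")
  # duplicate ids violate the dataset invariant
  problems <- add_problem(problems, duplicated(record_id) & !is.na(record_id),
                          "duplicate record_id")

  bad <- problems != ""
  if (any(bad) && strict) {
    rows <- which(bad)
    msgs <- paste0("row ", rows, ": ", problems[rows])
    abort_schema(c(
      paste0(sum(bad), " malformed row(s) in ", path),
      utils::head(msgs, 10)
    ))
  }

  keep <- !bad
  out <- new_encounter_tbl(
    record_id = record_id[keep], user_id = user_id[keep],
    profession = profession[keep], encounter_type = encounter_type[keep],
    appointment_date = appt[keep], entry_date = entry[keep],
    referral_date = ref[keep], referral_source = referral_source[keep],
    visit_reason = visit_reason[keep], no_show = no_show[keep],
    provenance = path
  )
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Write clinical encounter records to CSV
#'
#' Serialises an encounter tibble to CSV with ISO-8601 dates, `no_show` as
#' `"true"`/`"false"` and empty strings for missing optional values, such
#' that `read_encounters(write_encounters(d, path))` reproduces `d`
#' field-for-field (including the `1900-01-01` referral sentinel, written
#' literally). An empty dataset produces a header-only file.
#'
#' @param records An encounter tibble (see [read_encounters()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_encounters <- function(records, path) {
  stopifnot(all(ENCOUNTER_COLUMNS %in% names(records)))
  fmt_date <- function(x) ifelse(is.na(x), "", format(x, "%Y-%m-%d"))
  fmt_chr <- function(x) ifelse(is.na(x), "", as.character(x))
  out <- tibble::tibble(
    record_id = fmt_chr(records$record_id),
    user_id = fmt_chr(records$user_id),
    profession = fmt_chr(records$profession),
    encounter_type = fmt_chr(records$encounter_type),
    appointment_date = fmt_date(records$appointment_date),
    entry_date = fmt_date(records$entry_date),
    referral_date = fmt_date(records$referral_date),
    referral_source = fmt_chr(records$referral_source),
    visit_reason = fmt_chr(records$visit_reason),
    no_show = ifelse(records$no_show, "true", "false")
  )
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) {
      rlang::abort(paste0("Cannot write encounters to ", path, ": ",
                          conditionMessage(e)))
    }
  )
  invisible(path)
}
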