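# Vectorised proleptic-Gregorian calendar arithmetic on integer day counts
# (days since 1970-01-01), after Hinnant's civil-calendar algorithms. Used
# for the calendar-month date rules; exact for all Date values and much
# faster than POSIXlt round-trips on large cohorts.

# integer days -> list(year, month, day)
civil_from_days <- function(z) {
  z <- as.integer(z) + 719468L
  era <- (ifelse(z >= 0L, z, z - 146096L)) %/% 146097L
  doe <- z - era * 146097L
  yoe <- (doe - doe %/% 1460L + doe %/% 36524L - doe %/% 146096L) %/% 365L
  y <- yoe + era * 400L
  doy <- doe - (365L * yoe + yoe %/% 4L - yoe %/% 100L)
  mp <- (5L * doy + 2L) %/% 153L
  d <- doy - (153L * mp + 2L) %/% 5L + 1L
  m <- mp + ifelse(mp < 10L, 3L, -9L)
  list(year = y + (m <= 2L), month = m, day = d)
}

# list(year, month, day) -> integer days
days_from_civil <- function(y, m, d) {
  y <- as.integer(y) - (m <= 2L)
  era <- (ifelse(y >= 0L, y, y - 399L)) %/% 400L
  yoe <- y - era * 400L
  doy <- (153L * (m + ifelse(m > 2L, -3L, 9L)) + 2L) %/% 5L + d - 1L
  doe <- yoe * 365L + yoe %/% 4L - yoe %/% 100L + doy
  era * 146097L + doe - 719468L
}

days_in_month <- function(y, m) {
  lengths <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (y %% 4L == 0L & y %% 100L != 0L) | (y %% 400L == 0L)
  out <- lengths[m]
  out[m == 2L & leap] <- 29L
  out
}

# Calendar-month advancement with day-of-month clamping (Jan 31 + 1 month =
# Feb 28/29), the natural clinical reading of "N months" date rules.
add_months <- function(x, n) {
  c0 <- civil_from_days(unclass(as.Date(x)))
  total <- (c0$year * 12L + c0$month - 1L) + as.integer(n)
  y <- total %/% 12L
  m <- total %% 12L + 1L
  d <- pmin(c0$day, days_in_month(y, m))
  as.Date(days_from_civil(y, m, d), origin = "1970-01-01")
}

# TRUE for dates in the 14 days before a calendar-quarter end (inclusive of
# the quarter-end day itself). Operates on integer day counts.
quarter_end_window_i <- function(day_i) {
  cv <- civil_from_days(day_i)
  qm <- ((cv$month - 1L) %/% 3L) * 3L + 3L
  q_end <- days_from_civil(cv$year, qm, days_in_month(cv$year, qm))
  (q_end - day_i) < 14L
}
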