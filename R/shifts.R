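# Shift windows are anchored at 07:00 and 19:00 wall-clock time. All
# timestamps in the package are naive wall-clock datetimes carried as POSIXct
# in the "UTC" zone, which has no daylight-saving transitions: shift windows
# are therefore always exactly 12 wall-clock hours, matching how a charting
# timestamp reads on the chart.

SECS_PER_HOUR <- 3600L
SECS_PER_DAY <- 86400L
DAY_ANCHOR <- 7L * SECS_PER_HOUR   # 07:00:00
NIGHT_ANCHOR <- 19L * SECS_PER_HOUR # 19:00:00

#' Parse a wall-clock timestamp
#'
#' Parses ISO 8601 date-times ("2018-03-05T07:00:00" or with a space) into
#' the package's internal naive wall-clock representation (POSIXct, UTC,
#' floored to whole seconds). No timezone arithmetic is ever applied.
#'
#' @param x Character vector of ISO 8601 date-times.
#' @return POSIXct vector; elements that fail to parse are `NA`.
#' @export
wall_time <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    if (!anyNA(out)) break
    miss <- is.na(out)
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  # second resolution: drop any sub-second component
  as.POSIXct(floor(as.numeric(out)), tz = "UTC", origin = "1970-01-01")
}

#' Map timestamps to 12-hour shift identifiers
#'
#' The day shift runs 07:00:00-18:59:59 and the night shift 19:00:00-06:59:59
#' the following morning. Night shifts are labelled by their *start* date, so
#' 03:00 on March 6 belongs to the March 5 night shift. Implemented as
#' half-open windows `[07:00, 19:00)` / `[19:00, 07:00 next day)`, which is
#' identical at second resolution.
#'
#' @param timestamp POSIXct vector (wall-clock, see [wall_time()]).
#' @return A tibble with columns `shift_date` (Date) and `period`
#'   (`"day"` or `"night"`), one row per input timestamp.
#' @examples
#' shift_id_of(wall_time(c("2018-03-05T07:00:00", "2018-03-06T03:00:00")))
#' @export
shift_id_of <- function(timestamp) {
  secs <- as.numeric(timestamp)
  day0 <- floor(secs / SECS_PER_DAY)           # days since epoch, wall clock
  tod <- secs - day0 * SECS_PER_DAY            # seconds past midnight
  is_day <- tod >= DAY_ANCHOR & tod < NIGHT_ANCHOR
  # before 07:00 -> previous date's night shift
  shift_day <- ifelse(tod < DAY_ANCHOR, day0 - 1, day0)
  tibble::tibble(
    shift_date = as.Date(shift_day, origin = "1970-01-01"),
    period = c("night", "day")[as.integer(is_day) + 1L]
  )
}

#' Shift window boundaries for shift identifiers
#'
#' @param shift_date Date vector.
#' @param period Character vector, `"day"` or `"night"`.
#' @return A tibble with `window_start` (inclusive) and `window_end`
#'   (exclusive) POSIXct columns.
#' @export
shift_window <- function(shift_date, period) {
  stopifnot(all(period %in% c("day", "night")))
  base <- as.numeric(shift_date) * SECS_PER_DAY
  start <- base + ifelse(period == "day", DAY_ANCHOR, NIGHT_ANCHOR)
  end <- start + 12L * SECS_PER_HOUR
  tibble::tibble(
    window_start = as.POSIXct(start, tz = "UTC", origin = "1970-01-01"),
    window_end = as.POSIXct(end, tz = "UTC", origin = "1970-01-01")
  )
}

# Integer index of a shift on the global alternating day/night timeline.
# Consecutive indices are contiguous 12-h windows; used for ordering and for
# the prior-shift contiguity test in the step-2 exclusion.
shift_index <- function(shift_date, period) {
  as.integer(as.numeric(shift_date) * 2L + (period == "night"))
}

shift_from_index <- function(idx) {
  tibble::tibble(
    shift_date = as.Date(idx %/% 2L, origin = "1970-01-01"),
    period = c("day", "night")[(idx %% 2L) + 1L]
  )
}

#' Enumerate patient shifts covered by ICU stays
#'
#' Partitions each ICU stay into the mutually exclusive 12-hour nursing-shift
#' windows it overlaps, producing one patient-shift row per (patient, window)
#' pair. A stay contributes a patient shift for every window with a non-empty
#' intersection with `[icu_in, icu_out)`. When a patient has several stays
#' (including overlapping ones) the windows are unioned: each (patient,
#' window) appears once, with `icu_overlap_secs` measured against the union
#' of that patient's stay intervals.
#'
#' @param stays A stays tibble as returned by [read_stays()].
#' @return A tibble with one row per patient shift, ordered by patient and
#'   time: `patient_id`, `shift_date`, `period`, `window_start`,
#'   `window_end`, `icu_overlap_secs`.
#' @export
enumerate_patient_shifts <- function(stays) {
  stopifnot(all(c("patient_id", "icu_in", "icu_out") %in% names(stays)))
  if (nrow(stays) == 0) {
    return(tibble::tibble(
      patient_id = character(), shift_date = as.Date(character()),
      period = character(),
      window_start = as.POSIXct(character(), tz = "UTC"),
      window_end = as.POSIXct(character(), tz = "UTC"),
      icu_overlap_secs = numeric()
    ))
  }
  # per stay: range of shift indices touched
  first_id <- shift_id_of(stays$icu_in)
  # icu_out is an exclusive bound; the instant icu_out itself is not in the
  # stay, so use icu_out - 1s to find the last touched window
  last_id <- shift_id_of(stays$icu_out - 1)
  i0 <- shift_index(first_id$shift_date, first_id$period)
  i1 <- shift_index(last_id$shift_date, last_id$period)

  per_stay <- tibble::tibble(
    patient_id = rep(stays$patient_id, i1 - i0 + 1L),
    sidx = unlist(purrr::map2(i0, i1, seq), use.names = FALSE),
    icu_in = rep(stays$icu_in, i1 - i0 + 1L),
    icu_out = rep(stays$icu_out, i1 - i0 + 1L)
  )
  sw <- shift_from_index(per_stay$sidx)
  win <- shift_window(sw$shift_date, sw$period)
  per_stay$overlap <- pmax(
    0,
    as.numeric(pmin(win$window_end, per_stay$icu_out)) -
      as.numeric(pmax(win$window_start, per_stay$icu_in))
  )
  # union stays within a (patient, window): clip each stay to the window and
  # merge the clipped intervals so overlapping stays are not double counted
  per_stay$clip_lo <- pmax(as.numeric(win$window_start), as.numeric(per_stay$icu_in))
  per_stay$clip_hi <- pmin(as.numeric(win$window_end), as.numeric(per_stay$icu_out))

  merged <- per_stay |>
    dplyr::group_by(.data$patient_id, .data$sidx) |>
    dplyr::arrange(.data$clip_lo, .by_group = TRUE) |>
    dplyr::mutate(new_run = cumsum(
      dplyr::lag(cummax(.data$clip_hi), default = -Inf) < .data$clip_lo
    )) |>
    dplyr::group_by(.data$patient_id, .data$sidx, .data$new_run) |>
    dplyr::summarise(len = max(.data$clip_hi) - min(.data$clip_lo),
                     .groups = "drop") |>
    dplyr::group_by(.data$patient_id, .data$sidx) |>
    dplyr::summarise(icu_overlap_secs = sum(.data$len), .groups = "drop")

  sw2 <- shift_from_index(merged$sidx)
  win2 <- shift_window(sw2$shift_date, sw2$period)
  out <- tibble::tibble(
    patient_id = merged$patient_id,
    shift_date = sw2$shift_date,
    period = sw2$period,
    window_start = win2$window_start,
    window_end = win2$window_end,
    icu_overlap_secs = merged$icu_overlap_secs
  )
  out[order(out$patient_id, shift_index(out$shift_date, out$period)), ]
}

#' Attach charting events to patient shifts
#'
#' Joins events to the patient shift whose window contains their timestamp.
#' Within one (patient shift, nurse), identical timestamps collapse to one
#' unique charting time: nurses can electronically sign many charting
#' instances in the same second, and only distinct times carry signal.
#' Events are *not* clipped to the ICU-stay interval: anything stamped inside
#' the window of an enumerated patient shift counts, which is how charting
#' around admission/discharge transitions stays visible to the algorithm.
#'
#' @param events Events tibble ([read_events()]).
#' @param patient_shifts Output of [enumerate_patient_shifts()].
#' @return A list with `attached` — a tibble of unique charting times
#'   (`patient_id`, `shift_date`, `period`, `nurse_id`, `timestamp`) — and
#'   `unattached` — the events matching no enumerated patient shift.
#' @export
attach_events <- function(events, patient_shifts) {
  sid <- shift_id_of(events$timestamp)
  keyed <- tibble::tibble(
    patient_id = events$patient_id,
    shift_date = sid$shift_date,
    period = sid$period,
    nurse_id = events$nurse_id,
    timestamp = events$timestamp
  )
  shifts_key <- patient_shifts[c("patient_id", "shift_date", "period")]
  matched <- dplyr::semi_join(keyed, shifts_key,
                              by = c("patient_id", "shift_date", "period"))
  unmatched_idx <- !vctrs_in(keyed, shifts_key)
  attached <- dplyr::distinct(matched)
  attached <- attached[order(attached$patient_id,
                             shift_index(attached$shift_date, attached$period),
                             attached$nurse_id, attached$timestamp), ]
  list(attached = attached, unattached = events[unmatched_idx, ])
}

# row membership of keyed (by the three key cols) in shifts_key
vctrs_in <- function(keyed, shifts_key) {
  a <- paste(keyed$patient_id, keyed$shift_date, keyed$period, sep = "\r")
  b <- paste(shifts_key$patient_id, shifts_key$shift_date, shifts_key$period,
             sep = "\r")
  a %in% b
}
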