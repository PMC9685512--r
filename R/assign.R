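# The two-step primary-nurse selection rule.
#
# Two input variables per (patient shift, nurse): the count of *unique*
# charting times and the interval between first and last charting time.
# Step 1 takes the nurse with the highest count, breaking ties by the
# longest interval; a residual tie means no primary nurse (no randomness is
# ever introduced). Step 2 re-runs step 1 after excluding the nurse who was
# the step-1 primary of the patient's immediately preceding contiguous
# 12-hour shift, guarding against nurses who chart extensively after their
# own shift ended. Every patient shift lands in exactly one of six outcome
# categories:
#   1 one candidate nurse charted and was selected
#   2 multiple nurses charted; a unique maximum count decided
#   3 count tie broken by the charting interval
#   4 no nurse charted
#   5 count and interval both tied; unresolved, no primary nurse
#   6 the only charter was the prior shift's primary (excluded)

CATEGORY_LABELS <- c(
  "One nurse charted",
  "Multiple nurses charted, one charted the most times",
  "Multiple nurses charted the most times, tie broken by interval",
  "No nurse charted",
  "Multiple nurses charted the most times, tie not broken by interval",
  "One nurse charted and it was the primary nurse in the prior shift"
)

#' Per-nurse charting statistics for one patient shift
#'
#' @param times Tibble of unique charting times with columns `nurse_id`,
#'   `timestamp` (already deduplicated per nurse, as produced by
#'   [attach_events()]).
#' @return Tibble with one row per nurse: `nurse_id`, `chart_count`,
#'   `first_time`, `last_time`, `interval_secs`.
#' @export
compute_stats <- function(times) {
  if (nrow(times) == 0) {
    return(tibble::tibble(nurse_id = character(), chart_count = integer(),
                          first_time = as.POSIXct(character(), tz = "UTC"),
                          last_time = as.POSIXct(character(), tz = "UTC"),
                          interval_secs = numeric()))
  }
  times |>
    dplyr::group_by(.data$nurse_id) |>
    dplyr::summarise(chart_count = dplyr::n_distinct(.data$timestamp),
                     first_time = min(.data$timestamp),
                     last_time = max(.data$timestamp), .groups = "drop") |>
    dplyr::mutate(interval_secs = as.numeric(.data$last_time) -
                    as.numeric(.data$first_time))
}

#' Step-1 selection: argmax by count, ties broken by interval
#'
#' @param stats Per-nurse statistics for one patient shift
#'   ([compute_stats()]).
#' @return A list with `nurse_id` (string or `NA` for none) and `mode`, one
#'   of `"sole_charter"`, `"max_count"`, `"tie_broken"`, `"tie_unbroken"`,
#'   `"no_charter"`.
#' @export
step1_select <- function(stats) {
  if (nrow(stats) == 0) {
    return(list(nurse_id = NA_character_, mode = "no_charter"))
  }
  if (nrow(stats) == 1) {
    return(list(nurse_id = stats$nurse_id, mode = "sole_charter"))
  }
  top <- stats[stats$chart_count == max(stats$chart_count), ]
  if (nrow(top) == 1) {
    return(list(nurse_id = top$nurse_id, mode = "max_count"))
  }
  top2 <- top[top$interval_secs == max(top$interval_secs), ]
  if (nrow(top2) == 1) {
    return(list(nurse_id = top2$nurse_id, mode = "tie_broken"))
  }
  list(nurse_id = NA_character_, mode = "tie_unbroken")
}

# Map the selection mode on the post-exclusion candidate set to the outcome
# category. `had_any_charter` distinguishes "no nurse charted" (4) from "the
# only charter was the excluded prior primary" (6).
mode_to_category <- function(mode, had_any_charter) {
  switch(mode,
    sole_charter = 1L,
    max_count = 2L,
    tie_broken = 3L,
    tie_unbroken = 5L,
    no_charter = if (had_any_charter) 6L else 4L,
    rlang::abort(paste("unknown selection mode", mode),
                 class = "nursetrace_internal_error")
  )
}

#' Run the full two-step assignment over events and stays
#'
#' Enumerates patient shifts from the ICU stays, attaches unique charting
#' times, applies step 1 per shift and the step-2 prior-primary exclusion
#' per patient, and categorizes every shift. The exclusion uses the *step-1*
#' primary of the immediately preceding contiguous window for the same
#' patient; after a gap (the patient left the ICU and returned) no exclusion
#' applies. The whole pipeline is deterministic and invariant to row order
#' and to duplicated event rows.
#'
#' @param events Events tibble ([read_events()]).
#' @param stays Stays tibble ([read_stays()]).
#' @return A list with
#'   \describe{
#'     \item{assignments}{one row per patient shift: `patient_id`,
#'       `shift_date`, `period`, `primary_nurse_id` (`NA` = none),
#'       `category` (1-6), `step1_nurse_id` (pre-exclusion result, for
#'       audit), `icu_overlap_secs`.}
#'     \item{summary}{category counts and shares ([assignment_summary()]).}
#'     \item{n_unattached}{events falling in no enumerated patient shift.}
#'   }
#' @examples
#' stays <- tibble::tibble(patient_id = "p1", unit_id = "icu",
#'   icu_in = wall_time("2018-03-05T10:00:00"),
#'   icu_out = wall_time("2018-03-06T09:00:00"))
#' events <- tibble::tibble(patient_id = "p1", nurse_id = "n1",
#'   timestamp = wall_time("2018-03-05T11:00:00"), kind = "assessment")
#' assign_all(events, stays)$assignments
#' @export
assign_all <- function(events, stays) {
  shifts <- enumerate_patient_shifts(stays)
  att <- attach_events(events, shifts)
  shifts$sidx <- shift_index(shifts$shift_date, shifts$period)
  times <- att$attached
  times$sidx <- shift_index(times$shift_date, times$period)

  # per-(patient shift, nurse) statistics in one pass; dplyr probes the
  # summarise expressions even with zero groups, so guard the empty case
  stats_all <- if (nrow(times) == 0) {
    tibble::tibble(patient_id = character(), sidx = integer(),
                   nurse_id = character(), chart_count = integer(),
                   first_time = as.POSIXct(character(), tz = "UTC"),
                   last_time = as.POSIXct(character(), tz = "UTC"),
                   interval_secs = numeric())
  } else {
    times |>
      dplyr::group_by(.data$patient_id, .data$sidx, .data$nurse_id) |>
      dplyr::summarise(chart_count = dplyr::n(),
                       first_time = min(.data$timestamp),
                       last_time = max(.data$timestamp), .groups = "drop") |>
      dplyr::mutate(interval_secs = as.numeric(.data$last_time) -
                      as.numeric(.data$first_time))
  }

  stats_by_shift <- split(
    stats_all,
    paste(stats_all$patient_id, stats_all$sidx, sep = "\r")
  )
  shift_key <- paste(shifts$patient_id, shifts$sidx, sep = "\r")

  empty_stats <- compute_stats(
    tibble::tibble(nurse_id = character(),
                   timestamp = as.POSIXct(character(), tz = "UTC")))

  n <- nrow(shifts)
  step1_nurse <- character(n)
  final_nurse <- character(n)
  category <- integer(n)

  ord <- order(shifts$patient_id, shifts$sidx)
  prev_patient <- ""
  prev_sidx <- NA_integer_
  prev_step1 <- NA_character_
  for (i in ord) {
    st <- stats_by_shift[[shift_key[i]]]
    if (is.null(st)) st <- empty_stats
    s1 <- step1_select(st)
    step1_nurse[i] <- s1$nurse_id

    contiguous <- identical(shifts$patient_id[i], prev_patient) &&
      !is.na(prev_sidx) && shifts$sidx[i] == prev_sidx + 1L
    excluded <- if (contiguous) prev_step1 else NA_character_

    if (!is.na(excluded)) {
      st2 <- st[st$nurse_id != excluded, ]
      s2 <- step1_select(st2)
      final_nurse[i] <- s2$nurse_id
      category[i] <- mode_to_category(s2$mode, had_any_charter = nrow(st) > 0)
    } else {
      final_nurse[i] <- s1$nurse_id
      category[i] <- mode_to_category(s1$mode, had_any_charter = nrow(st) > 0)
    }

    prev_patient <- shifts$patient_id[i]
    prev_sidx <- shifts$sidx[i]
    prev_step1 <- s1$nurse_id
  }

  assignments <- tibble::tibble(
    patient_id = shifts$patient_id,
    shift_date = shifts$shift_date,
    period = shifts$period,
    primary_nurse_id = final_nurse,
    category = category,
    step1_nurse_id = step1_nurse,
    icu_overlap_secs = shifts$icu_overlap_secs
  )
  assignments <- assignments[ord, ]

  list(assignments = assignments,
       summary = assignment_summary(assignments),
       n_unattached = nrow(att$unattached))
}

#' Six-category summary of an assignment table
#'
#' @param assignments Assignment tibble (from [assign_all()] or
#'   [read_assignments()]).
#' @return Tibble with `category` (1-6), `label`, `count`, `share`; shares
#'   sum to 1 and counts sum to the number of patient shifts.
#' @export
assignment_summary <- function(assignments) {
  counts <- tabulate(assignments$category, nbins = 6L)
  tibble::tibble(
    category = 1:6,
    label = CATEGORY_LABELS,
    count = counts,
    share = if (sum(counts) > 0) counts / sum(counts) else rep(0, 6)
  )
}
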