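# CSV readers/writers for the four tables the pipeline exchanges. Dialect is
# fixed: comma-separated, UTF-8, header row, ISO 8601 timestamps. All
# readers raise classed conditions ("nursetrace_input_error") with the
# offending line so the CLI can map them to exit code 2.

input_error <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "nursetrace_input_error")
}

EVENT_KINDS <- c("assessment", "medication")

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    input_error("%s: missing required column(s): %s", path,
                paste(missing, collapse = ", "))
  }
}

parse_time_column <- function(x, col, path) {
  parsed <- wall_time(x)
  bad <- which(is.na(parsed) & !is.na(x))
  if (length(bad) > 0) {
    # +1 for the header row
    input_error("%s: unparseable %s at line %d: '%s'", path, col,
                bad[1] + 1L, x[bad[1]])
  }
  if (anyNA(x)) {
    input_error("%s: missing %s at line %d", path, col, which(is.na(x))[1] + 1L)
  }
  parsed
}

read_raw_csv <- function(path, col_types) {
  if (!file.exists(path)) input_error("file not found: %s", path)
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  na = character())
}

#' Read a charting-event table
#'
#' One row per electronic signature: a nurse documenting an assessment or a
#' medication administration for a patient at a given second. Duplicate rows
#' are retained at read time; collapsing identical (nurse, time) signatures
#' is an algorithm step ([attach_events()]), not an I/O step.
#'
#' @param path CSV with columns `patient_id,nurse_id,timestamp,kind`;
#'   timestamps ISO 8601, `kind` one of `"assessment"`, `"medication"`.
#' @return Tibble with `patient_id`, `nurse_id`, `timestamp` (POSIXct),
#'   `kind`, in file order.
#' @export
read_events <- function(path) {
  df <- read_raw_csv(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("patient_id", "nurse_id", "timestamp", "kind"), path)
  bad_kind <- which(!(df$kind %in% EVENT_KINDS))
  if (length(bad_kind) > 0) {
    input_error("%s: unknown event kind '%s' at line %d (expected %s)",
                path, df$kind[bad_kind[1]], bad_kind[1] + 1L,
                paste(EVENT_KINDS, collapse = "|"))
  }
  if (any(!nzchar(df$patient_id)) || any(!nzchar(df$nurse_id))) {
    bad <- which(!nzchar(df$patient_id) | !nzchar(df$nurse_id))[1]
    input_error("%s: empty patient_id or nurse_id at line %d", path, bad + 1L)
  }
  tibble::tibble(
    patient_id = df$patient_id,
    nurse_id = df$nurse_id,
    timestamp = parse_time_column(df$timestamp, "timestamp", path),
    kind = df$kind
  )
}

#' Read an ICU-stay table
#'
#' One row per contiguous interval a patient spent in one ICU. Overlapping
#' stays for the same patient are legal (transfer records often overlap by a
#' few minutes); they are kept and flagged with a warning, and patient-shift
#' enumeration unions their windows.
#'
#' @param path CSV with columns `patient_id,unit_id,icu_in,icu_out`.
#' @return Tibble with `patient_id`, `unit_id`, `icu_in`, `icu_out`.
#' @export
read_stays <- function(path) {
  df <- read_raw_csv(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("patient_id", "unit_id", "icu_in", "icu_out"), path)
  icu_in <- parse_time_column(df$icu_in, "icu_in", path)
  icu_out <- parse_time_column(df$icu_out, "icu_out", path)
  bad <- which(icu_out <= icu_in)
  if (length(bad) > 0) {
    input_error("%s: icu_out <= icu_in at line %d (patient %s)", path,
                bad[1] + 1L, df$patient_id[bad[1]])
  }
  out <- tibble::tibble(patient_id = df$patient_id, unit_id = df$unit_id,
                        icu_in = icu_in, icu_out = icu_out)
  flag_overlapping_stays(out)
  out
}

flag_overlapping_stays <- function(stays) {
  ov <- stays |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$icu_in, .by_group = TRUE) |>
    dplyr::summarise(overlap = any(
      dplyr::lag(cummax(as.numeric(.data$icu_out)), default = -Inf) >
        as.numeric(.data$icu_in)), .groups = "drop")
  n_ov <- sum(ov$overlap)
  if (n_ov > 0) {
    warning(sprintf("%d patient(s) have overlapping ICU stays; both retained, windows unioned",
                    n_ov), call. = FALSE)
  }
  invisible(n_ov)
}

#' Read a chart-review label table
#'
#' Reference-standard labels from manual chart review. An empty
#' `reviewed_nurse_id` field means the reviewer established that no primary
#' nurse existed for the shift.
#'
#' @param path CSV with columns
#'   `patient_id,shift_date,period,reviewed_nurse_id`.
#' @return Tibble; `reviewed_nurse_id` is `NA` for explicit "none" labels.
#' @export
read_review <- function(path) {
  df <- read_raw_csv(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("patient_id", "shift_date", "period",
                        "reviewed_nurse_id"), path)
  check_period(df$period, path)
  key <- paste(df$patient_id, df$shift_date, df$period)
  if (anyDuplicated(key)) {
    input_error("%s: more than one review label for patient shift %s", path,
                key[duplicated(key)][1])
  }
  tibble::tibble(
    patient_id = df$patient_id,
    shift_date = as.Date(df$shift_date),
    period = df$period,
    reviewed_nurse_id = dplyr::na_if(df$reviewed_nurse_id, "")
  )
}

check_period <- function(period, path) {
  bad <- which(!(period %in% c("day", "night")))
  if (length(bad) > 0) {
    input_error("%s: invalid period '%s' at line %d", path, period[bad[1]],
                bad[1] + 1L)
  }
}

#' Write / read an assignment table
#'
#' Serializes one row per patient shift: the inferred primary nurse (empty
#' field for "no primary nurse") and the outcome category 1-6. Categories
#' 1-3 always carry a nurse, categories 4-6 never do. `read_assignments()`
#' inverts `write_assignments()` exactly.
#'
#' @param assignments Tibble with `patient_id`, `shift_date`, `period`,
#'   `primary_nurse_id` (`NA` = none), `category`.
#' @param path Output CSV path.
#' @return `write_assignments()` returns `path` invisibly;
#'   `read_assignments()` returns the tibble.
#' @export
write_assignments <- function(assignments, path) {
  cols <- c("patient_id", "shift_date", "period", "primary_nurse_id",
            "category")
  stopifnot(all(cols %in% names(assignments)))
  key <- paste(assignments$patient_id, assignments$shift_date,
               assignments$period)
  if (anyDuplicated(key)) {
    input_error("two assignments collide for patient shift %s",
                key[duplicated(key)][1])
  }
  has_nurse <- !is.na(assignments$primary_nurse_id)
  if (!all(has_nurse == (assignments$category %in% 1:3))) {
    rlang::abort("assignment table inconsistent: categories 1-3 must carry a nurse, 4-6 must not",
                 class = "nursetrace_internal_error")
  }
  out <- assignments[cols]
  out$primary_nurse_id <- ifelse(is.na(out$primary_nurse_id), "",
                                 out$primary_nurse_id)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  df <- read_raw_csv(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("patient_id", "shift_date", "period",
                        "primary_nurse_id", "category"), path)
  check_period(df$period, path)
  cat <- suppressWarnings(as.integer(df$category))
  if (any(is.na(cat) | cat < 1L | cat > 6L)) {
    input_error("%s: category outside 1-6 at line %d", path,
                which(is.na(cat) | cat < 1L | cat > 6L)[1] + 1L)
  }
  tibble::tibble(
    patient_id = df$patient_id,
    shift_date = as.Date(df$shift_date),
    period = df$period,
    primary_nurse_id = dplyr::na_if(df$primary_nurse_id, ""),
    category = cat
  )
}
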