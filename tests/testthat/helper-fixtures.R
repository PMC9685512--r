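# Fixture builders shared across test files. Everything is generated in
# code; tests set their own seeds.

utc <- function(x) nursetrace::wall_time(x)

make_events <- function(patient_id, nurse_id, timestamp,
                        kind = "assessment") {
  tibble::tibble(patient_id = patient_id, nurse_id = nurse_id,
                 timestamp = utc(timestamp), kind = kind)
}

make_stay <- function(patient_id, icu_in, icu_out, unit_id = "MICU") {
  tibble::tibble(patient_id = patient_id, unit_id = unit_id,
                 icu_in = utc(icu_in), icu_out = utc(icu_out))
}

# Random events for one patient: <= n_nurses nurses, <= n_times unique
# second-resolution timestamps placed across the stay's shift windows.
# Timestamps are drawn coarsely (whole minutes) so count/interval ties occur
# often enough to exercise the tie-break paths.
random_patient_fixture <- function(pid, n_nurses = 6, n_times = 20,
                                   n_windows = 3) {
  base <- as.numeric(utc("2019-06-03T07:00:00"))
  nw <- sample(n_windows, 1)
  icu_in <- base + sample(0:600, 1) * 60
  icu_out <- base + nw * 12 * 3600 - sample(0:600, 1) * 60
  k_nurse <- sample(n_nurses, 1)
  k_ev <- sample(n_times, 1)
  ts <- base + sample(seq(-60, nw * 12 * 60 + 60), k_ev, replace = TRUE) * 60
  ev <- tibble::tibble(
    patient_id = pid,
    nurse_id = paste0("n", sample(k_nurse, k_ev, replace = TRUE)),
    timestamp = as.POSIXct(ts, tz = "UTC", origin = "1970-01-01"),
    kind = sample(c("assessment", "medication"), k_ev, replace = TRUE)
  )
  list(
    events = ev,
    stay = tibble::tibble(
      patient_id = pid, unit_id = "MICU",
      icu_in = as.POSIXct(icu_in, tz = "UTC", origin = "1970-01-01"),
      icu_out = as.POSIXct(icu_out, tz = "UTC", origin = "1970-01-01"))
  )
}

# Assignment + review tables realizing given confusion-matrix counts.
confusion_fixture <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  pid <- sprintf("P%03d", seq_len(n))
  dates <- as.Date("2019-02-01") + (seq_len(n) %% 28)
  algo <- c(sprintf("RN%03d", seq_len(tp)),          # tp: same nurse
            sprintf("RN%03d", tp + seq_len(fp)),     # fp: algorithm nurse
            rep(NA_character_, fn + tn))             # fn/tn: none
  # fp split: review names a different nurse for odd rows, none for even
  fp_rev <- ifelse(seq_len(fp) %% 2 == 1, sprintf("RNX%02d", seq_len(fp)),
                   NA_character_)
  review <- c(sprintf("RN%03d", seq_len(tp)), fp_rev,
              sprintf("RNY%02d", seq_len(fn)), rep(NA_character_, tn))
  assignments <- tibble::tibble(
    patient_id = pid, shift_date = dates,
    period = rep(c("day", "night"), length.out = n),
    primary_nurse_id = algo,
    category = ifelse(is.na(algo), 4L, 2L))
  labels <- tibble::tibble(
    patient_id = pid, shift_date = dates,
    period = assignments$period, reviewed_nurse_id = review)
  list(assignments = assignments, review = labels)
}

random_assignments <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  category <- sample(1:6, n, replace = TRUE)
  tibble::tibble(
    patient_id = sprintf("P%04d", sample(10 * n, n)),
    shift_date = as.Date("2018-01-01") + sample(0:900, n, replace = TRUE),
    period = sample(c("day", "night"), n, replace = TRUE),
    primary_nurse_id = ifelse(category <= 3,
                              sprintf("RN%03d", sample(500, n, replace = TRUE)),
                              NA_character_),
    category = category
  ) |> dplyr::distinct(patient_id, shift_date, period, .keep_all = TRUE)
}
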