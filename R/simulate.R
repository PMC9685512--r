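# Synthetic EHR metadata generator. Produces ICU stays, nurse schedules and
# charting event streams with known ground truth, including the documented
# real-world failure modes: brief cross-coverage charting, late post-shift
# charting by the outgoing nurse, orientees co-signing in lockstep with
# their preceptor, and very short boundary stays with no documentation.
#
# Reproducibility: one global seed; every patient and every patient shift
# draws from its own deterministic substream (a hash of the seed and the
# patient/shift index), so regeneration is independent of loop order.

#' Simulation configuration
#'
#' Defaults describe a plausible ICU: nurses document assessments roughly
#' every half hour and give about one medication an hour, ICU length of stay
#' is log-normal with a 36-hour median and enough spread that short
#' boundary-straddling stays occur naturally, and contamination scenarios
#' fire at low rates.
#'
#' @param n_units Number of ICUs.
#' @param nurses_per_unit Roster size per unit (>= 2, so that a different
#'   nurse can always take the adjacent shift).
#' @param n_patients Number of patients.
#' @param los_meanlog,los_sdlog Log-normal parameters of length of stay in
#'   hours (defaults: median 36 h, sdlog 1.2).
#' @param assessment_rate Primary nurse's assessment signatures per hour.
#' @param medication_rate Medication-administration signatures per hour.
#' @param p_cross_coverage Probability that a second nurse briefly charts
#'   during a shift, with `lambda_cross` expected signatures in a short span.
#' @param p_late_charting Probability the outgoing primary charts into the
#'   first hour of the next shift, with `lambda_late` expected signatures.
#' @param p_orientee Probability an orientee co-signs at exactly the
#'   primary's charting times (producing a count-and-interval tie).
#' @param p_no_documentation Probability that a boundary shift (under
#'   `boundary_hours` of ICU overlap) has its primary chart nothing.
#' @param boundary_hours Overlap threshold defining a boundary shift.
#' @param lambda_cross,lambda_late Poisson means for the contamination draws.
#' @param start_date First possible admission date.
#' @param admit_span_days Admissions are uniform over this many days.
#' @param seed Integer seed governing all draws.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_units = 2,
                       nurses_per_unit = 10,
                       n_patients = 50,
                       los_meanlog = log(36),
                       los_sdlog = 1.2,
                       assessment_rate = 2,
                       medication_rate = 1,
                       p_cross_coverage = 0.10,
                       lambda_cross = 2,
                       p_late_charting = 0.05,
                       lambda_late = 3,
                       p_orientee = 0.02,
                       p_no_documentation = 0.5,
                       boundary_hours = 1,
                       start_date = "2020-01-06",
                       admit_span_days = 60,
                       seed = 1L) {
  cfg <- list(n_units = as.integer(n_units),
              nurses_per_unit = as.integer(nurses_per_unit),
              n_patients = as.integer(n_patients),
              los_meanlog = los_meanlog, los_sdlog = los_sdlog,
              assessment_rate = assessment_rate,
              medication_rate = medication_rate,
              p_cross_coverage = p_cross_coverage,
              lambda_cross = lambda_cross,
              p_late_charting = p_late_charting,
              lambda_late = lambda_late,
              p_orientee = p_orientee,
              p_no_documentation = p_no_documentation,
              boundary_hours = boundary_hours,
              start_date = as.character(start_date),
              admit_span_days = admit_span_days,
              seed = as.integer(seed))
  probs <- c("p_cross_coverage", "p_late_charting", "p_orientee",
             "p_no_documentation")
  for (p in probs) {
    if (is.na(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      rlang::abort(sprintf("%s must lie in [0, 1], got %s", p, cfg[[p]]),
                   class = "nursetrace_input_error")
    }
  }
  for (r in c("assessment_rate", "medication_rate", "los_sdlog",
              "lambda_cross", "lambda_late")) {
    if (is.na(cfg[[r]]) || cfg[[r]] <= 0) {
      rlang::abort(sprintf("%s must be > 0", r),
                   class = "nursetrace_input_error")
    }
  }
  if (cfg$nurses_per_unit < 2) {
    rlang::abort("nurses_per_unit must be >= 2 to avoid adjacent-shift repeats",
                 class = "nursetrace_input_error")
  }
  if (cfg$n_units < 1 || cfg$n_patients < 1) {
    rlang::abort("n_units and n_patients must be >= 1",
                 class = "nursetrace_input_error")
  }
  structure(cfg, class = "sim_config")
}

# deterministic 31-bit substream seed from (seed, i, j); plain integer
# mixing, good enough to decorrelate substreams
substream_seed <- function(seed, i, j = 0) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) + 1
  x <- (x * 48271 + as.numeric(i) * 69621 + as.numeric(j) * 16807) %% m
  x <- (x * 48271 + 11) %% m
  as.integer(x)
}

with_substream <- function(seed, i, j, expr) {
  restore <- local_rng(substream_seed(seed, i, j))
  on.exit(restore(), add = TRUE)
  force(expr)
}

#' Simulate an EHR metadata bundle with ground truth
#'
#' For each patient: a unit, an admission time and a log-normal length of
#' stay produce one ICU stay; each of its 12-hour patient shifts gets a
#' scheduled primary nurse from the unit roster, never the same nurse as the
#' adjacent prior shift (mirroring 12-hour scheduling). The primary's
#' charting times are a Poisson process over the window intersected with the
#' stay; contamination scenarios are injected per the configured
#' probabilities. Truth records the scheduled primary, or none for shifts
#' that end up with zero charting events (there is then no digital evidence
#' of any nurse).
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_bundle"`: `stays`, `events`, `truth`
#'   (patient shift, `true_nurse_id` with `NA` = none, `scenario` tag), and
#'   `config`.
#' @export
simulate_ehr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  t0 <- as.numeric(wall_time(paste0(config$start_date, "T00:00:00")))

  units <- sprintf("U%02d", seq_len(config$n_units))
  roster <- lapply(seq_len(config$n_units), function(u) {
    sprintf("N%02d%03d", u, seq_len(config$nurses_per_unit))
  })
  names(roster) <- units

  stays_l <- vector("list", config$n_patients)
  events_l <- vector("list", config$n_patients)
  truth_l <- vector("list", config$n_patients)

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", p)
    pat <- with_substream(config$seed, p, 0, {
      unit <- units[sample.int(config$n_units, 1)]
      admit <- t0 + stats::runif(1, 0, config$admit_span_days * SECS_PER_DAY)
      los <- stats::rlnorm(1, config$los_meanlog, config$los_sdlog) * SECS_PER_HOUR
      list(unit = unit, admit = floor(admit), los = max(60, round(los)))
    })
    icu_in <- as.POSIXct(pat$admit, tz = "UTC", origin = "1970-01-01")
    icu_out <- as.POSIXct(pat$admit + pat$los, tz = "UTC",
                          origin = "1970-01-01")
    stay <- tibble::tibble(patient_id = pid, unit_id = pat$unit,
                           icu_in = icu_in, icu_out = icu_out)
    stays_l[[p]] <- stay

    shifts <- enumerate_patient_shifts(stay)
    ns <- nrow(shifts)
    pool <- roster[[pat$unit]]

    ev <- vector("list", ns)
    late_carry <- vector("list", ns) # events the outgoing primary leaves in shift k+1
    true_nurse <- character(ns)
    scen <- character(ns)
    prev_primary <- NA_character_

    for (k in seq_len(ns)) {
      ws <- as.numeric(shifts$window_start[k])
      we <- as.numeric(shifts$window_end[k])
      lo <- max(ws, pat$admit)
      hi <- min(we, pat$admit + pat$los)

      shift_out <- with_substream(config$seed, p, k, {
        # decision uniforms drawn first, in fixed order, so scenario firing
        # sets are monotone in their probabilities under a common seed
        u_nodoc <- stats::runif(1)
        u_cross <- stats::runif(1)
        u_late <- stats::runif(1)
        u_orientee <- stats::runif(1)

        cand <- setdiff(pool, prev_primary)
        primary <- cand[sample.int(length(cand), 1)]

        is_boundary <- (hi - lo) < config$boundary_hours * SECS_PER_HOUR
        suppress <- is_boundary && u_nodoc < config$p_no_documentation
        p_times <- if (suppress) numeric(0) else {
          n_ev <- stats::rpois(1, (config$assessment_rate +
                                     config$medication_rate) *
                                 (hi - lo) / SECS_PER_HOUR)
          sort(unique(floor(stats::runif(n_ev, lo, hi))))
        }
        n_assess <- if (length(p_times) > 0) {
          stats::rbinom(1, length(p_times),
                        config$assessment_rate /
                          (config$assessment_rate + config$medication_rate))
        } else 0L

        rows <- list()
        if (length(p_times) > 0) {
          kind <- c(rep("assessment", n_assess),
                    rep("medication", length(p_times) - n_assess))
          rows$primary <- tibble::tibble(patient_id = pid, nurse_id = primary,
                                         timestamp = p_times, kind = kind)
        }

        tag <- "clean"
        if (u_cross < config$p_cross_coverage && length(pool) > 1) {
          other <- setdiff(pool, primary)
          cross_nurse <- other[sample.int(length(other), 1)]
          kx <- stats::rpois(1, config$lambda_cross)
          if (kx > 0) {
            # brief visit: all signatures inside one random half hour
            span0 <- stats::runif(1, lo, max(lo, hi - 1800))
            x_times <- sort(unique(floor(stats::runif(kx, span0,
                                                      min(hi, span0 + 1800)))))
            rows$cross <- tibble::tibble(patient_id = pid,
                                         nurse_id = cross_nurse,
                                         timestamp = x_times,
                                         kind = "assessment")
            tag <- "cross_coverage"
          }
        }
        late <- NULL
        if (u_late < config$p_late_charting && k < ns &&
            shifts$window_end[k] == shifts$window_start[k + 1]) {
          nxt_lo <- we
          nxt_hi <- min(we + SECS_PER_HOUR, pat$admit + pat$los,
                        as.numeric(shifts$window_end[k + 1]))
          m <- stats::rpois(1, config$lambda_late)
          if (m > 0 && nxt_hi > nxt_lo) {
            l_times <- sort(unique(floor(stats::runif(m, nxt_lo, nxt_hi))))
            late <- tibble::tibble(patient_id = pid, nurse_id = primary,
                                   timestamp = l_times, kind = "assessment")
          }
        }
        # orientee duplicates the primary's time set exactly; drawn last so
        # enabling it never perturbs the draws above
        if (u_orientee < config$p_orientee && length(p_times) > 0 &&
            length(pool) > 1) {
          other <- setdiff(pool, primary)
          ori <- other[sample.int(length(other), 1)]
          rows$orientee <- tibble::tibble(patient_id = pid, nurse_id = ori,
                                          timestamp = p_times,
                                          kind = "assessment")
          tag <- "orientee"
        }
        list(primary = primary, rows = dplyr::bind_rows(rows), late = late,
             tag = tag)
      })

      ev[[k]] <- shift_out$rows
      if (!is.null(shift_out$late)) late_carry[[k]] <- shift_out$late
      true_nurse[k] <- shift_out$primary
      scen[k] <- shift_out$tag
      prev_primary <- shift_out$primary
    }

    # fold late-charting spillover into the receiving shift's event set and tag
    for (k in seq_len(ns)) {
      if (k > 1 && !is.null(late_carry[[k - 1]])) {
        ev[[k]] <- dplyr::bind_rows(ev[[k]], late_carry[[k - 1]])
        if (scen[k] == "clean") scen[k] <- "late_charting"
      }
      n_ev_k <- if (is.null(ev[[k]])) 0L else nrow(ev[[k]])
      if (n_ev_k == 0L) {
        true_nurse[k] <- NA_character_
        scen[k] <- "undocumented"
      }
    }

    events_l[[p]] <- dplyr::bind_rows(ev)
    truth_l[[p]] <- tibble::tibble(patient_id = pid,
                                   shift_date = shifts$shift_date,
                                   period = shifts$period,
                                   true_nurse_id = true_nurse,
                                   scenario = scen)
  }

  events <- dplyr::bind_rows(events_l)
  if (nrow(events) > 0) {
    events$timestamp <- as.POSIXct(events$timestamp, tz = "UTC",
                                   origin = "1970-01-01")
    events <- events[order(events$timestamp, events$patient_id,
                           events$nurse_id, events$kind), ]
  } else {
    events <- tibble::tibble(patient_id = character(),
                             nurse_id = character(),
                             timestamp = as.POSIXct(character(), tz = "UTC"),
                             kind = character())
  }
  structure(list(stays = dplyr::bind_rows(stays_l), events = events,
                 truth = dplyr::bind_rows(truth_l), config = config),
            class = "sim_bundle")
}

#' Ground-truth recovery of an assignment table
#'
#' A patient shift counts as recovered when the algorithm's output equals
#' the simulated truth: same nurse id, or both "none".
#'
#' @param assignments Assignment tibble from [assign_all()].
#' @param truth Truth tibble from [simulate_ehr()].
#' @return List with `overall` (recovery rate), `n`, and `by_scenario`
#'   (tibble `scenario,n,n_recovered,rate`).
#' @export
recovery_report <- function(assignments, truth) {
  j <- dplyr::full_join(truth, assignments,
                        by = c("patient_id", "shift_date", "period"))
  if (anyNA(j$scenario) || anyNA(j$category)) {
    rlang::abort("assignments and truth cover different patient shifts",
                 class = "nursetrace_input_error")
  }
  rec <- (is.na(j$primary_nurse_id) & is.na(j$true_nurse_id)) |
    (!is.na(j$primary_nurse_id) & !is.na(j$true_nurse_id) &
       j$primary_nurse_id == j$true_nurse_id)
  by_scen <- tibble::tibble(scenario = j$scenario, recovered = rec) |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(n = dplyr::n(), n_recovered = sum(.data$recovered),
                     rate = mean(.data$recovered), .groups = "drop")
  list(overall = mean(rec), n = length(rec), by_scenario = by_scen)
}

#' Write a simulation bundle to CSV files
#'
#' Writes `stays.csv`, `events.csv` and `truth.csv` under `dir`.
#'
#' @param bundle A `sim_bundle` from [simulate_ehr()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S")
  ev <- bundle$events
  ev$timestamp <- fmt(ev$timestamp)
  st <- bundle$stays
  st$icu_in <- fmt(st$icu_in)
  st$icu_out <- fmt(st$icu_out)
  tr <- bundle$truth
  tr$true_nurse_id <- ifelse(is.na(tr$true_nurse_id), "", tr$true_nurse_id)
  readr::write_csv(ev, file.path(dir, "events.csv"), progress = FALSE)
  readr::write_csv(st, file.path(dir, "stays.csv"), progress = FALSE)
  readr::write_csv(tr, file.path(dir, "truth.csv"), progress = FALSE)
  invisible(dir)
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("sim_bundle: %d stay(s), %d event(s), %d patient shift(s)\n",
              nrow(x$stays), nrow(x$events), nrow(x$truth)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (nm in names(unclass(x))) cat(sprintf("  %s: %s\n", nm, x[[nm]]))
  invisible(x)
}
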