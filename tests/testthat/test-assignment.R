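stats_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    nurse_id = vapply(rows, `[[`, "", 1),
    chart_count = vapply(rows, function(r) as.integer(r[[2]]), 1L),
    first_time = wall_time("2018-03-05T08:00:00"),
    last_time = wall_time("2018-03-05T08:00:00") +
      vapply(rows, function(r) as.numeric(r[[3]]), 1),
    interval_secs = vapply(rows, function(r) as.numeric(r[[3]]), 1)
  )
}

test_that("compute_stats derives counts and first-to-last intervals", {
  times <- tibble::tibble(
    nurse_id = c("A", "A", "A", "B"),
    timestamp = wall_time(c("2018-03-05T08:00:00", "2018-03-05T09:00:00",
                            "2018-03-05T17:00:00", "2018-03-05T12:00:00")))
  st <- compute_stats(times)
  a <- st[st$nurse_id == "A", ]
  expect_equal(a$chart_count, 3L)
  expect_equal(a$interval_secs, 9 * 3600)
  b <- st[st$nurse_id == "B", ]
  expect_equal(b$chart_count, 1L)
  expect_equal(b$interval_secs, 0)
  expect_equal(nrow(compute_stats(times[0, ])), 0)
})

test_that("step1_select: argmax by count, interval tie-break, residual tie -> none", {
  r <- step1_select(stats_tbl(list("A", 12, 3600), list("B", 3, 3600)))
  expect_equal(r$nurse_id, "A")
  expect_equal(r$mode, "max_count")

  r <- step1_select(stats_tbl(list("A", 5, 10 * 3600), list("B", 5, 2 * 3600)))
  expect_equal(r$nurse_id, "A")
  expect_equal(r$mode, "tie_broken")

  r <- step1_select(stats_tbl(list("A", 4, 6 * 3600), list("B", 4, 6 * 3600)))
  expect_true(is.na(r$nurse_id))
  expect_equal(r$mode, "tie_unbroken")

  r <- step1_select(stats_tbl(list("A", 2, 60)))
  expect_equal(r$mode, "sole_charter")

  r <- step1_select(compute_stats(tibble::tibble(
    nurse_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"))))
  expect_equal(r$mode, "no_charter")
  expect_true(is.na(r$nurse_id))
})

test_that("step-2 exclusion removes the prior contiguous shift's step-1 primary", {
  stay <- make_stay("p1", "2018-03-05T07:30:00", "2018-03-06T18:00:00")
  # shift 1: A sole charter; shift 2: A charts most but is excluded -> B;
  # shift 3: B (shift-2 step-1 primary is still A, so B is NOT excluded... )
  ev <- dplyr::bind_rows(
    make_events("p1", "A", sprintf("2018-03-05T%02d:00:00", 8:12)),
    make_events("p1", "A", sprintf("2018-03-05T%02d:10:00", 19:23)),
    make_events("p1", "A", c("2018-03-06T00:10:00", "2018-03-06T01:10:00",
                             "2018-03-06T02:10:00", "2018-03-06T03:10:00")),
    make_events("p1", "B", sprintf("2018-03-05T%02d:30:00", 20:23)),
    make_events("p1", "C", c("2018-03-05T21:45:00", "2018-03-05T22:45:00")),
    make_events("p1", "B", sprintf("2018-03-06T%02d:00:00", 8:11)))
  res <- assign_all(ev, stay)
  a <- res$assignments
  expect_equal(a$primary_nurse_id, c("A", "B", "B"))
  expect_equal(a$step1_nurse_id, c("A", "A", "B"))
  # shift 2: A had 9 unique times vs B's 4 and C's 2, but A was the prior
  # primary; among the remaining candidates B's count decides (category 2)
  expect_equal(a$category, c(1L, 2L, 1L))
})

test_that("a sole charter who was the prior primary yields category 6, none", {
  stay <- make_stay("p1", "2018-03-05T08:00:00", "2018-03-06T06:00:00")
  ev <- dplyr::bind_rows(
    make_events("p1", "A", sprintf("2018-03-05T%02d:00:00", 9:12)),
    make_events("p1", "A", c("2018-03-05T20:00:00", "2018-03-05T21:00:00")))
  a <- assign_all(ev, stay)$assignments
  expect_equal(a$primary_nurse_id, c("A", NA))
  expect_equal(a$category, c(1L, 6L))
  expect_equal(a$step1_nurse_id, c("A", "A"))
})

test_that("one nurse charting throughout a 3-window stay alternates into exclusion", {
  # with no other charter, unconditional exclusion (driven by step-1 priors)
  # blocks the same nurse in every window after the first
  stay <- make_stay("p1", "2018-03-05T08:00:00", "2018-03-06T18:00:00")
  ev <- make_events("p1", "A", c(
    sprintf("2018-03-05T%02d:00:00", 9:14),
    sprintf("2018-03-05T%02d:00:00", 20:23),
    sprintf("2018-03-06T%02d:00:00", 8:14)))
  a <- assign_all(ev, stay)$assignments
  expect_equal(a$step1_nurse_id, c("A", "A", "A"))
  expect_equal(a$primary_nurse_id, c("A", NA, NA))
  expect_equal(a$category, c(1L, 6L, 6L))
})

test_that("no exclusion across readmission gaps or across patients", {
  stays <- dplyr::bind_rows(
    make_stay("p1", "2018-03-05T08:00:00", "2018-03-05T18:00:00"),
    make_stay("p1", "2018-03-06T08:00:00", "2018-03-06T18:00:00"))
  ev <- make_events("p1", "A", c("2018-03-05T09:00:00", "2018-03-05T10:00:00",
                                 "2018-03-06T09:00:00", "2018-03-06T10:00:00"))
  a <- assign_all(ev, stays)$assignments
  # windows are a day apart: the same nurse may be primary in both
  expect_equal(a$primary_nurse_id, c("A", "A"))
  expect_equal(a$category, c(1L, 1L))
})

test_that("empty event table yields all category 4 and the partition holds", {
  stays <- dplyr::bind_rows(
    make_stay("p1", "2018-03-05T10:00:00", "2018-03-06T09:00:00"),
    make_stay("p2", "2018-03-05T11:00:00", "2018-03-05T12:00:00"))
  ev <- make_events(character(), character(), character())
  res <- assign_all(ev, stays)
  expect_equal(nrow(res$assignments), 4)
  expect_true(all(res$assignments$category == 4L))
  expect_equal(sum(res$summary$count), 4)
})

test_that("assign_all is deterministic and invariant to row order/duplication", {
  set.seed(99)
  fxs <- lapply(1:8, function(i) random_patient_fixture(sprintf("p%d", i)))
  events <- dplyr::bind_rows(lapply(fxs, `[[`, "events"))
  stays <- dplyr::bind_rows(lapply(fxs, `[[`, "stay"))
  base <- assign_all(events, stays)$assignments
  perm <- assign_all(events[sample(nrow(events)), ],
                     stays[sample(nrow(stays)), ])$assignments
  dup <- assign_all(dplyr::bind_rows(events, events[1:5, ]), stays)$assignments
  expect_identical(perm, base)
  expect_identical(dup, base)
})

test_that("invariants: exclusion safety, partition, nurse iff category 1-3", {
  set.seed(1234)
  for (i in 1:20) {
    fx <- random_patient_fixture("p1")
    a <- assign_all(fx$events, fx$stay)$assignments
    expect_true(all((a$category %in% 1:3) == !is.na(a$primary_nurse_id)))
    expect_equal(sum(assignment_summary(a)$count), nrow(a))
    if (nrow(a) > 1) {
      prior_step1 <- a$step1_nurse_id[-nrow(a)]
      fin <- a$primary_nurse_id[-1]
      both <- !is.na(prior_step1) & !is.na(fin)
      expect_false(any(fin[both] == prior_step1[both]))
    }
  }
})

test_that("adding events for the selected nurse never unseats them", {
  set.seed(555)
  for (i in 1:15) {
    fx <- random_patient_fixture("p1", n_windows = 1)
    a <- assign_all(fx$events, fx$stay)$assignments
    if (is.na(a$primary_nurse_id[1])) next
    winner <- a$primary_nurse_id[1]
    lo <- as.numeric(a$shift_date[1]) * 86400 + 7 * 3600
    extra_ts <- as.POSIXct(lo + sample(0:(12 * 3600 - 1), 3), tz = "UTC",
                           origin = "1970-01-01")
    more <- dplyr::bind_rows(fx$events, tibble::tibble(
      patient_id = "p1", nurse_id = winner, timestamp = extra_ts,
      kind = "assessment"))
    a2 <- assign_all(more, fx$stay)$assignments
    expect_equal(a2$primary_nurse_id[1], winner)
  }
})
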