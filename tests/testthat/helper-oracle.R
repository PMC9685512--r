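# Independent reference implementations used only as test oracles. These
# are written in a deliberately different style from the package (base-R
# loops, literal re-enumeration) so that agreement is informative.

# Literal step-1 selection: full sort of (count, interval), explicit tie
# scan. `stats` is a data.frame with nurse, count, interval.
bf_step1 <- function(stats) {
  if (nrow(stats) == 0) return(list(nurse = NA_character_, mode = "no_charter"))
  if (nrow(stats) == 1) return(list(nurse = stats$nurse[1], mode = "sole_charter"))
  ord <- order(-stats$count, -stats$interval)
  s <- stats[ord, ]
  n_count_tied <- sum(s$count == s$count[1])
  if (n_count_tied == 1) return(list(nurse = s$nurse[1], mode = "max_count"))
  tied <- s[seq_len(n_count_tied), ]
  n_int_tied <- sum(tied$interval == max(tied$interval))
  if (n_int_tied == 1) {
    return(list(nurse = tied$nurse[which.max(tied$interval)],
                mode = "tie_broken"))
  }
  list(nurse = NA_character_, mode = "tie_unbroken")
}

bf_mode_to_cat <- function(mode, any_charter) {
  if (mode == "sole_charter") return(1L)
  if (mode == "max_count") return(2L)
  if (mode == "tie_broken") return(3L)
  if (mode == "tie_unbroken") return(5L)
  if (any_charter) 6L else 4L
}

# Brute-force two-step run for ONE patient with ONE stay. Recomputes window
# membership, per-nurse unique times, step 1 and the exclusion re-run from
# raw events using base loops only. Returns a data.frame of final nurse and
# category per chronological shift.
bf_assign_patient <- function(events, icu_in, icu_out) {
  anchor <- function(t) { # index of 12h window containing time t
    floor((as.numeric(t) - 7 * 3600) / (12 * 3600))
  }
  w0 <- anchor(icu_in)
  w1 <- anchor(as.numeric(icu_out) - 1)
  widx <- seq(w0, w1)
  n <- length(widx)
  final <- character(n)
  category <- integer(n)
  step1 <- character(n)
  for (k in seq_len(n)) {
    ws <- widx[k] * 12 * 3600 + 7 * 3600
    we <- ws + 12 * 3600
    in_win <- as.numeric(events$timestamp) >= ws &
      as.numeric(events$timestamp) < we
    ev <- events[in_win, ]
    nurses <- unique(ev$nurse_id)
    stats <- data.frame(nurse = character(0), count = numeric(0),
                        interval = numeric(0))
    for (nu in nurses) {
      tt <- unique(as.numeric(ev$timestamp[ev$nurse_id == nu]))
      stats <- rbind(stats, data.frame(nurse = nu, count = length(tt),
                                       interval = max(tt) - min(tt)))
    }
    s1 <- bf_step1(stats)
    step1[k] <- s1$nurse
    excluded <- if (k > 1) step1[k - 1] else NA_character_
    if (!is.na(excluded)) {
      stats2 <- stats[stats$nurse != excluded, ]
      s2 <- bf_step1(stats2)
      final[k] <- s2$nurse
      category[k] <- bf_mode_to_cat(s2$mode, nrow(stats) > 0)
    } else {
      final[k] <- s1$nurse
      category[k] <- bf_mode_to_cat(s1$mode, nrow(stats) > 0)
    }
  }
  data.frame(widx = widx, final = final, category = category,
             step1 = step1, stringsAsFactors = FALSE)
}

# Clopper-Pearson oracle: direct inversion of binomial tail sums by
# vectorized bisection on pbinom (independent of the qbeta identity the
# package uses). 100 halvings of [0,1] -> ~8e-31 bracket width.
bf_clopper_pearson <- function(x, n, alpha = 0.05) {
  a2 <- alpha / 2
  lo_l <- rep(0, length(x)); hi_l <- rep(1, length(x))
  lo_h <- rep(0, length(x)); hi_h <- rep(1, length(x))
  for (i in 1:100) {
    # lower bound: P(X >= x | p) is increasing in p; solve = a2
    mid <- (lo_l + hi_l) / 2
    up <- 1 - pbinom(x - 1, n, mid) >= a2
    hi_l <- ifelse(up, mid, hi_l)
    lo_l <- ifelse(up, lo_l, mid)
    # upper bound: P(X <= x | p) is decreasing in p; solve = a2
    mid2 <- (lo_h + hi_h) / 2
    dn <- pbinom(x, n, mid2) <= a2
    hi_h <- ifelse(dn, mid2, hi_h)
    lo_h <- ifelse(dn, lo_h, mid2)
  }
  low <- ifelse(x == 0, 0, (lo_l + hi_l) / 2)
  high <- ifelse(x == n, 1, (lo_h + hi_h) / 2)
  list(low = low, high = high)
}

# Largest-remainder quota oracle: try every way of rounding each exact quota
# up or down is equivalent to floors + top-remainder increments; recompute
# it here by explicit remainder sorting with a stable order.
bf_quota <- function(shares, n_total) {
  exact <- shares * n_total
  q <- floor(exact)
  rem <- exact - q
  leftover <- n_total - sum(q)
  if (leftover > 0) {
    pri <- order(rem, decreasing = TRUE)
    # stable among equal remainders: order() is stable, keeps index order
    for (i in seq_len(leftover)) q[pri[i]] <- q[pri[i]] + 1
  }
  as.integer(q)
}
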