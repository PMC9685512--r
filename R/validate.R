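# Validation against chart review: stratified sampling of patient shifts,
# confusion matrix, and accuracy/precision with exact (Clopper-Pearson)
# binomial confidence intervals.

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided exact interval obtained by inverting binomial tail
#' probabilities, computed via the beta-quantile identity. The lower bound
#' is exactly 0 when `successes == 0` and the upper bound exactly 1 when
#' `successes == n`.
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, `>= 1`.
#' @param alpha Two-sided error rate (default 0.05 for a 95% CI).
#' @return Named numeric vector `c(low = , high = )`.
#' @examples
#' clopper_pearson(186, 200)
#' @export
clopper_pearson <- function(successes, n, alpha = 0.05) {
  if (length(successes) != 1 || length(n) != 1 || is.na(successes) ||
      is.na(n) || n < 1 || successes < 0 || successes > n ||
      successes != round(successes) || n != round(n)) {
    rlang::abort("clopper_pearson: need integer 0 <= successes <= n, n >= 1",
                 class = "nursetrace_input_error")
  }
  low <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  high <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(low = low, high = high)
}

#' Confusion matrix of algorithm output against chart review
#'
#' A reviewed shift is a true positive when the algorithm named a nurse and
#' review confirmed the same nurse; a false positive when the algorithm
#' named a nurse but review found a different nurse or none; a false
#' negative when the algorithm found none but review identified a nurse
#' (including nurses newly identified from record elements the algorithm
#' cannot see); a true negative when both found none.
#'
#' @param assignments Assignment tibble.
#' @param review Review-label tibble ([read_review()]).
#' @return A list of counts `tp`, `fp`, `fn`, `tn` (class
#'   `"confusion_matrix"`); they sum to the number of reviewed shifts.
#' @export
confusion <- function(assignments, review) {
  j <- dplyr::left_join(review, assignments,
                        by = c("patient_id", "shift_date", "period"))
  if (anyNA(j$category)) {
    miss <- j[is.na(j$category), ]
    rlang::abort(sprintf(
      "review labels refer to %d patient shift(s) with no algorithm result, e.g. %s %s %s",
      nrow(miss), miss$patient_id[1], miss$shift_date[1], miss$period[1]),
      class = "nursetrace_input_error")
  }
  algo_pos <- !is.na(j$primary_nurse_id)
  rev_pos <- !is.na(j$reviewed_nurse_id)
  cm <- list(
    tp = sum(algo_pos & rev_pos & j$primary_nurse_id == j$reviewed_nurse_id,
             na.rm = TRUE),
    fp = sum(algo_pos & (!rev_pos |
                           j$primary_nurse_id != j$reviewed_nurse_id),
             na.rm = TRUE),
    fn = sum(!algo_pos & rev_pos),
    tn = sum(!algo_pos & !rev_pos)
  )
  structure(cm, class = "confusion_matrix")
}

metric_estimate <- function(successes, n, alpha = 0.05) {
  ci <- clopper_pearson(successes, n, alpha)
  tibble::tibble(point = successes / n, ci_low = ci[["low"]],
                 ci_high = ci[["high"]], n = n)
}

#' Accuracy and precision with exact 95% CIs
#'
#' Accuracy is (TP + TN) / (TP + TN + FP + FN): the share of reviewed shifts
#' where the algorithm either named the correct primary nurse or correctly
#' found none. Precision is TP / (TP + FP): the share of nurse-naming calls
#' that named the correct nurse.
#'
#' @param cm A confusion matrix from [confusion()].
#' @param alpha Two-sided CI error rate.
#' @return A one-row tibble: `point`, `ci_low`, `ci_high`, `n`.
#' @examples
#' cm <- structure(list(tp = 184, fp = 11, fn = 3, tn = 2),
#'                 class = "confusion_matrix")
#' accuracy(cm)  # 0.93
#' precision(cm) # 0.944
#' @export
accuracy <- function(cm, alpha = 0.05) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0) {
    rlang::abort("accuracy undefined: empty confusion matrix",
                 class = "nursetrace_input_error")
  }
  metric_estimate(cm$tp + cm$tn, n, alpha)
}

#' @rdname accuracy
#' @export
precision <- function(cm, alpha = 0.05) {
  if (cm$tp + cm$fp == 0) {
    rlang::abort("precision undefined: algorithm made no positive calls",
                 class = "nursetrace_input_error")
  }
  metric_estimate(cm$tp, cm$tp + cm$fp, alpha)
}

#' Stratified sample of patient shifts for chart review
#'
#' Draws `n_total` patient shifts matching the proportion of shifts in each
#' of the six outcome categories. Per-category quotas are computed by
#' largest-remainder rounding (floor each exact quota, then hand out the
#' remaining units in order of largest fractional remainder, ties going to
#' the lower category number), so quotas always sum to `n_total`. Sampling
#' within a category is without replacement and reproducible by `seed`.
#'
#' @param assignments Assignment tibble.
#' @param n_total Total sample size (the validation study used 200).
#' @param seed Integer RNG seed.
#' @return The sampled assignment rows, with a `quota` attribute giving the
#'   per-category quotas.
#' @export
stratified_sample <- function(assignments, n_total, seed) {
  counts <- tabulate(assignments$category, nbins = 6L)
  quotas <- largest_remainder(counts / sum(counts), n_total)
  short <- which(quotas > counts)
  if (length(short) > 0) {
    rlang::abort(sprintf(
      "category %d has only %d shift(s) but a quota of %d",
      short[1], counts[short[1]], quotas[short[1]]),
      class = "nursetrace_input_error")
  }
  rng <- local_rng(seed)
  picked <- lapply(1:6, function(k) {
    idx <- which(assignments$category == k)
    if (quotas[k] == 0) return(integer(0))
    idx[sample.int(length(idx), quotas[k])]
  })
  on.exit(rng(), add = TRUE)
  out <- assignments[sort(unlist(picked)), ]
  attr(out, "quota") <- quotas
  out
}

# floor + distribute remainder by largest fractional part; ties -> lowest index
largest_remainder <- function(shares, n_total) {
  exact <- shares * n_total
  base <- floor(exact)
  rem <- n_total - sum(base)
  if (rem > 0) {
    frac <- exact - base
    give <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

# save/restore the global RNG state around a seeded draw
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Validate an assignment table against chart-review labels
#'
#' Convenience wrapper: confusion matrix plus accuracy and precision with
#' exact 95% CIs, in the long metric layout the `validate` command writes.
#'
#' @param assignments Assignment tibble.
#' @param review Review-label tibble.
#' @return A list with `confusion` and `metrics` (tibble
#'   `metric,point,ci_low,ci_high,n`).
#' @export
validate_assignments <- function(assignments, review) {
  cm <- confusion(assignments, review)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(accuracy(cm), metric = "accuracy", .before = 1),
    dplyr::mutate(precision(cm), metric = "precision", .before = 1)
  )
  list(confusion = cm, metrics = metrics)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (n = %d reviewed shifts)\n",
              x$tp + x$fp + x$fn + x$tn))
  cat(sprintf("  TP %d  FP %d\n  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}
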