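#' Per-comparison baseline differences
#'
#' For every comparison in the set, the baseline difference is the drug-arm
#' summary minus the control-arm summary, computed on the stored values at
#' reported precision (no internal re-rounding): a mean difference in the
#' characteristic's units for continuous characteristics, a difference in
#' percentage points for binary ones. The direction is the sign of that
#' difference, or `"missing"` when either arm lacks the characteristic.
#'
#' Standard errors accompany the differences for downstream pooling:
#' `sqrt(sd_d^2/n_d + sd_c^2/n_c)` for continuous characteristics and, in
#' percentage points, `100 * sqrt(p_d(1-p_d)/n_d + p_c(1-p_c)/n_c)` with
#' `p = pct/100` for binary ones. The binomial form uses the reported
#' percentages directly, so event counts are not required. A continuous
#' characteristic with a missing SD in either arm keeps its difference but
#' has `se = NA`.
#'
#' @param ts a [trial_set()].
#' @param characteristic one of `"age"`, `"male"`, `"ldl"`, `"bmi"`,
#'   `"dm"`, `"smoking"`, `"htn"`.
#' @param continuity if `TRUE`, binary-characteristic variances replace
#'   reported proportions of exactly 0 or 1 by `0.5/n` respectively
#'   `1 - 0.5/n`, so degenerate arms do not produce a zero standard error.
#' @return data.frame with columns `trial_id`, `drug`, `control`,
#'   `trial_class`, `characteristic`, `value`, `se`, `direction`.
#' @export
baseline_differences <- function(ts, characteristic, continuity = FALSE) {
  info <- char_info(characteristic)
  p <- comparison_pairs(ts)
  out <- p$key
  out$characteristic <- characteristic
  if (info$type == "continuous") {
    md <- p$drug[[info$mean_col]]; mc <- p$control[[info$mean_col]]
    sdd <- p$drug[[info$sd_col]];  sdc <- p$control[[info$sd_col]]
    out$value <- md - mc
    out$se <- sqrt(sdd^2 / p$drug$n + sdc^2 / p$control$n)
  } else {
    pd <- p$drug[[info$pct_col]] / 100
    pc <- p$control[[info$pct_col]] / 100
    out$value <- (pd - pc) * 100
    if (continuity) {
      pd_v <- pmin(pmax(pd, 0.5 / p$drug$n), 1 - 0.5 / p$drug$n)
      pc_v <- pmin(pmax(pc, 0.5 / p$control$n), 1 - 0.5 / p$control$n)
    } else {
      pd_v <- pd; pc_v <- pc
    }
    out$se <- 100 * sqrt(pd_v * (1 - pd_v) / p$drug$n +
                           pc_v * (1 - pc_v) / p$control$n)
  }
  out$direction <- difference_direction(out$value)
  rownames(out) <- NULL
  out
}

#' Per-comparison differences between reported standard deviations
#'
#' Drug-arm SD minus control-arm SD at reported precision, for the
#' continuous characteristics only. Under intact randomization the two
#' arms sample the same population, so SDs should differ only by chance;
#' a systematic preponderance of larger drug-arm SDs is a randomization-
#' integrity signal in its own right.
#'
#' @inheritParams baseline_differences
#' @param characteristic one of `"age"`, `"ldl"`, `"bmi"`.
#' @return data.frame as in [baseline_differences()], with `se` absent
#'   (`NA`): SD differences are described and sign-tested, not pooled.
#' @export
sd_differences <- function(ts, characteristic) {
  if (!characteristic %in% continuous_characteristics()) {
    stop("SD differences are defined for continuous characteristics only (",
         paste(continuous_characteristics(), collapse = ", "),
         "), not '", characteristic, "'", call. = FALSE)
  }
  info <- char_info(characteristic)
  p <- comparison_pairs(ts)
  out <- p$key
  out$characteristic <- characteristic
  out$value <- p$drug[[info$sd_col]] - p$control[[info$sd_col]]
  out$se <- NA_real_
  out$direction <- difference_direction(out$value)
  rownames(out) <- NULL
  out
}

difference_direction <- function(value) {
  ifelse(is.na(value), "missing",
         ifelse(value < 0, "negative",
                ifelse(value > 0, "positive", "zero")))
}

#' Tally the directions of a collection of differences
#'
#' Counts negative / zero / positive differences (missing ones are
#' excluded from the tallies but reported) and records the range of the
#' non-missing values.
#'
#' @param diffs data.frame from [baseline_differences()] or
#'   [sd_differences()]; all rows must share one characteristic.
#' @return one-row data.frame: `characteristic`, `n_neg`, `n_zero`,
#'   `n_pos`, `n_missing`, `range_min`, `range_max`.
#' @export
classify_directions <- function(diffs) {
  ch <- unique(diffs$characteristic)
  if (length(ch) != 1L) {
    stop("classify_directions expects differences of a single ",
         "characteristic; got: ", paste(ch, collapse = ", "), call. = FALSE)
  }
  ok <- !is.na(diffs$value)
  if (!any(ok)) {
    stop("no non-missing differences to classify for characteristic '",
         ch, "'", call. = FALSE)
  }
  data.frame(
    characteristic = ch,
    n_neg = sum(diffs$direction == "negative"),
    n_zero = sum(diffs$direction == "zero"),
    n_pos = sum(diffs$direction == "positive"),
    n_missing = sum(diffs$direction == "missing"),
    range_min = min(diffs$value[ok]),
    range_max = max(diffs$value[ok]),
    stringsAsFactors = FALSE
  )
}

#' Exact one-sided sign test on imbalance directions
#'
#' Tests whether imbalances fall in their majority direction more often
#' than chance allows. Ties (zero differences) and missing differences
#' are excluded, leaving `n_effective = n_neg + n_pos` informative trials;
#' with `k_max = max(n_neg, n_pos)` the p-value is the exact upper tail
#' \deqn{p = \sum_{k = k_{max}}^{n} \binom{n}{k} / 2^{n},}
#' the probability of at least `k_max` same-direction imbalances among
#' `n_effective` fair coin flips. The test is one-sided toward the
#' observed majority; when the counts tie, `k_max = n_neg = n_pos` and
#' `p >= 0.5` follows automatically.
#'
#' @param n_neg number of negative differences, or a one-row data.frame
#'   from [classify_directions()].
#' @param n_pos number of positive differences (ignored when `n_neg` is a
#'   direction-count row).
#' @return An object of class `sign_test`: list with `n_effective`,
#'   `k_max`, `p_value` (full precision; display-round with
#'   [round_half_up()] at 3 decimals).
#' @export
#' @examples
#' sign_test(9, 20)   # p = 0.031
#' sign_test(18, 17)  # p = 0.500 exactly
sign_test <- function(n_neg, n_pos = NULL) {
  if (is.data.frame(n_neg)) {
    counts <- n_neg
    n_neg <- counts$n_neg
    n_pos <- counts$n_pos
  }
  stopifnot(length(n_neg) == 1L, length(n_pos) == 1L)
  if (is.na(n_neg) || is.na(n_pos) || n_neg < 0 || n_pos < 0 ||
      n_neg != round(n_neg) || n_pos != round(n_pos)) {
    stop("n_neg and n_pos must be non-negative integers", call. = FALSE)
  }
  n_eff <- n_neg + n_pos
  if (n_eff == 0L) {
    stop("sign test undefined: no informative (non-tied, non-missing) ",
         "differences", call. = FALSE)
  }
  k_max <- max(n_neg, n_pos)
  p <- stats::pbinom(k_max - 1, n_eff, 0.5, lower.tail = FALSE)
  structure(list(n_effective = as.integer(n_eff), k_max = as.integer(k_max),
                 p_value = p),
            class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat("Exact one-sided sign test: ", x$k_max, "/", x$n_effective,
      " in majority direction, p = ",
      formatC(round_half_up(x$p_value, 3), format = "f", digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Direction table for a set of characteristics
#'
#' Machine twin of a range-and-direction table: one row per
#' characteristic with the range of differences, the direction tallies
#' and the exact sign-test p-value.
#'
#' @param ts a [trial_set()].
#' @param characteristics characteristics to tabulate; defaults to all
#'   seven for `what = "baseline"` and the three continuous ones for
#'   `what = "sd"`.
#' @param what `"baseline"` for differences of means/percentages,
#'   `"sd"` for differences of standard deviations.
#' @return data.frame: characteristic, scope, n, range_min, range_max,
#'   n_neg, n_zero, n_pos, n_missing, sign_p.
#' @export
direction_table <- function(ts, characteristics = NULL,
                            what = c("baseline", "sd")) {
  what <- match.arg(what)
  if (is.null(characteristics)) {
    characteristics <- if (what == "sd") continuous_characteristics() else
      baseline_characteristics()$characteristic
  }
  rows <- lapply(characteristics, function(ch) {
    diffs <- if (what == "sd") sd_differences(ts, ch) else
      baseline_differences(ts, ch)
    n <- nrow(diffs)
    dc <- tryCatch(classify_directions(diffs), error = function(e) NULL)
    if (is.null(dc)) {
      return(data.frame(characteristic = ch, scope = ts$scope, n = n,
                        range_min = NA_real_, range_max = NA_real_,
                        n_neg = 0L, n_zero = 0L, n_pos = 0L, n_missing = n,
                        sign_p = NA_real_, stringsAsFactors = FALSE))
    }
    p <- if (dc$n_neg + dc$n_pos >= 1L) sign_test(dc)$p_value else NA_real_
    data.frame(characteristic = ch, scope = ts$scope, n = n,
               range_min = dc$range_min, range_max = dc$range_max,
               n_neg = dc$n_neg, n_zero = dc$n_zero, n_pos = dc$n_pos,
               n_missing = dc$n_missing, sign_p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
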