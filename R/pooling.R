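#' Fixed-effect inverse-variance pooling of baseline differences
#'
#' Under intact randomization every trial estimates the same quantity --
#' zero expected baseline difference -- so the fixed-effect model is the
#' appropriate one and any between-trial heterogeneity is itself a
#' diagnostic signal. Weights are `w_i = 1/se_i^2`; the pooled estimate is
#' `sum(w * theta) / sum(w)` with standard error `1/sqrt(sum(w))` and a
#' 95% CI at `estimate +/- 1.96 * se`. Heterogeneity is summarized by
#' Cochran's `Q = sum(w * (theta - estimate)^2)` with `df = k - 1`, its
#' chi-square upper-tail p-value, and `I2 = max(0, (Q - df)/Q) * 100`,
#' with a test-based 95% CI from [i2_confidence_interval()].
#'
#' @param value per-trial differences (any common unit).
#' @param se per-trial standard errors, same unit.
#' @param trial_id optional labels used in error messages.
#' @return An object of class `pooled_estimate`: list with `k`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `Q`, `df`, `p_Q`, `I2`,
#'   `I2_ci_low`, `I2_ci_high`. With a single trial the estimate and CI
#'   are the trial's own; `Q = df = 0` and the I2 fields are `NA`
#'   (pooling language is reserved for `k >= 2`).
#' @export
#' @examples
#' pool_fixed(c(1, 3), c(1, 1)) # estimate 2, Q = 2, I2 = 50%
pool_fixed <- function(value, se, trial_id = NULL) {
  if (is.null(trial_id)) trial_id <- as.character(seq_along(value))
  keep <- !is.na(value) & !is.na(se)
  value <- value[keep]; se <- se[keep]; trial_id <- trial_id[keep]
  k <- length(value)
  if (k == 0L) {
    stop("no trials with both a difference and a standard error to pool",
         call. = FALSE)
  }
  if (any(se <= 0)) {
    stop("degenerate (non-positive) standard error for trial '",
         trial_id[which(se <= 0)[1]],
         "'; consider the continuity adjustment", call. = FALSE)
  }
  w <- 1 / se^2
  est <- sum(w * value) / sum(w)
  se_p <- 1 / sqrt(sum(w))
  Q <- sum(w * (value - est)^2)
  df <- k - 1L
  if (k >= 2L) {
    p_Q <- stats::pchisq(Q, df, lower.tail = FALSE)
    I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
    ci <- i2_confidence_interval(Q, k)
  } else {
    Q <- 0; p_Q <- NA_real_; I2 <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  structure(list(k = k, estimate = est, se = se_p,
                 ci_low = est - 1.96 * se_p, ci_high = est + 1.96 * se_p,
                 Q = Q, df = df, p_Q = p_Q, I2 = I2,
                 I2_ci_low = ci[1], I2_ci_high = ci[2]),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Fixed-effect pooled estimate (k = %d): %.4f (95%% CI %.4f to %.4f)\n",
              x$k, x$estimate, x$ci_low, x$ci_high))
  if (!is.na(x$I2)) {
    cat(sprintf("  Q = %.4f (df = %d, p = %.4f), I2 = %.1f%%", x$Q, x$df,
                x$p_Q, x$I2))
    if (!is.na(x$I2_ci_low)) {
      cat(sprintf(" (95%% CI %.1f to %.1f)", x$I2_ci_low, x$I2_ci_high))
    }
    cat("\n")
  }
  invisible(x)
}

#' Test-based 95% confidence interval for I-squared
#'
#' The interval is built on the log of `H = sqrt(Q/(k-1))` (floored at 1).
#' The standard error of `ln H` is
#' `0.5 * (ln Q - ln(k-1)) / (sqrt(2Q) - sqrt(2k-3))` when `Q >= k`, and
#' `sqrt(1/(2(k-2)) * (1 - 1/(3(k-2)^2)))` otherwise. Normal 95% bounds on
#' `ln H` are mapped through `I2 = 100 * (H^2 - 1)/H^2`, with `H` bounds
#' floored at 1 so the interval is truncated to [0, 100]. When `Q < k`
#' and `k <= 3` the small-sample formula is undefined and both bounds are
#' `NA`.
#'
#' @param Q Cochran's heterogeneity statistic (`>= 0`).
#' @param k number of pooled trials (`>= 2`).
#' @return numeric length-2 vector `c(low, high)` in percent, or `NA`s
#'   when undefined.
#' @export
i2_confidence_interval <- function(Q, k) {
  stopifnot(length(Q) == 1L, length(k) == 1L)
  if (is.na(Q) || is.na(k) || k < 2 || Q < 0) return(c(NA_real_, NA_real_))
  if (Q >= k) {
    se_ln_h <- 0.5 * (log(Q) - log(k - 1)) / (sqrt(2 * Q) - sqrt(2 * k - 3))
  } else {
    if (k <= 3) return(c(NA_real_, NA_real_))
    se_ln_h <- sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  }
  ln_h <- log(max(1, sqrt(Q / (k - 1))))
  h_bounds <- pmax(1, exp(ln_h + c(-1, 1) * 1.96 * se_ln_h))
  100 * (h_bounds^2 - 1) / h_bounds^2
}

#' Pool baseline differences for every characteristic
#'
#' Complete-case per characteristic: trials not reporting a
#' characteristic (or lacking the SDs needed for its standard error) are
#' omitted from that characteristic's pool only. Continuous
#' characteristics are pooled as mean differences in their own units;
#' binary characteristics as risk differences on the proportion scale
#' (reported percentage points / 100), matching how portfolio-level
#' baseline tables print them.
#'
#' @param ts a [trial_set()].
#' @param characteristics subset of characteristics; defaults to all 7.
#' @param continuity passed to [baseline_differences()] for binary
#'   characteristics.
#' @return data.frame, one row per characteristic with at least one
#'   poolable trial: characteristic, scope, measure ("MD"/"RD"), k,
#'   estimate, se, ci_low, ci_high, Q, df, p_Q, I2, I2_ci_low, I2_ci_high.
#' @export
pool_all <- function(ts, characteristics = NULL, continuity = FALSE) {
  if (is.null(characteristics)) {
    characteristics <- baseline_characteristics()$characteristic
  }
  chars <- baseline_characteristics()
  rows <- lapply(characteristics, function(ch) {
    type <- chars$type[chars$characteristic == ch]
    d <- baseline_differences(ts, ch, continuity = continuity)
    value <- d$value; se <- d$se
    if (type == "binary") { value <- value / 100; se <- se / 100 }
    if (!any(!is.na(value) & !is.na(se))) return(NULL)
    p <- pool_fixed(value, se, trial_id = d$trial_id)
    data.frame(characteristic = ch, scope = ts$scope,
               measure = if (type == "binary") "RD" else "MD",
               k = p$k, estimate = p$estimate, se = p$se,
               ci_low = p$ci_low, ci_high = p$ci_high,
               Q = p$Q, df = p$df, p_Q = p$p_Q, I2 = p$I2,
               I2_ci_low = p$I2_ci_low, I2_ci_high = p$I2_ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(characteristic = character(), scope = character(),
                      measure = character(), k = integer(),
                      estimate = numeric(), se = numeric(),
                      ci_low = numeric(), ci_high = numeric(), Q = numeric(),
                      df = integer(), p_Q = numeric(), I2 = numeric(),
                      I2_ci_low = numeric(), I2_ci_high = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
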