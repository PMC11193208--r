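#' Pooled standard deviation across trials
#'
#' Degrees-of-freedom-weighted root mean square of per-trial SDs:
#' `sqrt(sum((n_i - 1) * sd_i^2) / sum(n_i - 1))`. Equals the common SD
#' when all contributing SDs are equal.
#'
#' @param sd per-trial standard deviations (`>= 0`).
#' @param n per-trial arm sizes (`>= 2`).
#' @param trial_id optional labels for error messages.
#' @return list: `value` (pooled SD), `k` (trials contributing),
#'   `total_df` (`sum(n - 1)`).
#' @export
#' @examples
#' pooled_sd(c(2, 4), c(5, 5)) # sqrt(10)
pooled_sd <- function(sd, n, trial_id = NULL) {
  if (is.null(trial_id)) trial_id <- as.character(seq_along(sd))
  keep <- !is.na(sd) & !is.na(n)
  sd <- sd[keep]; n <- n[keep]; trial_id <- trial_id[keep]
  if (!length(sd)) stop("no SDs to pool", call. = FALSE)
  if (any(sd < 0)) stop("negative SD", call. = FALSE)
  if (any(n < 2)) {
    stop("arm size below 2 (no degrees of freedom) for trial '",
         trial_id[which(n < 2)[1]], "'", call. = FALSE)
  }
  df <- n - 1
  list(value = sqrt(sum(df * sd^2) / sum(df)), k = length(sd),
       total_df = sum(df))
}

#' Compare the drug-arm and control-arm SD collections
#'
#' A systematic tendency of one arm to have larger spreads shows up as a
#' mean difference between the two collections of per-trial SDs. The
#' default treats the collections as two groups and runs Welch's unpaired
#' t-test on them; `mode = "paired"` instead tests the within-trial SD
#' differences, exploiting the structural pairing of arms within trials.
#' Only trials with both SDs present contribute.
#'
#' @param drug_sd,control_sd paired per-trial SD values (equal length).
#' @param mode `"welch"` (unpaired, default) or `"paired"`.
#' @return list: `t`, `df`, `p` (two-sided), `mode`, `k` (usable pairs),
#'   `mean_drug`, `mean_control`.
#' @export
compare_sd_collections <- function(drug_sd, control_sd,
                                   mode = c("welch", "paired")) {
  mode <- match.arg(mode)
  stopifnot(length(drug_sd) == length(control_sd))
  keep <- !is.na(drug_sd) & !is.na(control_sd)
  d <- drug_sd[keep]; c_ <- control_sd[keep]
  if (length(d) < 2L) {
    stop("need at least 2 comparisons with SDs in both arms", call. = FALSE)
  }
  if (mode == "welch" && stats::var(d) + stats::var(c_) == 0) {
    # identical constant collections: no variability to test against
    tt <- list(statistic = c(t = 0), parameter = c(df = 2 * (length(d) - 1)),
               p.value = 1)
  } else if (mode == "paired" && stats::var(d - c_) == 0) {
    # constant within-trial differences: t is 0 or +/-Inf by sign
    m <- mean(d - c_)
    tt <- list(statistic = c(t = if (m == 0) 0 else sign(m) * Inf),
               parameter = c(df = length(d) - 1),
               p.value = if (m == 0) 1 else 0)
  } else if (mode == "welch") {
    tt <- stats::t.test(d, c_, var.equal = FALSE)
  } else {
    tt <- stats::t.test(d, c_, paired = TRUE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mode = mode, k = length(d),
       mean_drug = mean(d), mean_control = mean(c_))
}

#' Variance-ratio test for equal spread in one trial
#'
#' With only summary statistics available, equality of the two arms'
#' variances is tested by the F ratio of the larger to the smaller sample
#' variance under normality, with numerator degrees of freedom from the
#' larger-variance arm; the two-sided p-value is twice the smaller F tail
#' (capped at 1). This is the aggregate-data surrogate for Levene's test;
#' [levene_test()] provides the individual-level original for
#' cross-validation on simulated data.
#'
#' @param sd1,n1 SD and size of arm 1 (`sd > 0`, `n >= 2`).
#' @param sd2,n2 SD and size of arm 2.
#' @return An object of class `variance_test`: list with `statistic`
#'   (F `>= 1`), `df1`, `df2`, `p_value`, and `larger` (`"arm1"`,
#'   `"arm2"` or `"none"`).
#' @export
#' @examples
#' variance_equality_test(2, 31, 1, 31) # F = 4
variance_equality_test <- function(sd1, n1, sd2, n2) {
  stopifnot(length(sd1) == 1L, length(sd2) == 1L)
  if (is.na(sd1) || is.na(sd2) || is.na(n1) || is.na(n2)) {
    stop("missing inputs to variance_equality_test", call. = FALSE)
  }
  if (n1 < 2 || n2 < 2) stop("arm sizes must be >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) {
    stop("degenerate (zero) SD: variance ratio undefined", call. = FALSE)
  }
  if (sd1 >= sd2) {
    f <- sd1^2 / sd2^2; df1 <- n1 - 1; df2 <- n2 - 1
    larger <- if (sd1 > sd2) "arm1" else "none"
  } else {
    f <- sd2^2 / sd1^2; df1 <- n2 - 1; df2 <- n1 - 1
    larger <- "arm2"
  }
  p <- min(1, 2 * min(stats::pf(f, df1, df2),
                      stats::pf(f, df1, df2, lower.tail = FALSE)))
  structure(list(statistic = f, df1 = df1, df2 = df2, p_value = p,
                 larger = larger),
            class = "variance_test")
}

#' @export
print.variance_test <- function(x, ...) {
  cat(sprintf("Variance-ratio test: F(%d, %d) = %.4f, two-sided p = %.4f\n",
              x$df1, x$df2, x$statistic, x$p_value))
  invisible(x)
}

#' Levene's test on individual-level data
#'
#' One-way ANOVA of the absolute deviations from the group means
#' (Levene's original mean-centred form). Available when individual data
#' are retained by the simulator, to cross-validate the summary-data
#' variance-ratio surrogate.
#'
#' @param values numeric vector of individual observations.
#' @param groups group labels, same length.
#' @return list: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
levene_test <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  centers <- tapply(values, groups, mean)
  z <- abs(values - centers[groups])
  fit <- stats::anova(stats::lm(z ~ groups))
  list(statistic = fit[1, "F value"], df1 = fit[1, "Df"],
       df2 = fit[2, "Df"], p_value = fit[1, "Pr(>F)"])
}

#' Per-comparison variance-ratio tests for a trial set
#'
#' @param ts a [trial_set()].
#' @param characteristics continuous characteristics to test; default all
#'   three.
#' @return data.frame: trial_id, control, characteristic, statistic, df1,
#'   df2, p_value; comparisons lacking an SD (or with a zero SD) in
#'   either arm are omitted.
#' @export
variance_test_table <- function(ts, characteristics = NULL) {
  if (is.null(characteristics)) characteristics <- continuous_characteristics()
  p <- comparison_pairs(ts)
  rows <- list()
  for (ch in characteristics) {
    info <- char_info(ch)
    sdd <- p$drug[[info$sd_col]]; sdc <- p$control[[info$sd_col]]
    for (i in seq_len(nrow(p$key))) {
      if (is.na(sdd[i]) || is.na(sdc[i]) || sdd[i] <= 0 || sdc[i] <= 0) next
      vt <- variance_equality_test(sdd[i], p$drug$n[i], sdc[i], p$control$n[i])
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = p$key$trial_id[i], control = p$key$control[i],
        characteristic = ch, statistic = vt$statistic, df1 = vt$df1,
        df2 = vt$df2, p_value = vt$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(trial_id = character(), control = character(),
                      characteristic = character(), statistic = numeric(),
                      df1 = numeric(), df2 = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a collection of p-values
#'
#' Decile histogram ([0, 0.1), ..., [0.9, 1]) plus the count and fraction
#' strictly below a threshold. Under a true null with continuous test
#' statistics the p-values are uniform, so a left-skewed histogram or an
#' excess below 0.05 indicates systematic differences.
#'
#' @param p p-values in (0, 1].
#' @param threshold flag level, default 0.05.
#' @return list: `histogram` (data.frame bin_low, bin_high, count),
#'   `n_below`, `fraction_below`, `threshold`, `n`.
#' @export
pvalue_distribution <- function(p, threshold = 0.05) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values to summarize", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  breaks <- seq(0, 1, by = 0.1)
  bin <- cut(p, breaks, right = FALSE, include.lowest = TRUE)
  # cut(right = FALSE) leaves p = 1 unbinned; it belongs to [0.9, 1]
  bin[p == 1] <- levels(bin)[10]
  counts <- as.integer(table(bin))
  list(histogram = data.frame(bin_low = breaks[-11], bin_high = breaks[-1],
                              count = counts),
       n_below = sum(p < threshold),
       fraction_below = sum(p < threshold) / length(p),
       threshold = threshold, n = length(p))
}

#' Pooled-SD table per characteristic
#'
#' For each continuous characteristic, the pooled SD of the drug arms and
#' of the control arms (over comparisons reporting the SD in both arms,
#' so the two pools cover the same trials), and the t-test comparing the
#' two SD collections.
#'
#' @param ts a [trial_set()].
#' @param characteristics continuous characteristics; default all three.
#' @param mode t-test mode, see [compare_sd_collections()].
#' @return data.frame: characteristic, scope, k, pooled_sd_drug,
#'   pooled_sd_control, t, df, t_p, mode.
#' @export
pooled_sd_table <- function(ts, characteristics = NULL,
                            mode = c("welch", "paired")) {
  mode <- match.arg(mode)
  if (is.null(characteristics)) characteristics <- continuous_characteristics()
  p <- comparison_pairs(ts)
  rows <- lapply(characteristics, function(ch) {
    info <- char_info(ch)
    sdd <- p$drug[[info$sd_col]]; sdc <- p$control[[info$sd_col]]
    keep <- !is.na(sdd) & !is.na(sdc)
    if (sum(keep) < 2L) return(NULL)
    psd_d <- pooled_sd(sdd[keep], p$drug$n[keep])
    psd_c <- pooled_sd(sdc[keep], p$control$n[keep])
    tt <- compare_sd_collections(sdd[keep], sdc[keep], mode = mode)
    data.frame(characteristic = ch, scope = ts$scope, k = sum(keep),
               pooled_sd_drug = psd_d$value, pooled_sd_control = psd_c$value,
               t = tt$t, df = tt$df, t_p = tt$p, mode = mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(characteristic = character(), scope = character(),
                      k = integer(), pooled_sd_drug = numeric(),
                      pooled_sd_control = numeric(), t = numeric(),
                      df = numeric(), t_p = numeric(), mode = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
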