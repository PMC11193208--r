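#' Per-trial log odds ratio with continuity handling
#'
#' Effect of drug vs control on a binary outcome from the 2x2 table of
#' events. If any cell is zero, 0.5 is added to all four cells and the
#' `corrected` flag is set; trials with zero events in both arms (or all
#' events in both arms) carry no information about the odds ratio and are
#' marked excluded with a reason.
#'
#' @param e_d,n_d events and analyzed sample size in the drug arm.
#' @param e_c,n_c events and analyzed sample size in the control arm.
#' @return list: `effect` (log OR), `variance` (sum of reciprocal cells),
#'   `corrected` (logical), `excluded` (logical), `reason` (character or
#'   `NA`).
#' @export
#' @examples
#' trial_log_or(20, 100, 10, 100) # log(2.25)
trial_log_or <- function(e_d, n_d, e_c, n_c) {
  stopifnot(length(e_d) == 1L)
  if (anyNA(c(e_d, n_d, e_c, n_c))) {
    return(list(effect = NA_real_, variance = NA_real_, corrected = NA,
                excluded = TRUE, reason = "missing counts"))
  }
  if (e_d < 0 || e_c < 0 || e_d > n_d || e_c > n_c) {
    stop("event counts must satisfy 0 <= events <= n in each arm",
         call. = FALSE)
  }
  if (e_d == 0 && e_c == 0) {
    return(list(effect = NA_real_, variance = NA_real_, corrected = NA,
                excluded = TRUE, reason = "no events in either arm"))
  }
  if (e_d == n_d && e_c == n_c) {
    return(list(effect = NA_real_, variance = NA_real_, corrected = NA,
                excluded = TRUE, reason = "all events in both arms"))
  }
  cells <- c(e_d, n_d - e_d, e_c, n_c - e_c)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(effect = log((cells[1] * cells[4]) / (cells[3] * cells[2])),
       variance = sum(1 / cells), corrected = corrected,
       excluded = FALSE, reason = NA_character_)
}

#' Convert a percent LDL-c change to an absolute change
#'
#' Trials sometimes report the LDL-c change from baseline as a
#' percentage; the absolute change is `baseline_mean * pct_change / 100`
#' in mg/dl.
#'
#' @param baseline_mean baseline LDL-c mean in mg/dl (`> 0`).
#' @param pct_change percent change (negative for reductions).
#' @return absolute change in mg/dl.
#' @export
#' @examples
#' percent_to_absolute_change(100, -60) # -60 mg/dl
percent_to_absolute_change <- function(baseline_mean, pct_change) {
  if (anyNA(baseline_mean) || any(baseline_mean <= 0)) {
    stop("baseline LDL-c mean must be present and positive for the ",
         "percent-to-absolute conversion", call. = FALSE)
  }
  baseline_mean * pct_change / 100
}

#' Per-trial difference in LDL-c change
#'
#' Drug-arm change minus control-arm change in mg/dl, with sampling
#' variance `sd_d^2/n_d + sd_c^2/n_c`.
#'
#' @param change_d,sd_d,n_d drug-arm change mean, change SD, analyzed n.
#' @param change_c,sd_c,n_c control-arm equivalents.
#' @return list: `effect`, `variance`, `excluded`, `reason`.
#' @export
ldl_effect <- function(change_d, sd_d, n_d, change_c, sd_c, n_c) {
  if (anyNA(c(change_d, sd_d, n_d, change_c, sd_c, n_c))) {
    return(list(effect = NA_real_, variance = NA_real_, excluded = TRUE,
                reason = "missing LDL-c change mean or SD"))
  }
  if (sd_d < 0 || sd_c < 0 || n_d < 1 || n_c < 1) {
    stop("invalid LDL-c change summaries", call. = FALSE)
  }
  list(effect = change_d - change_c,
       variance = sd_d^2 / n_d + sd_c^2 / n_c,
       excluded = FALSE, reason = NA_character_)
}

#' Per-trial outcome effects for a trial set
#'
#' Builds the regressand table for one outcome: log odds ratios for the
#' binary outcomes (`mace`, `sae`, `any_ae`, `mortality`) or the
#' difference in LDL-c change (`ldl_reduction`). Trials that cannot
#' contribute are kept with `excluded = TRUE` and a reason.
#'
#' @param ts a [trial_set()] with an outcome table.
#' @param outcome one of `"ldl_reduction"`, `"mace"`, `"sae"`, `"any_ae"`,
#'   `"mortality"`.
#' @return data.frame: trial_id, control, trial_class, outcome, effect,
#'   variance, corrected, excluded, reason.
#' @export
trial_effects <- function(ts, outcome) {
  reg <- outcome_registry()
  if (!outcome %in% reg$outcome) {
    stop("unknown outcome '", outcome, "'; expected one of: ",
         paste(reg$outcome, collapse = ", "), call. = FALSE)
  }
  if (is.null(ts$outcomes)) {
    stop("trial set has no outcome table", call. = FALSE)
  }
  oc <- ts$outcomes
  key <- paste(oc$trial_id, oc$control, sep = "\r")
  d <- oc[oc$arm == "drug", ]; c_ <- oc[oc$arm == "control", ]
  keys <- unique(key)
  d <- d[match(keys, paste(d$trial_id, d$control, sep = "\r")), ]
  c_ <- c_[match(keys, paste(c_$trial_id, c_$control, sep = "\r")), ]
  base <- comparison_pairs(ts)$key
  cls <- base$trial_class[match(paste(d$trial_id, d$control, sep = "\r"),
                                paste(base$trial_id, base$control,
                                      sep = "\r"))]
  rows <- lapply(seq_along(keys), function(i) {
    if (outcome == "ldl_reduction") {
      eff <- ldl_effect(d$ldl_change_mean[i], d$ldl_change_sd[i],
                        d$n_analyzed[i], c_$ldl_change_mean[i],
                        c_$ldl_change_sd[i], c_$n_analyzed[i])
      eff$corrected <- NA
    } else {
      col <- reg$count_col[reg$outcome == outcome]
      eff <- trial_log_or(d[[col]][i], d$n_analyzed[i],
                          c_[[col]][i], c_$n_analyzed[i])
    }
    data.frame(trial_id = d$trial_id[i], control = d$control[i],
               trial_class = cls[i], outcome = outcome,
               effect = eff$effect, variance = eff$variance,
               corrected = eff$corrected, excluded = eff$excluded,
               reason = eff$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate random-effects meta-regression (DerSimonian-Laird)
#'
#' Regresses per-trial effects on one trial-level moderator with a
#' method-of-moments between-trial variance. With fixed weights
#' `w_i = 1/v_i` and design `X = (1, x)`, the residual heterogeneity
#' statistic `Q_E` gives
#' `tau2 = max(0, (Q_E - (k - 2)) / (tr(W) - tr((X'WX)^-1 X'W^2X)))`;
#' the slope is then re-estimated by weighted least squares with weights
#' `1/(v_i + tau2)`. The default CI is normal-based
#' (`beta +/- 1.96 se`); `ci_method = "knha"` applies the Knapp-Hartung
#' adjustment (t quantile with `k - 2` df and variance scaled by the
#' standardized residual mean square).
#'
#' @param effect per-trial effects (log OR or mg/dl).
#' @param variance per-trial sampling variances (`> 0`).
#' @param moderator per-trial moderator values (baseline differences).
#' @param ci_method `"z"` (default) or `"knha"`.
#' @return An object of class `meta_regression`: list with `k`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p_value`, `tau2`, `intercept`,
#'   `method` ("DL"), `ci_method`.
#' @export
meta_regress <- function(effect, variance, moderator,
                         ci_method = c("z", "knha")) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(effect) & !is.na(variance) & !is.na(moderator)
  y <- effect[keep]; v <- variance[keep]; x <- moderator[keep]
  k <- length(y)
  if (k < 3L) {
    stop("meta-regression needs at least 3 trials with effect, variance ",
         "and moderator; got ", k, call. = FALSE)
  }
  if (any(v <= 0)) stop("sampling variances must be positive", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("moderator is constant across trials (collinear with the ",
         "intercept)", call. = FALSE)
  }
  X <- cbind(1, x)
  w <- 1 / v
  xtwx <- crossprod(X, w * X)
  b_fixed <- solve(xtwx, crossprod(X, w * y))
  qe <- sum(w * (y - X %*% b_fixed)^2)
  trace_p <- sum(w) - sum(diag(solve(xtwx, crossprod(X, w^2 * X))))
  tau2 <- max(0, (qe - (k - 2)) / trace_p)

  ws <- 1 / (v + tau2)
  xtwsx <- crossprod(X, ws * X)
  b <- solve(xtwsx, crossprod(X, ws * y))
  vcov_b <- solve(xtwsx)
  beta <- unname(b[2, 1]); se <- unname(sqrt(vcov_b[2, 2]))
  intercept <- unname(b[1, 1])
  if (ci_method == "knha") {
    s2 <- sum(ws * (y - X %*% b)^2) / (k - 2)
    se <- se * sqrt(s2)
    crit <- stats::qt(0.975, k - 2)
    p <- 2 * stats::pt(abs(beta / se), k - 2, lower.tail = FALSE)
  } else {
    crit <- 1.96
    p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  }
  structure(list(k = k, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 p_value = p, tau2 = tau2, intercept = intercept,
                 method = "DL", ci_method = ci_method),
            class = "meta_regression")
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf(
    "Random-effects (DL) meta-regression, k = %d:\n  beta = %.4f (95%% CI %.4f to %.4f), tau2 = %.4f [%s CI]\n",
    x$k, x$beta, x$ci_low, x$ci_high, x$tau2, x$ci_method))
  invisible(x)
}

#' Meta-regression grid over characteristics and outcomes
#'
#' One univariate random-effects meta-regression per characteristic x
#' outcome pair with enough data; the moderator is the per-trial baseline
#' difference (characteristic units for continuous, percentage points for
#' binary), so a slope is a change in log OR (or mg/dl of LDL-c change)
#' per unit of imbalance. `exp(beta)` is annotated for the binary
#' outcomes. SAE rows of clinical-outcomes trials are excluded by default
#' (their SAE reporting is not comparable); `exclude_outcome_trials`
#' removes clinical-outcomes trials from every regression as a
#' sensitivity analysis. No multiple-testing correction is applied; the
#' number of fitted regressions is recorded in attribute `n_tests`.
#'
#' @param ts a [trial_set()] with outcomes.
#' @param outcomes subset of outcomes; default all five.
#' @param characteristics subset of characteristics; default all seven.
#' @param sae_exclude_outcome_trials drop clinical-outcomes trials from
#'   the SAE regressions (default `TRUE`).
#' @param exclude_outcome_trials drop clinical-outcomes trials everywhere
#'   (default `FALSE`).
#' @param ci_method passed to [meta_regress()].
#' @return data.frame: characteristic, outcome, k, beta, se, ci_low,
#'   ci_high, p_value, tau2, exp_beta (NA for `ldl_reduction`), note.
#'   Pairs with too little data keep a row with `NA` estimates and an
#'   explanatory note. Attribute `exclusions` logs every omitted trial.
#' @export
regress_all <- function(ts, outcomes = NULL, characteristics = NULL,
                        sae_exclude_outcome_trials = TRUE,
                        exclude_outcome_trials = FALSE,
                        ci_method = c("z", "knha")) {
  ci_method <- match.arg(ci_method)
  if (is.null(outcomes)) outcomes <- outcome_registry()$outcome
  if (is.null(characteristics)) {
    characteristics <- baseline_characteristics()$characteristic
  }
  mods <- lapply(characteristics, function(ch) baseline_differences(ts, ch))
  names(mods) <- characteristics
  exclusions <- list()
  rows <- list()
  n_tests <- 0L
  for (oc in outcomes) {
    eff <- trial_effects(ts, oc)
    drop <- eff$excluded
    if (exclude_outcome_trials ||
        (oc == "sae" && sae_exclude_outcome_trials)) {
      is_co <- eff$trial_class == "clinical_outcomes"
      if (any(is_co & !drop)) {
        exclusions[[length(exclusions) + 1L]] <- data.frame(
          stage = paste0("meta-regression/", oc),
          trial_id = eff$trial_id[is_co & !drop],
          reason = "clinical-outcomes trial excluded by flag",
          stringsAsFactors = FALSE)
      }
      drop <- drop | is_co
    }
    if (any(eff$excluded)) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        stage = paste0("effects/", oc),
        trial_id = eff$trial_id[eff$excluded],
        reason = eff$reason[eff$excluded], stringsAsFactors = FALSE)
    }
    eff_key <- paste(eff$trial_id, eff$control, sep = "\r")
    for (ch in characteristics) {
      m <- mods[[ch]]
      mod_val <- m$value[match(eff_key, paste(m$trial_id, m$control,
                                              sep = "\r"))]
      use <- !drop & !is.na(eff$effect) & !is.na(mod_val)
      fit <- tryCatch(
        meta_regress(eff$effect[use], eff$variance[use], mod_val[use],
                     ci_method = ci_method),
        error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          characteristic = ch, outcome = oc, k = sum(use),
          beta = NA_real_, se = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p_value = NA_real_, tau2 = NA_real_,
          exp_beta = NA_real_, note = conditionMessage(fit),
          stringsAsFactors = FALSE)
      } else {
        n_tests <- n_tests + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          characteristic = ch, outcome = oc, k = fit$k, beta = fit$beta,
          se = fit$se, ci_low = fit$ci_low, ci_high = fit$ci_high,
          p_value = fit$p_value, tau2 = fit$tau2,
          exp_beta = if (oc == "ldl_reduction") NA_real_ else exp(fit$beta),
          note = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(exclusions))
    do.call(rbind, exclusions) else
      data.frame(stage = character(), trial_id = character(),
                 reason = character(), stringsAsFactors = FALSE)
  attr(out, "n_tests") <- n_tests
  out
}
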