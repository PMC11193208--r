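#' Default assessment configuration
#'
#' @return named list of the pipeline options: `dual_arm_policy` (combined
#'   scope arm for dual-control trials), `sd_t_mode` ("welch"/"paired"),
#'   `sae_exclude_outcome_trials`, `exclude_outcome_trials`, `continuity`
#'   (binary-variance continuity adjustment), `ci_method` ("z"/"knha"),
#'   `p_threshold` (variance-test flag level), `strata` (extra strata to
#'   rerun: any of "alirocumab", "evolocumab", "excl_clinical_outcomes").
#' @export
assessment_config <- function() {
  list(dual_arm_policy = "both_arms", sd_t_mode = "welch",
       sae_exclude_outcome_trials = TRUE, exclude_outcome_trials = FALSE,
       continuity = FALSE, ci_method = "z", p_threshold = 0.05,
       strata = character())
}

# restrict a trial_set to arm rows satisfying keep (logical over rows)
filter_trials <- function(ts, keep) {
  trial_set(ts$baseline[keep, ], outcomes = ts$outcomes, scope = ts$scope,
            decimals = ts$decimals[keep, ])
}

#' Run the full baseline-imbalance assessment
#'
#' Executes the whole battery over a trial portfolio: per-scope
#' (placebo, ezetimibe, combined) direction tables with exact sign tests
#' for the seven baseline characteristics and the three SD differences,
#' fixed-effect pooled differences with heterogeneity diagnostics, pooled
#' SDs with the SD-collection t-test, per-trial variance-ratio tests with
#' their p-value histogram, and (when outcomes are available) the
#' meta-regression grid on the combined scope. Optional strata rerun the
#' baseline tables per drug or excluding clinical-outcomes trials.
#'
#' @param trials a [trial_set()] or path to a trial CSV.
#' @param outcomes optional path to an outcome CSV (ignored when `trials`
#'   is already a trial set carrying outcomes).
#' @param config named list overriding entries of [assessment_config()].
#' @return An object of class `assessment_report`: list with `tables`
#'   (directions, sd_directions, pooled, pooled_sds, variance_tests,
#'   pvalue_histogram, pvalue_summary, metareg, exclusions) and `meta`
#'   (package version, effective config and its hash, comparison counts).
#' @export
run_assessment <- function(trials, outcomes = NULL, config = list()) {
  cfg <- utils::modifyList(assessment_config(), config)
  ts <- if (is.character(trials)) read_trial_table(trials, outcomes) else
    trials

  scopes <- c("placebo", "ezetimibe", "combined")
  sel <- lapply(scopes, function(s) {
    tryCatch(select_comparisons(ts, s, dual_arm_policy = cfg$dual_arm_policy),
             error = function(e) NULL)
  })
  names(sel) <- scopes
  if (is.null(sel$combined)) stop("trial set has no comparisons",
                                  call. = FALSE)

  scope_tables <- function(sub, scope) {
    if (is.null(sub)) {
      tmpl <- scope_tables(sel$combined, "combined")
      return(lapply(tmpl, function(df) df[0, ]))
    }
    list(directions = direction_table(sub, what = "baseline"),
         sd_directions = direction_table(sub, what = "sd"),
         pooled = pool_all(sub, continuity = cfg$continuity),
         pooled_sds = pooled_sd_table(sub, mode = cfg$sd_t_mode))
  }
  per_scope <- lapply(scopes, function(s) scope_tables(sel[[s]], s))
  bind_scope <- function(name, stratum = "all", tabs = per_scope) {
    out <- do.call(rbind, lapply(tabs, `[[`, name))
    if (nrow(out)) out <- cbind(stratum = stratum, out) else
      out <- cbind(stratum = character(), out)
    out
  }
  directions <- bind_scope("directions")
  sd_directions <- bind_scope("sd_directions")
  pooled <- bind_scope("pooled")
  pooled_sds <- bind_scope("pooled_sds")

  for (st in cfg$strata) {
    keep <- if (st == "excl_clinical_outcomes")
      ts$baseline$trial_class != "clinical_outcomes" else
        ts$baseline$drug == st
    if (!any(keep)) next
    sub_ts <- filter_trials(ts, keep)
    sub_sel <- lapply(scopes, function(s) {
      tryCatch(select_comparisons(sub_ts, s,
                                  dual_arm_policy = cfg$dual_arm_policy),
               error = function(e) NULL)
    })
    names(sub_sel) <- scopes
    if (is.null(sub_sel$combined)) next
    sub_tabs <- lapply(scopes, function(s) {
      if (is.null(sub_sel[[s]])) {
        lapply(scope_tables(sub_sel$combined, "combined"),
               function(df) df[0, ])
      } else scope_tables(sub_sel[[s]], s)
    })
    directions <- rbind(directions, bind_scope("directions", st, sub_tabs))
    sd_directions <- rbind(sd_directions,
                           bind_scope("sd_directions", st, sub_tabs))
    pooled <- rbind(pooled, bind_scope("pooled", st, sub_tabs))
    pooled_sds <- rbind(pooled_sds, bind_scope("pooled_sds", st, sub_tabs))
  }

  vt <- variance_test_table(sel$combined)
  hist_rows <- list(); summ_rows <- list()
  for (ch in continuous_characteristics()) {
    ps <- vt$p_value[vt$characteristic == ch]
    if (!length(ps)) next
    pd <- pvalue_distribution(ps, threshold = cfg$p_threshold)
    hist_rows[[ch]] <- cbind(characteristic = ch, pd$histogram)
    summ_rows[[ch]] <- data.frame(
      characteristic = ch, n = pd$n, n_below = pd$n_below,
      fraction_below = pd$fraction_below, threshold = pd$threshold,
      stringsAsFactors = FALSE)
  }
  pvalue_histogram <- if (length(hist_rows)) do.call(rbind, hist_rows) else
    data.frame(characteristic = character(), bin_low = numeric(),
               bin_high = numeric(), count = integer(),
               stringsAsFactors = FALSE)
  pvalue_summary <- if (length(summ_rows)) do.call(rbind, summ_rows) else
    data.frame(characteristic = character(), n = integer(),
               n_below = integer(), fraction_below = numeric(),
               threshold = numeric(), stringsAsFactors = FALSE)
  rownames(pvalue_histogram) <- rownames(pvalue_summary) <- NULL

  exclusions <- data.frame(stage = character(), trial_id = character(),
                           reason = character(), stringsAsFactors = FALSE)
  metareg <- data.frame(characteristic = character(), outcome = character(),
                        k = integer(), beta = numeric(), se = numeric(),
                        ci_low = numeric(), ci_high = numeric(),
                        p_value = numeric(), tau2 = numeric(),
                        exp_beta = numeric(), note = character(),
                        stringsAsFactors = FALSE)
  n_tests <- 0L
  if (!is.null(sel$combined$outcomes) && nrow(sel$combined$outcomes)) {
    metareg <- regress_all(
      sel$combined,
      sae_exclude_outcome_trials = cfg$sae_exclude_outcome_trials,
      exclude_outcome_trials = cfg$exclude_outcome_trials,
      ci_method = cfg$ci_method)
    exclusions <- attr(metareg, "exclusions")
    n_tests <- attr(metareg, "n_tests")
    attr(metareg, "exclusions") <- NULL
    attr(metareg, "n_tests") <- NULL
  }

  structure(list(
    tables = list(directions = directions, sd_directions = sd_directions,
                  pooled = pooled, pooled_sds = pooled_sds,
                  variance_tests = vt, pvalue_histogram = pvalue_histogram,
                  pvalue_summary = pvalue_summary, metareg = metareg,
                  exclusions = exclusions),
    meta = list(
      package_version = as.character(utils::packageVersion("rctbalance")),
      config = cfg, config_hash = config_hash(cfg),
      n_comparisons = lapply(sel, function(s)
        if (is.null(s)) 0L else n_comparisons(s)),
      n_metareg_tests = n_tests)),
    class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("<assessment_report>\n  comparisons:",
      paste(names(x$meta$n_comparisons), unlist(x$meta$n_comparisons),
            sep = "=", collapse = ", "), "\n  tables:",
      paste(names(x$tables), vapply(x$tables, nrow, integer(1)),
            sep = "/", collapse = ", "), "\n")
  invisible(x)
}

#' Render an assessment report to files
#'
#' Writes one CSV per table (full precision), a JSON bundle that
#' round-trips through [read_report()], and a markdown summary with
#' display rounding (3 decimals for p-values, half-up; 2 for estimates).
#' Output is deterministic: rendering the same report twice produces
#' byte-identical files.
#'
#' @param report an [run_assessment()] result.
#' @param out_dir output directory (created if absent).
#' @param fig also render the variance-test p-value histogram as a PNG.
#' @return invisibly, the paths written.
#' @export
render_report <- function(report, out_dir, fig = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(report$tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(report$tables[[nm]], p, row.names = FALSE, na = "")
    paths[nm] <- p
  }
  json_path <- file.path(out_dir, "report.json")
  payload <- list(
    tables = lapply(report$tables, function(df) {
      list(columns = as.list(df),
           classes = vapply(df, function(col) class(col)[1], character(1)))
    }),
    meta = report$meta)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  paths["json"] <- json_path

  md <- file.path(out_dir, "summary.md")
  writeLines(report_markdown(report), md)
  paths["summary"] <- md

  if (fig && nrow(report$tables$pvalue_histogram)) {
    fp <- file.path(out_dir, "pvalue_histogram.png")
    grDevices::png(fp, width = 900, height = 320)
    on.exit(grDevices::dev.off(), add = TRUE)
    hist_df <- report$tables$pvalue_histogram
    chars <- unique(hist_df$characteristic)
    graphics::par(mfrow = c(1, length(chars)))
    for (ch in chars) {
      h <- hist_df[hist_df$characteristic == ch, ]
      graphics::barplot(h$count, names.arg = sprintf("%.1f", h$bin_low),
                        main = ch, xlab = "variance-test p-value",
                        ylab = "trials", col = "grey70")
    }
    paths["figure"] <- fp
  }
  invisible(paths)
}

report_markdown <- function(report) {
  f2 <- function(x) ifelse(is.na(x), "",
                           formatC(round_half_up(x, 2), format = "f",
                                   digits = 2))
  f3 <- function(x) ifelse(is.na(x), "",
                           formatC(round_half_up(x, 3), format = "f",
                                   digits = 3))
  lines <- c("# Baseline-imbalance assessment", "",
             paste0("Comparisons: ",
                    paste(names(report$meta$n_comparisons),
                          unlist(report$meta$n_comparisons), sep = " = ",
                          collapse = ", ")), "",
             "## Direction of baseline differences", "",
             "characteristic | scope | range | n-/n0/n+ | sign p",
             "---|---|---|---|---")
  d <- report$tables$directions
  d <- d[d$stratum == "all", ]
  for (i in seq_len(nrow(d))) {
    lines <- c(lines, paste(
      d$characteristic[i], d$scope[i],
      paste0(f2(d$range_min[i]), " to ", f2(d$range_max[i])),
      paste(d$n_neg[i], d$n_zero[i], d$n_pos[i], sep = "/"),
      f3(d$sign_p[i]), sep = " | "))
  }
  p <- report$tables$pooled
  p <- p[p$stratum == "all", ]
  lines <- c(lines, "", "## Pooled baseline differences (fixed effect)", "",
             "characteristic | scope | k | estimate (95% CI) | p(Q) | I2 (95% CI)",
             "---|---|---|---|---|---")
  for (i in seq_len(nrow(p))) {
    lines <- c(lines, paste(
      p$characteristic[i], p$scope[i], p$k[i],
      paste0(f2(p$estimate[i]), " (", f2(p$ci_low[i]), " to ",
             f2(p$ci_high[i]), ")"),
      f3(p$p_Q[i]),
      if (is.na(p$I2[i])) "" else
        paste0(f2(p$I2[i]), if (!is.na(p$I2_ci_low[i]))
          paste0(" (", f2(p$I2_ci_low[i]), " to ", f2(p$I2_ci_high[i]), ")")
          else ""),
      sep = " | "))
  }
  m <- report$tables$metareg
  if (nrow(m)) {
    lines <- c(lines, "", "## Meta-regression of imbalances on outcomes", "",
               paste0("Univariate random-effects (DL) regressions, ",
                      report$meta$n_metareg_tests,
                      " tests run, no multiplicity correction."), "",
               "characteristic | outcome | k | beta (95% CI) | exp(beta)",
               "---|---|---|---|---")
    for (i in seq_len(nrow(m))) {
      lines <- c(lines, paste(
        m$characteristic[i], m$outcome[i], m$k[i],
        if (is.na(m$beta[i])) m$note[i] else
          paste0(f2(m$beta[i]), " (", f2(m$ci_low[i]), " to ",
                 f2(m$ci_high[i]), ")"),
        f2(m$exp_beta[i]), sep = " | "))
    }
  }
  lines
}

#' Read an assessment report back from its JSON bundle
#'
#' @param path path to a `report.json` written by [render_report()].
#' @return an `assessment_report` equal (tables and meta) to the one
#'   rendered.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  tables <- lapply(payload$tables, function(tb) {
    cols <- tb$columns
    classes <- stats::setNames(unlist(tb$classes), names(cols))
    out <- lapply(names(cols), function(nm) {
      col <- cols[[nm]]
      if (is.null(col) || (is.list(col) && !length(col))) {
        col <- vector(classes[[nm]], 0)
      }
      if (is.list(col)) {
        col <- unlist(lapply(col, function(v) if (is.null(v)) NA else v))
      }
      switch(classes[[nm]],
             integer = as.integer(col), numeric = as.numeric(col),
             logical = as.logical(col), as.character(col))
    })
    names(out) <- names(cols)
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  meta <- payload$meta
  meta$config$strata <- as.character(meta$config$strata %||% character())
  meta$n_comparisons <- lapply(meta$n_comparisons, as.integer)
  structure(list(tables = tables, meta = meta), class = "assessment_report")
}
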