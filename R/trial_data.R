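TRIAL_COLUMNS <- c("trial_id", "drug", "control", "trial_class", "arm", "n",
                   "age_mean", "age_sd", "male_pct", "ldl_mean", "ldl_sd",
                   "bmi_mean", "bmi_sd", "dm_pct", "smoking_pct", "htn_pct")
TRIAL_NUMERIC <- TRIAL_COLUMNS[-(1:5)]

OUTCOME_COLUMNS <- c("trial_id", "control", "arm", "n_analyzed",
                     "ldl_change_mean", "ldl_change_sd", "mace_events",
                     "sae_events", "ae_events", "deaths")
OUTCOME_NUMERIC <- OUTCOME_COLUMNS[-(1:3)]

#' Construct a trial set
#'
#' A trial set holds a portfolio of two-arm comparisons in long format:
#' one row per trial arm, one comparison per (`trial_id`, `control`) pair.
#' A trial with both a placebo and an ezetimibe arm contributes two
#' comparisons that share the base `trial_id` and duplicate the drug arm.
#' Percentages are stored on the 0--100 scale exactly as printed;
#' conversion to proportions happens inside computations, never in storage.
#'
#' @param baseline data.frame with the columns listed in
#'   [read_trial_table()] (`trial_id`, `drug`, `control`, `trial_class`,
#'   `arm`, `n`, and the characteristic summary columns). `arm` must be
#'   `"drug"` or `"control"`.
#' @param outcomes optional data.frame of per-arm outcome summaries
#'   (`trial_id`, `control`, `arm`, `n_analyzed`, `ldl_change_mean`,
#'   `ldl_change_sd`, `mace_events`, `sae_events`, `ae_events`, `deaths`).
#' @param scope which comparisons the set represents: `"combined"`,
#'   `"placebo"` or `"ezetimibe"`.
#' @param decimals optional data.frame, same shape as the numeric part of
#'   `baseline`, holding the number of decimals each value was reported
#'   with. Defaults to the decimals of the literal values.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(baseline, outcomes = NULL, scope = "combined",
                      decimals = NULL) {
  baseline <- as.data.frame(baseline)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(baseline))
  if (length(missing_cols)) {
    stop("trial table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  baseline <- baseline[, TRIAL_COLUMNS]
  bad_arm <- setdiff(unique(baseline$arm), c("drug", "control"))
  if (length(bad_arm)) {
    stop("arm labels must be 'drug' or 'control'; found: ",
         paste(bad_arm, collapse = ", "), call. = FALSE)
  }
  check_pairing(baseline)

  if (!is.null(outcomes)) {
    outcomes <- as.data.frame(outcomes)
    miss <- setdiff(OUTCOME_COLUMNS, names(outcomes))
    if (length(miss)) {
      stop("outcome table is missing mandatory column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    outcomes <- outcomes[, OUTCOME_COLUMNS]
  }

  if (is.null(decimals)) {
    decimals <- as.data.frame(lapply(baseline[TRIAL_NUMERIC], count_decimals))
  }

  structure(
    list(baseline = baseline, outcomes = outcomes, scope = scope,
         decimals = as.data.frame(decimals)),
    class = "trial_set"
  )
}

# every (trial_id, control) pair must contribute exactly one drug and one
# control row
check_pairing <- function(baseline) {
  key <- paste(baseline$trial_id, baseline$control, sep = "\r")
  for (k in unique(key)) {
    arms <- baseline$arm[key == k]
    id <- baseline$trial_id[key == k][1]
    if (sum(arms == "drug") != 1L || sum(arms == "control") != 1L) {
      stop("incomplete arm pair for trial '", id,
           "': need exactly one drug and one control row per ",
           "(trial_id, control) comparison", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set>", n_comparisons(x), "comparisons (",
      nrow(x$baseline), "arm rows ), scope:", x$scope, "\n")
  tab <- table(x$baseline$control[x$baseline$arm == "drug"])
  cat("  controls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$outcomes)) {
    cat("  outcomes: ", nrow(x$outcomes), "arm rows\n")
  }
  invisible(x)
}

#' Number of comparisons in a trial set
#' @param ts a [trial_set()].
#' @return integer count of (trial_id, control) comparisons.
#' @export
n_comparisons <- function(ts) {
  nrow(unique(ts$baseline[, c("trial_id", "control")]))
}

# split a trial_set into matched drug/control row pairs, preserving the
# input comparison order; returns list(drug = df, control = df, key = df)
comparison_pairs <- function(ts) {
  b <- ts$baseline
  key <- paste(b$trial_id, b$control, sep = "\r")
  ord <- !duplicated(key)
  keys <- key[ord]
  d <- b[b$arm == "drug", ]
  c_ <- b[b$arm == "control", ]
  d <- d[match(keys, paste(d$trial_id, d$control, sep = "\r")), ]
  c_ <- c_[match(keys, paste(c_$trial_id, c_$control, sep = "\r")), ]
  list(drug = d, control = c_,
       key = d[, c("trial_id", "drug", "control", "trial_class")])
}

#' Read a long-format trial table (and optional outcome table)
#'
#' The trial CSV has one row per trial arm with the exact columns
#' `trial_id, drug, control, trial_class, arm, n, age_mean, age_sd,
#' male_pct, ldl_mean, ldl_sd, bmi_mean, bmi_sd, dm_pct, smoking_pct,
#' htn_pct`; blank cells are missing values, the decimal separator is a
#' period, and a header row is mandatory. The number of decimals of every
#' literal is recorded as reported-precision metadata, so that directions
#' of differences are later classified on the figures exactly as printed.
#'
#' @param path path to the trial CSV.
#' @param outcomes_path optional path to the outcome CSV
#'   (`trial_id, control, arm, n_analyzed, ldl_change_mean, ldl_change_sd,
#'   mace_events, sae_events, ae_events, deaths`).
#' @return A [trial_set()].
#' @export
read_trial_table <- function(path, outcomes_path = NULL) {
  baseline <- read_checked_csv(path, TRIAL_COLUMNS, TRIAL_NUMERIC)
  decimals <- attr(baseline, "decimals")
  outcomes <- NULL
  if (!is.null(outcomes_path)) {
    outcomes <- read_checked_csv(outcomes_path, OUTCOME_COLUMNS,
                                 OUTCOME_NUMERIC)
    attr(outcomes, "decimals") <- NULL
  }
  trial_set(baseline, outcomes = outcomes, decimals = decimals)
}

read_checked_csv <- function(path, columns, numeric_columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(columns, names(raw))
  if (length(missing_cols)) {
    stop("'", basename(path), "' is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, columns]
  dec <- as.data.frame(lapply(raw[numeric_columns], count_decimals))
  for (col in numeric_columns) {
    txt <- trimws(raw[[col]])
    txt[txt == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(num))
    if (length(bad)) {
      stop("non-numeric value '", txt[bad[1]], "' in column '", col,
           "', row ", bad[1] + 1L, " of ", basename(path), call. = FALSE)
    }
    raw[[col]] <- num
  }
  attr(raw, "decimals") <- dec
  raw
}

#' Write a trial set back to CSV
#'
#' Numeric cells are formatted with their recorded number of decimals, so
#' a read / write / read cycle reproduces both the values and the
#' reported-precision metadata field-for-field.
#'
#' @param ts a [trial_set()].
#' @param path output path for the trial CSV.
#' @param outcomes_path optional output path for the outcome CSV.
#' @return `ts`, invisibly.
#' @export
write_trial_table <- function(ts, path, outcomes_path = NULL) {
  out <- ts$baseline
  for (col in TRIAL_NUMERIC) {
    out[[col]] <- format_decimals(out[[col]], ts$decimals[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(outcomes_path) && !is.null(ts$outcomes)) {
    oc <- ts$outcomes
    for (col in OUTCOME_NUMERIC) {
      oc[[col]] <- ifelse(is.na(oc[[col]]), "",
                          format(oc[[col]], trim = TRUE, scientific = FALSE))
    }
    utils::write.csv(oc, outcomes_path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(ts)
}

#' Validate a trial set
#'
#' Validation reports and never raises: each violated invariant (sample
#' size below 1, percentage outside 0--100, negative SD, SD reported
#' without its mean, event count exceeding the analyzed sample size)
#' becomes one row of the violations table, and per-characteristic
#' availability counts record how many comparisons report each
#' characteristic in both arms.
#'
#' @param ts a [trial_set()].
#' @return An object of class `validation_report`: a list with elements
#'   `violations` (data.frame: trial_id, control, arm, field, issue, value),
#'   `availability` (data.frame: characteristic, n_reporting,
#'   n_comparisons) and `valid` (logical).
#' @export
validate_trial_set <- function(ts) {
  b <- ts$baseline
  v <- list()
  flag <- function(rows, field, issue, value) {
    if (!length(rows)) return()
    v[[length(v) + 1L]] <<- data.frame(
      trial_id = b$trial_id[rows], control = b$control[rows],
      arm = b$arm[rows], field = field, issue = issue,
      value = value, stringsAsFactors = FALSE)
  }
  flag(which(!is.na(b$n) & b$n < 1), "n", "sample size below 1",
       b$n[which(!is.na(b$n) & b$n < 1)])
  flag(which(is.na(b$n)), "n", "sample size missing", NA_real_)
  chars <- baseline_characteristics()
  for (i in seq_len(nrow(chars))) {
    if (chars$type[i] == "binary") {
      col <- chars$pct_col[i]
      bad <- which(!is.na(b[[col]]) & (b[[col]] < 0 | b[[col]] > 100))
      flag(bad, col, "percentage outside [0, 100]", b[[col]][bad])
    } else {
      sd_col <- chars$sd_col[i]; mean_col <- chars$mean_col[i]
      bad <- which(!is.na(b[[sd_col]]) & b[[sd_col]] < 0)
      flag(bad, sd_col, "negative SD", b[[sd_col]][bad])
      orphan <- which(!is.na(b[[sd_col]]) & is.na(b[[mean_col]]))
      flag(orphan, sd_col, "SD reported without its mean", b[[sd_col]][orphan])
    }
  }
  if (!is.null(ts$outcomes)) {
    oc <- ts$outcomes
    for (col in c("mace_events", "sae_events", "ae_events", "deaths")) {
      bad <- which(!is.na(oc[[col]]) &
                     (oc[[col]] < 0 | oc[[col]] > oc$n_analyzed))
      if (length(bad)) {
        v[[length(v) + 1L]] <- data.frame(
          trial_id = oc$trial_id[bad], control = oc$control[bad],
          arm = oc$arm[bad], field = col,
          issue = "event count negative or above n_analyzed",
          value = oc[[col]][bad], stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(trial_id = character(), control = character(),
               arm = character(), field = character(), issue = character(),
               value = numeric(), stringsAsFactors = FALSE)

  pairs <- comparison_pairs(ts)
  avail <- chars[, "characteristic", drop = FALSE]
  avail$n_reporting <- vapply(seq_len(nrow(chars)), function(i) {
    col <- if (chars$type[i] == "binary") chars$pct_col[i] else chars$mean_col[i]
    sum(!is.na(pairs$drug[[col]]) & !is.na(pairs$control[[col]]))
  }, integer(1))
  avail$n_comparisons <- n_comparisons(ts)

  structure(list(violations = violations, availability = avail,
                 valid = nrow(violations) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$valid) "no violations" else
    paste(nrow(x$violations), "violation(s)"), "\n")
  if (!x$valid) print(x$violations)
  cat("availability per characteristic:\n")
  print(x$availability, row.names = FALSE)
  invisible(x)
}

#' Select the comparisons for one analysis scope
#'
#' Placebo scope keeps placebo-controlled comparisons, ezetimibe scope the
#' ezetimibe-controlled ones. The combined scope keeps, by default, every
#' comparison: a trial with both a placebo and an ezetimibe arm
#' contributes both, so a 26 + 9 + 4-dual portfolio yields 30 placebo,
#' 13 ezetimibe and 43 combined comparisons. Setting `dual_arm_policy` to
#' `"placebo_arm"` or `"ezetimibe_arm"` instead de-duplicates dual-control
#' trials to one comparison per base trial via the named arm.
#'
#' @param ts a [trial_set()].
#' @param scope `"placebo"`, `"ezetimibe"` or `"combined"`.
#' @param dual_arm_policy how the combined scope treats dual-control
#'   trials: `"both_arms"` (default), `"placebo_arm"` or
#'   `"ezetimibe_arm"`.
#' @return A [trial_set()] restricted to the selected comparisons, with
#'   its `scope` field set.
#' @export
select_comparisons <- function(ts, scope = c("combined", "placebo", "ezetimibe"),
                               dual_arm_policy = c("both_arms",
                                                   "placebo_arm",
                                                   "ezetimibe_arm")) {
  scope <- match.arg(scope)
  dual_arm_policy <- match.arg(dual_arm_policy)
  b <- ts$baseline
  if (scope %in% c("placebo", "ezetimibe")) {
    keep <- b$control == scope
  } else if (dual_arm_policy == "both_arms") {
    keep <- rep(TRUE, nrow(b))
  } else {
    prefer <- if (dual_arm_policy == "placebo_arm") "placebo" else "ezetimibe"
    dual_ids <- unique(b$trial_id[b$control == "placebo"])
    dual_ids <- intersect(dual_ids, unique(b$trial_id[b$control == "ezetimibe"]))
    keep <- !(b$trial_id %in% dual_ids) | b$control == prefer
  }
  if (!any(keep)) {
    stop("no comparisons left after selecting scope '", scope, "'",
         call. = FALSE)
  }
  outcomes <- ts$outcomes
  if (!is.null(outcomes)) {
    kept_keys <- unique(paste(b$trial_id[keep], b$control[keep], sep = "\r"))
    outcomes <- outcomes[paste(outcomes$trial_id, outcomes$control,
                               sep = "\r") %in% kept_keys, ]
  }
  trial_set(b[keep, ], outcomes = outcomes, scope = scope,
            decimals = ts$decimals[keep, ])
}
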