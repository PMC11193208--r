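#' Configuration for the synthetic trial-portfolio generator
#'
#' Defaults describe a portfolio like the lipid-lowering trial programmes
#' the package diagnoses: 43 two-arm trials with 2:1 drug:control
#' allocation, control arms of 50--500 participants, a hyperlipidaemic
#' population (age 60 (10) years, LDL-c 120 (35) mg/dl, BMI 29 (5) kg/m2,
#' 60% male, 35% diabetic, 22% smokers, 55% hypertensive), publication
#' rounding to one decimal, and the reporting gaps typical of such
#' portfolios (BMI missing in ~28% of trials, diabetes ~14%, smoking
#' ~42%, hypertension ~37%). Randomization is intact by default
#' (`imbalance_shift = 0`, `sd_inflation = 1`); both dials exist so tests
#' can break it on purpose.
#'
#' @param n_trials number of trials.
#' @param arm_size_range `c(min, max)` for the control-arm size; the drug
#'   arm follows `allocation_ratio`.
#' @param allocation_ratio drug:control ratio as `c(drug, control)`.
#' @param population per-characteristic truth: continuous entries are
#'   `c(mean, sd)`, binary entries a single prevalence in (0, 1).
#' @param imbalance_shift named additive shifts applied to the drug arm's
#'   sampling distribution (characteristic units for continuous,
#'   proportion scale for binary).
#' @param sd_inflation named (or scalar) multiplicative factor on
#'   drug-arm SDs of continuous characteristics.
#' @param missingness named per-characteristic probability that a trial
#'   omits the field (both arms).
#' @param rounding named per-characteristic number of reported decimals
#'   applied to means, SDs and percentages after summary computation;
#'   `NULL` disables publication rounding.
#' @param outcome_model per-outcome list with `intercept` (logit scale),
#'   `treatment` (log OR of the drug) and `coef` (named per-covariate
#'   log-odds slopes); see [default_outcome_model()].
#' @param ldl_model per-arm LDL-c change model:
#'   `list(drug = c(mean, sd), control = c(mean, sd))` in mg/dl.
#' @param bmi_dm_correlation latent Gaussian-copula correlation between
#'   BMI and diabetes (0 disables; obesity and diabetes travel together
#'   in real populations).
#' @param drug drug label(s) recycled across trials.
#' @param control control label(s) recycled across trials.
#' @param trial_class trial class label(s) recycled across trials.
#' @param seed integer root seed; per-trial streams are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_trials = 43,
                       arm_size_range = c(50, 500),
                       allocation_ratio = c(2, 1),
                       population = default_population(),
                       imbalance_shift = NULL,
                       sd_inflation = 1,
                       missingness = NULL,
                       rounding = default_rounding(),
                       outcome_model = default_outcome_model(),
                       ldl_model = list(drug = c(mean = -60, sd = 20),
                                        control = c(mean = 0, sd = 20)),
                       bmi_dm_correlation = 0,
                       drug = c("alirocumab", "evolocumab"),
                       control = "placebo",
                       trial_class = "lipid_lowering",
                       seed = 1L) {
  chars <- names(population)
  bad <- setdiff(chars, baseline_characteristics()$characteristic)
  if (length(bad)) {
    stop("unknown characteristic(s) in population: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!length(chars)) stop("population must not be empty", call. = FALSE)
  if (n_trials < 1) stop("invalid config field n_trials", call. = FALSE)
  if (length(arm_size_range) != 2 || any(arm_size_range < 2) ||
      arm_size_range[1] > arm_size_range[2]) {
    stop("invalid config field arm_size_range", call. = FALSE)
  }
  if (length(allocation_ratio) != 2 || any(allocation_ratio <= 0)) {
    stop("invalid config field allocation_ratio", call. = FALSE)
  }
  full <- function(x, default) {
    out <- rep(default, length(chars)); names(out) <- chars
    if (!is.null(x) && length(x)) {
      if (is.null(names(x)) && length(x) == 1) x <- stats::setNames(
        rep(x, length(chars)), chars)
      out[names(x)] <- x
    }
    out
  }
  shift <- full(imbalance_shift, 0)
  lambda <- full(sd_inflation, 1)
  miss <- full(missingness, if (is.null(missingness))
    default_missingness()[chars] else 0)
  if (any(lambda <= 0)) stop("invalid config field sd_inflation",
                             call. = FALSE)
  if (any(miss < 0 | miss > 1)) stop("invalid config field missingness",
                                     call. = FALSE)
  types <- baseline_characteristics()
  for (ch in chars) {
    ty <- types$type[types$characteristic == ch]
    p <- population[[ch]]
    if (ty == "binary" && (length(p) != 1 || p <= 0 || p >= 1)) {
      stop("invalid config field population$", ch,
           " (binary prevalence must lie in (0, 1))", call. = FALSE)
    }
    if (ty == "continuous" && (length(p) != 2 || p[2] <= 0)) {
      stop("invalid config field population$", ch,
           " (continuous truth is c(mean, sd), sd > 0)", call. = FALSE)
    }
  }
  if (abs(bmi_dm_correlation) >= 1) {
    stop("invalid config field bmi_dm_correlation", call. = FALSE)
  }
  structure(list(
    n_trials = as.integer(n_trials), arm_size_range = arm_size_range,
    allocation_ratio = allocation_ratio, population = population,
    imbalance_shift = shift, sd_inflation = lambda, missingness = miss,
    rounding = rounding, outcome_model = outcome_model,
    ldl_model = ldl_model, bmi_dm_correlation = bmi_dm_correlation,
    drug = drug, control = control, trial_class = trial_class,
    seed = as.integer(seed)),
    class = "sim_config")
}

#' @rdname sim_config
#' @export
default_population <- function() {
  list(age = c(mean = 60, sd = 10), male = 0.60,
       ldl = c(mean = 120, sd = 35), bmi = c(mean = 29, sd = 5),
       dm = 0.35, smoking = 0.22, htn = 0.55)
}

#' @rdname sim_config
#' @export
default_missingness <- function() {
  c(age = 0, male = 0, ldl = 0, bmi = 12 / 43, dm = 6 / 43,
    smoking = 18 / 43, htn = 16 / 43)
}

#' @rdname sim_config
#' @export
default_rounding <- function() {
  c(age = 1, male = 1, ldl = 1, bmi = 1, dm = 1, smoking = 1, htn = 1)
}

#' Default covariate-linked outcome model
#'
#' Logistic event models with rates typical of lipid-lowering portfolios:
#' MACE ~3% with a protective drug effect, SAE ~20%, any AE ~70%,
#' mortality ~2%; age and diabetes raise MACE and mortality risk.
#'
#' @return named list, one entry per binary outcome, each with
#'   `intercept`, `treatment` and a named `coef` vector (covariate slopes
#'   on the logit scale; continuous covariates enter centred at the
#'   population mean, binary ones as 0/1).
#' @export
default_outcome_model <- function() {
  list(
    mace = list(intercept = stats::qlogis(0.03), treatment = log(0.85),
                coef = c(age = 0.04, dm = 0.5)),
    sae = list(intercept = stats::qlogis(0.20), treatment = 0,
               coef = c(age = 0.02)),
    any_ae = list(intercept = stats::qlogis(0.70), treatment = 0,
                  coef = numeric()),
    mortality = list(intercept = stats::qlogis(0.02), treatment = 0,
                     coef = c(age = 0.07, dm = 0.4))
  )
}

#' Simulate a portfolio of two-arm trials with known truth
#'
#' Per trial: the control-arm size is drawn uniformly from
#' `arm_size_range` and the drug arm follows the allocation ratio;
#' individual covariates are sampled from the population, with the
#' configured additive shifts and SD inflation applied to the drug arm's
#' sampling distribution; arm summaries are computed, then publication
#' rounding and field missingness are applied. Per-trial random streams
#' are derived deterministically from the root seed, so a portfolio is
#' reproducible given its config.
#'
#' @param config a [sim_config()].
#' @param keep_individual retain per-participant records (needed by
#'   [simulate_outcomes()] and by exact-recomputation oracles).
#' @return An object of class `simulated_portfolio`: list with
#'   `trial_set` (a [trial_set()]), `truth` (the config) and
#'   `individual` (`NULL` unless retained: per trial, a list of `drug` /
#'   `control` data.frames of raw covariate values).
#' @export
simulate_portfolio <- function(config, keep_individual = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  trial_seeds <- sample.int(2147483646L, config$n_trials)
  chars_meta <- baseline_characteristics()
  chars <- names(config$population)
  ratio <- config$allocation_ratio[1] / config$allocation_ratio[2]
  drugs <- rep_len(config$drug, config$n_trials)
  controls <- rep_len(config$control, config$n_trials)
  classes <- rep_len(config$trial_class, config$n_trials)

  rows <- vector("list", config$n_trials)
  indiv <- if (keep_individual) vector("list", config$n_trials) else NULL
  num_template <- stats::setNames(rep(NA_real_, length(TRIAL_NUMERIC)),
                                  TRIAL_NUMERIC)

  for (i in seq_len(config$n_trials)) {
    set.seed(trial_seeds[i])
    n_c <- sample(seq(config$arm_size_range[1], config$arm_size_range[2]), 1L)
    n_d <- max(2L, as.integer(round(n_c * ratio)))
    drug_vals <- num_template; ctrl_vals <- num_template
    drug_vals["n"] <- n_d; ctrl_vals["n"] <- n_c
    drug_df <- if (keep_individual) list() else NULL
    ctrl_df <- if (keep_individual) list() else NULL

    rho <- config$bmi_dm_correlation
    use_copula <- rho != 0 && all(c("bmi", "dm") %in% chars)
    z_bmi_d <- z_bmi_c <- NULL

    for (ch in chars) {
      meta <- chars_meta[chars_meta$characteristic == ch, ]
      miss <- stats::runif(1) < config$missingness[ch]
      if (meta$type == "continuous") {
        p <- config$population[[ch]]
        lam <- config$sd_inflation[ch]
        x_d <- stats::rnorm(n_d, p[1] + config$imbalance_shift[ch],
                            p[2] * lam)
        x_c <- stats::rnorm(n_c, p[1], p[2])
        if (use_copula && ch == "bmi") {
          z_bmi_d <- (x_d - (p[1] + config$imbalance_shift[ch])) /
            (p[2] * lam)
          z_bmi_c <- (x_c - p[1]) / p[2]
        }
        vals_d <- c(mean(x_d), stats::sd(x_d))
        vals_c <- c(mean(x_c), stats::sd(x_c))
        dec <- config$rounding[ch]
        if (!is.null(config$rounding) && !is.na(dec)) {
          vals_d <- round_half_up(vals_d, dec)
          vals_c <- round_half_up(vals_c, dec)
        }
        if (!miss) {
          drug_vals[c(meta$mean_col, meta$sd_col)] <- vals_d
          ctrl_vals[c(meta$mean_col, meta$sd_col)] <- vals_c
        }
      } else {
        prev <- config$population[[ch]]
        prev_d <- min(1 - 1e-12,
                      max(1e-12, prev + config$imbalance_shift[ch]))
        if (use_copula && ch == "dm" && !is.null(z_bmi_d)) {
          e_d <- stats::rnorm(n_d); e_c <- stats::rnorm(n_c)
          lat_d <- rho * z_bmi_d + sqrt(1 - rho^2) * e_d
          lat_c <- rho * z_bmi_c + sqrt(1 - rho^2) * e_c
          x_d <- as.numeric(lat_d > stats::qnorm(1 - prev_d))
          x_c <- as.numeric(lat_c > stats::qnorm(1 - prev))
        } else {
          x_d <- as.numeric(stats::runif(n_d) < prev_d)
          x_c <- as.numeric(stats::runif(n_c) < prev)
        }
        pct_d <- 100 * mean(x_d); pct_c <- 100 * mean(x_c)
        dec <- config$rounding[ch]
        if (!is.null(config$rounding) && !is.na(dec)) {
          pct_d <- round_half_up(pct_d, dec)
          pct_c <- round_half_up(pct_c, dec)
        }
        if (!miss) {
          drug_vals[meta$pct_col] <- pct_d
          ctrl_vals[meta$pct_col] <- pct_c
        }
      }
      if (keep_individual) {
        drug_df[[ch]] <- x_d
        ctrl_df[[ch]] <- x_c
      }
    }

    id <- sprintf("T%03d", i)
    rows[[i]] <- data.frame(
      trial_id = id, drug = drugs[i], control = controls[i],
      trial_class = classes[i], arm = c("drug", "control"),
      rbind(drug_vals, ctrl_vals), row.names = NULL,
      stringsAsFactors = FALSE)
    if (keep_individual) {
      indiv[[i]] <- list(drug = as.data.frame(drug_df),
                         control = as.data.frame(ctrl_df))
      names(indiv)[i] <- id
    }
  }
  baseline <- do.call(rbind, rows)
  decs <- as.data.frame(lapply(stats::setNames(TRIAL_NUMERIC, TRIAL_NUMERIC),
                               function(col) {
    ch <- chars_meta$characteristic[match(col, chars_meta$mean_col)]
    if (is.na(ch)) ch <- chars_meta$characteristic[match(col, chars_meta$sd_col)]
    if (is.na(ch)) ch <- chars_meta$characteristic[match(col, chars_meta$pct_col)]
    d <- if (col == "n" || is.null(config$rounding) || is.na(ch))
      NA_integer_ else unname(config$rounding[ch])
    out <- rep(as.integer(d), nrow(baseline))
    out[is.na(baseline[[col]])] <- NA_integer_
    out
  }))
  ts <- trial_set(baseline, scope = "combined", decimals = decs)
  structure(list(trial_set = ts, truth = config, individual = indiv),
            class = "simulated_portfolio")
}

#' @export
print.simulated_portfolio <- function(x, ...) {
  cat("<simulated_portfolio>", x$truth$n_trials, "trials, seed",
      x$truth$seed, "\n")
  print(x$trial_set)
  invisible(x)
}

#' Simulate covariate-linked outcomes for a portfolio
#'
#' Per participant and binary outcome, the event probability is
#' `plogis(intercept + sum(coef * covariate) + treatment * is_drug)`,
#' with continuous covariates centred at their population mean so the
#' intercept stays interpretable as a control-arm baseline rate; events
#' are aggregated per arm. The LDL-c change is drawn per participant from
#' the arm's change model. Requires individual data
#' (`keep_individual = TRUE` at portfolio simulation).
#'
#' @param portfolio a [simulate_portfolio()] result with individual data.
#' @param outcome_model,ldl_model override the portfolio's truth models.
#' @param seed seed for the outcome stream; defaults to the portfolio
#'   root seed + 1.
#' @return the portfolio with `trial_set$outcomes` filled in.
#' @export
simulate_outcomes <- function(portfolio, outcome_model = NULL,
                              ldl_model = NULL, seed = NULL) {
  stopifnot(inherits(portfolio, "simulated_portfolio"))
  if (is.null(portfolio$individual)) {
    stop("simulate_outcomes needs individual data; rerun ",
         "simulate_portfolio(..., keep_individual = TRUE)", call. = FALSE)
  }
  cfg <- portfolio$truth
  om <- outcome_model %||% cfg$outcome_model
  lm_ <- ldl_model %||% cfg$ldl_model
  set.seed(seed %||% ((cfg$seed %% 2147483645L) + 1L))
  pairs <- comparison_pairs(portfolio$trial_set)
  centers <- vapply(names(cfg$population), function(ch) {
    p <- cfg$population[[ch]]
    if (length(p) == 2) p[1] else 0
  }, numeric(1))

  reg <- outcome_registry()
  rows <- list()
  for (i in seq_len(nrow(pairs$key))) {
    id <- pairs$key$trial_id[i]
    ind <- portfolio$individual[[id]]
    for (arm in c("drug", "control")) {
      df <- ind[[arm]]
      n <- nrow(df)
      rec <- list(trial_id = id, control = pairs$key$control[i], arm = arm,
                  n_analyzed = n)
      chg <- stats::rnorm(n, lm_[[arm]]["mean"], lm_[[arm]]["sd"])
      rec$ldl_change_mean <- mean(chg)
      rec$ldl_change_sd <- stats::sd(chg)
      for (oc in reg$outcome[-1]) {
        mdl <- om[[oc]]
        if (is.null(mdl)) { rec[[reg$count_col[reg$outcome == oc]]] <- NA_real_; next }
        lp <- rep(mdl$intercept, n)
        for (cv in names(mdl$coef)) {
          if (!is.null(df[[cv]])) {
            lp <- lp + mdl$coef[[cv]] * (df[[cv]] - centers[[cv]])
          }
        }
        if (arm == "drug") lp <- lp + mdl$treatment
        rec[[reg$count_col[reg$outcome == oc]]] <-
          sum(stats::runif(n) < stats::plogis(lp))
      }
      rows[[length(rows) + 1L]] <- as.data.frame(rec,
                                                 stringsAsFactors = FALSE)
    }
  }
  outcomes <- do.call(rbind, rows)
  outcomes <- outcomes[, OUTCOME_COLUMNS]
  portfolio$trial_set <- trial_set(portfolio$trial_set$baseline,
                                   outcomes = outcomes,
                                   scope = portfolio$trial_set$scope,
                                   decimals = portfolio$trial_set$decimals)
  portfolio
}

#' Write a simulated portfolio to disk
#'
#' Emits `trials.csv` / `outcomes.csv` in the long trial-table schema and
#' a `truth.json` sidecar recording the generating configuration.
#'
#' @param portfolio a [simulate_portfolio()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_portfolio <- function(portfolio, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials <- file.path(dir, "trials.csv")
  outcomes <- if (!is.null(portfolio$trial_set$outcomes))
    file.path(dir, "outcomes.csv") else NULL
  write_trial_table(portfolio$trial_set, trials, outcomes_path = outcomes)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(unclass(portfolio$truth), truth, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(trials = trials, outcomes = outcomes, truth = truth))
}

#' Read a simulator configuration from YAML
#'
#' Scalar fields map directly onto [sim_config()] arguments; the
#' `population` entry lists `c(mean, sd)` pairs for continuous
#' characteristics and bare prevalences for binary ones.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  args <- y[intersect(names(y), names(formals(sim_config)))]
  for (fld in c("imbalance_shift", "sd_inflation", "missingness",
                "rounding")) {
    if (!is.null(args[[fld]])) args[[fld]] <- unlist(args[[fld]])
  }
  if (!is.null(args$population)) {
    args$population <- lapply(args$population, unlist)
  }
  do.call(sim_config, args)
}
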