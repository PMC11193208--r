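test_that("the generator is deterministic given its seed", {
  cfg <- sim_config(n_trials = 6, seed = 99)
  a <- simulate_portfolio(cfg, keep_individual = TRUE)
  b <- simulate_portfolio(cfg, keep_individual = TRUE)
  expect_identical(a$trial_set$baseline, b$trial_set$baseline)
  expect_identical(a$individual, b$individual)
  c_ <- simulate_portfolio(sim_config(n_trials = 6, seed = 100))
  expect_false(identical(a$trial_set$baseline, c_$trial_set$baseline))
  # outcome stream deterministic too
  oa <- simulate_outcomes(a)$trial_set$outcomes
  ob <- simulate_outcomes(b)$trial_set$outcomes
  expect_identical(oa, ob)
})

test_that("summaries equal recomputation from individuals before rounding", {
  cfg <- sim_config(n_trials = 5, arm_size_range = c(30, 90),
                    rounding = NULL, missingness = 0, seed = 12)
  p <- simulate_portfolio(cfg, keep_individual = TRUE)
  pairs <- rctbalance:::comparison_pairs(p$trial_set)
  for (i in seq_len(nrow(pairs$key))) {
    ind <- p$individual[[pairs$key$trial_id[i]]]
    expect_equal(pairs$drug$age_mean[i], mean(ind$drug$age))
    expect_equal(pairs$drug$age_sd[i], sd(ind$drug$age))
    expect_equal(pairs$control$ldl_mean[i], mean(ind$control$ldl))
    expect_equal(pairs$drug$male_pct[i], 100 * mean(ind$drug$male))
    expect_equal(pairs$drug$n[i], nrow(ind$drug))
  }
})

test_that("allocation ratio and arm-size range are honoured", {
  cfg <- sim_config(n_trials = 15, arm_size_range = c(50, 100),
                    allocation_ratio = c(2, 1), seed = 4)
  pairs <- rctbalance:::comparison_pairs(simulate_portfolio(cfg)$trial_set)
  expect_true(all(pairs$control$n >= 50 & pairs$control$n <= 100))
  expect_equal(pairs$drug$n, as.integer(round(pairs$control$n * 2)))
})

test_that("rounding and missingness emulate publication reporting", {
  cfg <- sim_config(n_trials = 30, rounding = c(age = 1, male = 0),
                    population = list(age = c(mean = 60, sd = 10),
                                      male = 0.6),
                    missingness = c(male = 0.5), seed = 31)
  ts <- simulate_portfolio(cfg)$trial_set
  b <- ts$baseline
  expect_true(all(b$age_mean == round_half_up(b$age_mean, 1)))
  expect_true(all(b$male_pct[!is.na(b$male_pct)] ==
                    round(b$male_pct[!is.na(b$male_pct)])))
  frac_missing <- mean(is.na(b$male_pct))
  expect_gt(frac_missing, 0.2); expect_lt(frac_missing, 0.8)
  # missingness strikes whole trials, both arms at once
  pairs <- rctbalance:::comparison_pairs(ts)
  expect_equal(is.na(pairs$drug$male_pct), is.na(pairs$control$male_pct))
  # decimals metadata mirrors the configured rounding
  expect_true(all(ts$decimals$age_mean == 1L))
})

test_that("a null portfolio has centred differences, inflation shifts SDs", {
  cfg <- sim_config(n_trials = 60, arm_size_range = c(2000, 2000),
                    population = list(age = c(mean = 60, sd = 10)),
                    missingness = 0, seed = 41)
  d <- baseline_differences(simulate_portfolio(cfg)$trial_set, "age")
  mcse <- sd(d$value) / sqrt(length(d$value))
  expect_lt(abs(mean(d$value)), 3 * mcse + 1e-9)

  cfg_l <- sim_config(n_trials = 40, arm_size_range = c(200, 400),
                      population = list(age = c(mean = 60, sd = 10)),
                      sd_inflation = c(age = 1.1), missingness = 0,
                      seed = 42)
  s <- sd_differences(simulate_portfolio(cfg_l)$trial_set, "age")
  expect_gt(mean(s$value > 0), 0.6)
})

test_that("outcome generation matches its logistic truth", {
  om <- list(any_ae = list(intercept = qlogis(0.1), treatment = 0,
                           coef = numeric()))
  cfg <- sim_config(n_trials = 25, arm_size_range = c(400, 600),
                    population = list(age = c(mean = 60, sd = 10)),
                    outcome_model = om, missingness = 0, seed = 55)
  p <- simulate_outcomes(simulate_portfolio(cfg, keep_individual = TRUE))
  oc <- p$trial_set$outcomes
  rate <- sum(oc$ae_events) / sum(oc$n_analyzed)
  expect_lt(abs(rate - 0.1), 0.01)
  expect_true(all(is.na(oc$mace_events)))

  om2 <- list(any_ae = list(intercept = qlogis(0.3), treatment = -0.2,
                            coef = numeric()))
  cfg2 <- sim_config(n_trials = 40, arm_size_range = c(800, 1200),
                     population = list(age = c(mean = 60, sd = 10)),
                     outcome_model = om2, missingness = 0, seed = 56)
  p2 <- simulate_outcomes(simulate_portfolio(cfg2, keep_individual = TRUE))
  eff <- trial_effects(p2$trial_set, "any_ae")
  expect_lt(abs(mean(eff$effect) + 0.2), 0.05)
})

test_that("a covariate-linked shift induces a recoverable slope", {
  # age raises mortality risk; the drug arm samples older patients, so the
  # per-trial age imbalance should predict the mortality log OR
  om <- list(mortality = list(intercept = qlogis(0.10), treatment = 0,
                              coef = c(age = 0.08)))
  slopes <- vapply(1:8, function(r) {
    cfg <- sim_config(n_trials = 40, arm_size_range = c(500, 900),
                      population = list(age = c(mean = 60, sd = 10)),
                      outcome_model = om, missingness = 0, rounding = NULL,
                      seed = 600 + r)
    p <- simulate_outcomes(simulate_portfolio(cfg, keep_individual = TRUE))
    eff <- trial_effects(p$trial_set, "mortality")
    mod <- baseline_differences(p$trial_set, "age")
    meta_regress(eff$effect, eff$variance, mod$value)$beta
  }, numeric(1))
  expect_gt(mean(slopes), 0.04) # truth 0.08 per year of imbalance
})

test_that("the BMI-diabetes copula induces the requested association", {
  cfg <- sim_config(n_trials = 1, arm_size_range = c(20000, 20000),
                    population = list(bmi = c(mean = 29, sd = 5), dm = 0.35),
                    bmi_dm_correlation = 0.5, missingness = 0, seed = 71)
  p <- simulate_portfolio(cfg, keep_individual = TRUE)
  ind <- p$individual[[1]]$control
  expect_gt(cor(ind$bmi, ind$dm), 0.25)
  expect_equal(mean(ind$dm), 0.35, tolerance = 0.02)
})

test_that("invalid configurations are rejected by field name", {
  expect_error(sim_config(n_trials = 0), "n_trials")
  expect_error(sim_config(arm_size_range = c(100, 50)), "arm_size_range")
  expect_error(sim_config(population = list(dm = 1.2)), "population\\$dm")
  expect_error(sim_config(population = list(banana = 1)), "banana")
  expect_error(sim_config(sd_inflation = -1), "sd_inflation")
  expect_error(sim_config(missingness = c(age = 2)), "missingness")
  expect_error(
    simulate_outcomes(simulate_portfolio(sim_config(n_trials = 2))),
    "individual")
})

test_that("portfolios round-trip through disk and YAML config", {
  cfg <- sim_config(n_trials = 4, seed = 8)
  p <- simulate_outcomes(simulate_portfolio(cfg, keep_individual = TRUE))
  dir <- tempfile()
  paths <- write_portfolio(p, dir)
  ts <- read_trial_table(paths["trials"], paths["outcomes"])
  expect_equal(ts$baseline, p$trial_set$baseline, ignore_attr = TRUE)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$seed, 8L)

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("n_trials: 5", "seed: 3", "population:",
               "  age: [60, 10]", "  dm: 0.3",
               "imbalance_shift:", "  age: 0.5"), yml)
  cfg2 <- read_sim_config(yml)
  expect_equal(cfg2$n_trials, 5L)
  expect_equal(unname(cfg2$imbalance_shift["age"]), 0.5)
  expect_equal(cfg2$population$age, c(60, 10), ignore_attr = TRUE)
  cfg3 <- read_sim_config(yml, seed = 9)
  expect_equal(cfg3$seed, 9L)
})
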