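test_that("trial log odds ratios follow the 2x2 arithmetic", {
  null <- trial_log_or(10, 100, 10, 100)
  expect_equal(null$effect, 0)
  expect_equal(null$variance, 2 * (1 / 10 + 1 / 90))
  expect_false(null$corrected)
  up <- trial_log_or(20, 100, 10, 100)
  expect_equal(up$effect, log(2.25))
  expect_equal(up$variance, 1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  # zero cell: 0.5 added to all four cells, flagged
  z <- trial_log_or(0, 50, 5, 50)
  expect_true(z$corrected)
  expect_equal(z$effect, log((0.5 * 45.5) / (5.5 * 50.5)))
  # arm exchange flips the sign, keeps the variance
  a <- trial_log_or(20, 100, 10, 100); b <- trial_log_or(10, 100, 20, 100)
  expect_equal(a$effect, -b$effect)
  expect_equal(a$variance, b$variance)
  # uninformative trials are excluded with a reason, not an error
  expect_true(trial_log_or(0, 50, 0, 50)$excluded)
  expect_true(trial_log_or(50, 50, 40, 40)$excluded)
  expect_error(trial_log_or(60, 50, 10, 50), "0 <= events <= n")
})

test_that("percent LDL-c change converts on the baseline mean", {
  expect_equal(percent_to_absolute_change(100, -60), -60)
  expect_equal(percent_to_absolute_change(120, -50), -60)
  expect_error(percent_to_absolute_change(0, -50), "positive")
  expect_error(percent_to_absolute_change(NA, -50), "positive")
})

test_that("LDL effect and variance come from the change summaries", {
  e <- ldl_effect(-60, 20, 100, 0, 20, 100)
  expect_equal(e$effect, -60)
  expect_equal(e$variance, 8)
  expect_equal(ldl_effect(-30, 15, 50, -30, 15, 50)$effect, 0)
  miss <- ldl_effect(-60, 20, 100, 0, NA, 100)
  expect_true(miss$excluded)
  expect_match(miss$reason, "SD")
})

test_that("meta-regression reduces to OLS on exact linear data", {
  x <- c(1, 2, 3, 4, 5)
  y <- 0.5 + 0.3 * x
  fit <- meta_regress(y, rep(0.04, 5), x)
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-12)
  expect_equal(fit$tau2, 0)
  expect_error(meta_regress(y, rep(0.04, 5), rep(2, 5)), "constant")
  expect_error(meta_regress(y[1:2], rep(0.04, 2), x[1:2]), "at least 3")
})

test_that("meta-regression matches metafor's DL implementation", {
  library(metafor)
  set.seed(14)
  for (i in 1:5) {
    k <- sample(8:30, 1)
    x <- rnorm(k, 0, 3)
    v <- runif(k, 0.02, 0.3)
    y <- 0.1 + 0.05 * x + rnorm(k, 0, sqrt(v + 0.02))
    mine <- meta_regress(y, v, x)
    ref <- rma(yi = y, vi = v, mods = ~x, method = "DL")
    expect_equal(mine$beta, as.numeric(ref$beta[2]), tolerance = 1e-8)
    expect_equal(mine$se, ref$se[2], tolerance = 1e-8)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-8)
    kh <- meta_regress(y, v, x, ci_method = "knha")
    refkh <- rma(yi = y, vi = v, mods = ~x, method = "DL", test = "knha")
    expect_equal(kh$se, refkh$se[2], tolerance = 1e-8)
    expect_equal(kh$ci_low, refkh$ci.lb[2], tolerance = 1e-6)
  }
})

test_that("intercept-only structure reduces to DL pooling", {
  library(metafor)
  set.seed(15)
  k <- 20
  v <- runif(k, 0.05, 0.2)
  y <- rnorm(k, 0.3, sqrt(v + 0.05))
  # moderator centred and orthogonal-ish: intercept matches DL pooling of y
  x <- scale(rnorm(k), scale = FALSE)[, 1]
  fit <- meta_regress(y, v, x)
  ref <- rma(yi = y, vi = v, mods = ~x, method = "DL")
  expect_equal(fit$intercept, as.numeric(ref$beta[1]), tolerance = 1e-8)
})

test_that("tau2 truncates at zero and beta ignores moderator location", {
  set.seed(16)
  x <- rnorm(10); v <- runif(10, 0.1, 0.3)
  y <- 0.2 * x + rnorm(10, 0, 0.05) # residual noise well below v: Q_E small
  fit <- meta_regress(y, v, x)
  expect_gte(fit$tau2, 0)
  shifted <- meta_regress(y, v, x + 100)
  expect_equal(shifted$beta, fit$beta, tolerance = 1e-9)
  expect_equal(shifted$tau2, fit$tau2, tolerance = 1e-9)
})

test_that("slope recovery over replicated portfolios is unbiased", {
  set.seed(17)
  betas <- replicate(120, {
    k <- 40
    x <- rnorm(k, 0, 4)
    v <- runif(k, 0.05, 0.3)
    y <- 0.02 * x + rnorm(k, 0, sqrt(v))
    meta_regress(y, v, x)$beta
  })
  expect_lt(abs(mean(betas) - 0.02), 3 * sd(betas) / sqrt(120))
})

test_that("the regression grid handles flags and bookkeeping", {
  cfg <- sim_config(n_trials = 12, arm_size_range = c(150, 300),
                    missingness = c(smoking = 1),
                    trial_class = c(rep("lipid_lowering", 10),
                                    rep("clinical_outcomes", 2)),
                    seed = 23)
  p <- simulate_outcomes(simulate_portfolio(cfg, keep_individual = TRUE))
  grid <- regress_all(p$trial_set)
  expect_lte(nrow(grid), 35)
  expect_setequal(unique(grid$outcome),
                  c("ldl_reduction", "mace", "sae", "any_ae", "mortality"))
  # smoking is unreported everywhere: no fit, an explanatory note instead
  smk <- grid[grid$characteristic == "smoking", ]
  expect_true(all(is.na(smk$beta)))
  # SAE drops the clinical-outcomes trials by default
  sae_k <- grid$k[grid$outcome == "sae" & grid$characteristic == "age"]
  ae_k <- grid$k[grid$outcome == "any_ae" & grid$characteristic == "age"]
  expect_equal(ae_k - sae_k, 2L)
  excl <- attr(grid, "exclusions")
  expect_true(any(excl$reason == "clinical-outcomes trial excluded by flag"))
  # sensitivity switch removes them everywhere
  grid2 <- regress_all(p$trial_set, exclude_outcome_trials = TRUE)
  expect_equal(grid2$k[grid2$outcome == "any_ae" &
                         grid2$characteristic == "age"], ae_k - 2L)
  # exp(beta) annotated for binary outcomes only
  expect_true(all(is.na(grid$exp_beta[grid$outcome == "ldl_reduction"])))
  expect_true(all(!is.na(grid$exp_beta[grid$outcome == "any_ae" &
                                         !is.na(grid$beta)])))
})
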