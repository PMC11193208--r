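test_that("pooled SD follows the df-weighted formula", {
  expect_equal(pooled_sd(c(2, 4), c(5, 5))$value, sqrt(10))
  expect_equal(pooled_sd(rep(3.3, 5), rep(40, 5))$value, 3.3) # fixed point
  one <- pooled_sd(9.3, 100)
  expect_equal(one$value, 9.3)
  expect_equal(one$total_df, 99)
  expect_error(pooled_sd(numeric(), numeric()), "no SDs")
  expect_error(pooled_sd(c(2, 3), c(5, 1), trial_id = c("a", "b")), "b")
})

test_that("pooled SD equals the individual-level within-group recomputation", {
  cfg <- sim_config(n_trials = 6, arm_size_range = c(30, 80),
                    population = list(age = c(mean = 60, sd = 10)),
                    missingness = 0, rounding = NULL, seed = 77)
  p <- simulate_portfolio(cfg, keep_individual = TRUE)
  pairs <- rctbalance:::comparison_pairs(p$trial_set)
  for (arm in c("drug", "control")) {
    summ <- pooled_sd(pairs[[arm]]$age_sd, pairs[[arm]]$n)
    # concatenate raw individuals and pool within-trial deviations
    ss <- 0; df <- 0
    for (t in p$individual) {
      x <- t[[arm]]$age
      ss <- ss + sum((x - mean(x))^2); df <- df + length(x) - 1
    }
    expect_equal(summ$value, sqrt(ss / df), tolerance = 1e-12)
  }
})

test_that("SD-collection t-test matches the textbook Welch formula", {
  d <- c(10, 12, 14); c_ <- c(9, 11, 13)
  out <- compare_sd_collections(d, c_)
  tw <- (mean(d) - mean(c_)) / sqrt(var(d) / 3 + var(c_) / 3)
  expect_equal(out$t, tw)
  expect_equal(out$df, 4) # equal variances, equal n
  expect_equal(out$p, 2 * pt(-abs(tw), 4))
  expect_equal(out$mode, "welch")
  same <- compare_sd_collections(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  # constant within-trial differences are an extreme paired result
  paired <- compare_sd_collections(d, c_, mode = "paired")
  expect_equal(paired$mode, "paired")
  expect_equal(paired$t, Inf)
  expect_equal(paired$p, 0)
  expect_error(compare_sd_collections(1, 2), "at least 2")
})

test_that("SD inflation in the drug arm is detectable (power check)", {
  hits <- 0L
  for (r in 1:25) {
    cfg <- sim_config(n_trials = 40, arm_size_range = c(100, 400),
                      population = list(age = c(mean = 60, sd = 10)),
                      sd_inflation = c(age = 1.1), missingness = 0,
                      seed = 1300 + r)
    pairs <- rctbalance:::comparison_pairs(simulate_portfolio(cfg)$trial_set)
    out <- compare_sd_collections(pairs$drug$age_sd, pairs$control$age_sd,
                                  mode = "paired")
    hits <- hits + (out$p < 0.05)
  }
  expect_gt(hits / 25, 0.5)
})

test_that("variance-ratio test puts the larger variance on top", {
  vt <- variance_equality_test(2, 31, 1, 31)
  expect_equal(vt$statistic, 4)
  expect_equal(c(vt$df1, vt$df2), c(30, 30))
  expect_equal(vt$p_value, 2 * pf(4, 30, 30, lower.tail = FALSE))
  expect_equal(vt$larger, "arm1")
  eqv <- variance_equality_test(3, 20, 3, 20)
  expect_equal(eqv$statistic, 1)
  expect_equal(eqv$p_value, 1)
  # tied SDs with unequal df stay symmetric under arm exchange
  t1 <- variance_equality_test(3, 20, 3, 25)
  t2 <- variance_equality_test(3, 25, 3, 20)
  expect_equal(t1$p_value, t2$p_value)
  # symmetry in the two arms
  a <- variance_equality_test(2.5, 40, 1.8, 60)
  b <- variance_equality_test(1.8, 60, 2.5, 40)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_error(variance_equality_test(0, 10, 1, 10), "degenerate")
})

test_that("variance-ratio p agrees with var.test on raw samples", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(40, sd = 2); y <- rnorm(25, sd = 1.4)
    ref <- var.test(x, y)
    mine <- variance_equality_test(sd(x), 40, sd(y), 25)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the F surrogate tracks Levene's test on individual data", {
  set.seed(21)
  agree <- mapply(function(n1, n2, s2) {
    x <- rnorm(n1); y <- rnorm(n2, sd = s2)
    lev <- levene_test(c(x, y), rep(c("a", "b"), c(n1, n2)))$p_value
    f <- variance_equality_test(sd(x), n1, sd(y), n2)$p_value
    c(lev, f)
  }, n1 = rep(c(80, 200), 10), n2 = rep(c(120, 150), 10),
     s2 = rep(c(1, 1.5), each = 10))
  # strong rank agreement between the surrogate and the original
  expect_gt(cor(agree[1, ], agree[2, ], method = "spearman"), 0.8)
})

test_that("levene_test matches car::leveneTest with mean centring", {
  library(car)
  set.seed(3)
  x <- rnorm(120, sd = rep(c(1, 1.6), 60))
  g <- rep(c("a", "b"), 60)
  mine <- levene_test(x, g)
  ref <- car::leveneTest(x ~ factor(g), center = "mean")
  expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(mine$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("p-value distribution summarises deciles and a threshold", {
  out <- pvalue_distribution(c(0.04, 0.5, 0.96))
  expect_equal(out$n_below, 1L)
  expect_equal(out$fraction_below, 1 / 3)
  expect_equal(sum(out$histogram$count), 3)
  expect_equal(out$histogram$count[c(1, 6, 10)], c(1L, 1L, 1L))
  # a 10-below-0.05-of-43 composition reports 23%
  ps <- c(seq(0.001, 0.049, length.out = 10), seq(0.06, 1, length.out = 33))
  frac <- pvalue_distribution(ps)$fraction_below
  expect_equal(round(100 * frac), 23)
  # boundary handling: p = 1 lands in the last bin
  expect_equal(pvalue_distribution(c(1, 1))$histogram$count[10], 2L)
  expect_error(pvalue_distribution(numeric()), "no p-values")
  expect_error(pvalue_distribution(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("pooled_sd_table pairs arms over the same trials", {
  ts <- complete_fixture()
  tab <- pooled_sd_table(ts)
  expect_setequal(tab$characteristic, c("age", "ldl", "bmi"))
  expect_equal(tab$k, rep(2L, 3))
  age <- tab[tab$characteristic == "age", ]
  expect_equal(age$pooled_sd_drug,
               pooled_sd(c(9.6, 10.2), c(100, 200))$value)
})
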