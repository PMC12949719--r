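test_that("demographics tests are null on mirrored groups", {
  tab <- demographics_table(mirror_cohort(), variables = c("age", "bmi", "alps"))
  cont <- tab[tab$variable != "sex", ]
  expect_true(all(cont$p > 0.99))
  expect_true(all(abs(cont$statistic[cont$test %in% c("Welch t", "Student t")]) < 1e-10))
})

test_that("demographics routing and power match the study design", {
  set.seed(14)
  n <- 10000
  coh <- data.frame(
    group = rep(c("CD", "HC"), each = n),
    sex = "female",
    bmi = c(rnorm(n, 26.32, 3.7), rnorm(n, 22.78, 3.7)),
    cortisol_8am = c(rlnorm(n, log(683), 0.37), rlnorm(n, log(330), 0.32)))
  tab <- demographics_table(coh, variables = c("bmi", "cortisol_8am"))
  expect_lt(tab$p[tab$variable == "bmi"], 1e-15)
  # log-normal cortisol fails the normality screen and routes to Mann-Whitney
  expect_equal(tab$test[tab$variable == "cortisol_8am"], "Mann-Whitney U")
  expect_lt(tab$p[tab$variable == "cortisol_8am"], 1e-15)
})

test_that("sex distribution of the study groups is not significant", {
  coh <- data.frame(
    group = rep(c("CD", "HC"), times = c(66, 64)),
    sex = c(rep("female", 60), rep("male", 6), rep("female", 59), rep("male", 5)),
    age = 40)
  tab <- demographics_table(coh, variables = character(0))
  expect_equal(tab$variable, "sex")
  expect_gt(tab$p, 0.05)
})

test_that("Welch test from summary statistics matches t.test", {
  w <- welch_from_summary(5, 1, 30, 5, 2, 40)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  set.seed(3)
  x <- rnorm(25, 1, 2); y <- rnorm(35, 0.2, 1.4)
  w <- welch_from_summary(mean(x), sd(x), 25, mean(y), sd(y), 35)
  tt <- t.test(x, y)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(w$p, tt$p.value, tolerance = 1e-12)
  expect_error(welch_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("adjusted group difference recovers a planted effect", {
  set.seed(8)
  cfg <- cohort_config(n_cd = 500L, n_hc = 500L, seed = 81L)
  g <- generate_cohort(cfg)
  res <- adjusted_group_difference(g$cohort, "SLF I_L_FA")
  planted <- -0.8 * cfg$sd_fa
  se <- res$adjusted_effect / res$t_statistic
  expect_lt(abs(res$adjusted_effect - planted), 3 * se)
  expect_equal(res$direction, "decrease")
  expect_equal(res$n_used, 1000L)
})

test_that("rank-deficient designs are rejected with the offending column", {
  coh <- mirror_cohort()
  coh$age2 <- coh$age
  expect_error(adjusted_group_difference(coh, "alps", c("age", "age2")),
               "rank deficient.*age2")
})

test_that("BH adjustment matches an independent step-up evaluation", {
  step_up <- function(p) {           # independent hand implementation
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.3), 0.3)
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- fdr_bh(p)
    expect_equal(q, step_up(p))
    expect_true(all(q >= p))
    # order invariance and monotonicity in the raw values
    sh <- sample(length(p))
    expect_equal(fdr_bh(p[sh]), q[sh])
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("partial correlation reduces to Pearson and recovers planted values", {
  set.seed(6)
  d <- data.frame(x = rnorm(200), y = rnorm(200), z = rnorm(200))
  pc <- partial_correlation(d, "x", "y")
  expect_equal(pc$r, cor(d$x, d$y), tolerance = 1e-12)
  expect_equal(pc$p_raw, cor.test(d$x, d$y)$p.value, tolerance = 1e-10)
  expect_equal(partial_correlation(d, "x", "x", "z")$r, 1)

  # true partial r = 0.42 given three covariates
  n <- 10000
  Z <- matrix(rnorm(3 * n), n, 3)
  e1 <- rnorm(n)
  e2 <- 0.42 * e1 + sqrt(1 - 0.42^2) * rnorm(n)
  d <- data.frame(x = Z %*% c(1, -1, 0.5) + e1, y = Z %*% c(0.3, 0.2, -1) + e2,
                  z1 = Z[, 1], z2 = Z[, 2], z3 = Z[, 3])
  pc <- partial_correlation(d, "x", "y", c("z1", "z2", "z3"))
  expect_lt(abs(pc$r - 0.42), 0.03)
  expect_equal(pc$df, n - 3 - 2)
})

test_that("correlation panel applies FDR within the family", {
  set.seed(7)
  n <- 500
  d <- data.frame(x = rnorm(n))
  d$hit <- 0.4 * d$x + sqrt(1 - 0.16) * rnorm(n)
  for (j in 1:9) d[[paste0("null", j)]] <- rnorm(n)
  pan <- correlation_panel(d, "x", c("hit", paste0("null", 1:9)))
  expect_true(pan$significant[pan$y == "hit"])
  expect_equal(sum(pan$significant), 1)
  one <- correlation_panel(d, "x", "hit")
  expect_equal(one$p_fdr, one$p_raw)
})

test_that("a single huge tract effect is the top FDR discovery", {
  tmpl <- default_tract_effects(0, 0)
  tmpl$fa_shift[tmpl$tract == "CST_L"] <- -2
  g <- generate_cohort(cohort_config(tract_effect_template = tmpl, seed = 90L,
                                     path_b = 0, path_a = 0))
  pan <- tract_panel_comparison(g$cohort, "FA")
  expect_true(pan$significant[pan$tract == "CST_L"])
  expect_equal(pan$tract[which.min(pan$p_fdr)], "CST_L")
  # single-discovery BH: the smallest raw p is multiplied by the family size
  expect_equal(min(pan$p_fdr), min(pan$p_raw) * 42, tolerance = 1e-12)
})
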