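test_that("product-of-coefficients recovers a known generative model", {
  set.seed(10)
  n <- 10000
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.8 * m + rnorm(n)                 # no direct effect
  d <- data.frame(x = x, m = m, y = y)
  spec <- mediation_spec(treatment = "x", mediator = "m", outcome = "y",
                         covariates = character(), n_boot = 300,
                         standardize = FALSE, seed = 4)
  fit <- fit_mediation(d, spec)
  boot_se <- apply(fit$ci, 1, diff) / (2 * qnorm(0.975))
  expect_lt(abs(fit$acme - 0.4), 3 * boot_se["acme"])
  expect_lt(abs(fit$ade - 0), 3 * boot_se["ade"])
  expect_equal(fit$a_path, 0.5, tolerance = 0.05)
  expect_equal(fit$b_path, 0.8, tolerance = 0.05)
  expect_equal(fit$classification, "full")
})

test_that("TE = ACME + ADE holds exactly and CIs contain their estimates", {
  set.seed(11)
  for (i in 1:5) {
    n <- 150
    d <- data.frame(x = rnorm(n), c1 = rnorm(n), c2 = rnorm(n))
    d$m <- 0.4 * d$x + 0.2 * d$c1 + rnorm(n)
    d$y <- 0.3 * d$m + 0.2 * d$x - 0.1 * d$c2 + rnorm(n)
    fit <- fit_mediation(d, mediation_spec("x", "m", "y", c("c1", "c2"),
                                           n_boot = 150, seed = i))
    expect_lt(abs(fit$te - (fit$acme + fit$ade)), 1e-10)
    expect_gte(fit$acme, fit$ci["acme", 1]); expect_lte(fit$acme, fit$ci["acme", 2])
    expect_gte(fit$ade, fit$ci["ade", 1]);   expect_lte(fit$ade, fit$ci["ade", 2])
  }
})

test_that("bootstrap is reproducible under a fixed seed", {
  g <- generate_cohort(cohort_config())
  cd <- g$cohort[g$cohort$group == "CD", ]
  spec <- mediation_spec(n_boot = 200, seed = 77)
  f1 <- fit_mediation(cd, spec)
  f2 <- fit_mediation(cd, spec)
  expect_identical(f1$ci, f2$ci)
  expect_identical(f1$p, f2$p)
  expect_equal(f1$n_used, 69L)
})

test_that("noise covariates leave the estimates essentially unchanged", {
  set.seed(12)
  n <- 2000
  d <- data.frame(x = rnorm(n))
  d$m <- -0.35 * d$x + rnorm(n)
  d$y <- 0.4 * d$m + rnorm(n)
  d$junk1 <- rnorm(n); d$junk2 <- rnorm(n)
  base <- fit_mediation(d, mediation_spec("x", "m", "y", character(),
                                          n_boot = 150, seed = 1))
  with_j <- fit_mediation(d, mediation_spec("x", "m", "y", c("junk1", "junk2"),
                                            n_boot = 150, seed = 1))
  expect_equal(with_j$acme, base$acme, tolerance = 0.02)
  expect_equal(with_j$ade, base$ade, tolerance = 0.02)
})

test_that("classification follows the confidence-interval rule", {
  mk <- function(acme_ci, ade_ci)
    list(ci = rbind(acme = acme_ci, ade = ade_ci, te = c(-1, 1)))
  # the reported study pattern: mediated path significant, direct path not
  expect_equal(classify_mediation(mk(c(-0.319, -0.013), c(-0.204, 0.277))), "full")
  expect_equal(classify_mediation(mk(c(-0.3, -0.1), c(-0.4, -0.2))), "partial")
  expect_equal(classify_mediation(mk(c(-0.1, 0.2), c(-0.4, -0.2))), "none")
})

test_that("null-mediator ACME intervals achieve nominal coverage", {
  set.seed(13)
  cover <- vapply(1:100, function(i) {
    n <- 200
    x <- rnorm(n)
    m <- 0.5 * x + rnorm(n)            # a path present
    y <- 0.3 * x + rnorm(n)            # b path absent: true ACME = 0
    d <- data.frame(x = x, m = m, y = y)
    fit <- fit_mediation(d, mediation_spec("x", "m", "y", character(),
                                           n_boot = 199, seed = i))
    fit$ci["acme", 1] <= 0 && fit$ci["acme", 2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("a null-path cohort yields a near-zero ACME", {
  g <- generate_cohort(cohort_config(n_cd = 5000L, n_hc = 64L,
                                     path_a = 0, path_b = 0, seed = 19L))
  cd <- g$cohort[g$cohort$group == "CD", ]
  fit <- fit_mediation(cd, mediation_spec(n_boot = 150, seed = 3))
  expect_lt(abs(fit$acme), 0.02)
})

test_that("degenerate inputs are rejected", {
  d <- data.frame(x = rnorm(6), m = rnorm(6), y = rnorm(6))
  expect_error(fit_mediation(d, mediation_spec("x", "m", "y", character(),
                                               n_boot = 100)),
               "too few")
  expect_error(mediation_spec(n_boot = 10), ">= 100")
  expect_error(mediation_spec(ci_level = 1.2), "\\(0, 1\\)")
})
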