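#' Configuration for the synthetic subject cohort
#'
#' Generates a subject-level table with the statistical structure of the
#' Cushing's-disease study population: 69 CD patients and 64 healthy
#' controls; group marginals for age, sex, education duration (ED), BMI and
#' total brain volume (TBV); serum cortisol at 8 a.m. (both groups,
#' log-normal matched to the reported median/IQR) and at 4 p.m. and 00:00
#' (CD only; 00:00 normal truncated at zero); a DTI-ALPS index whose CD
#' values depend on standardized 00:00 cortisol through `path_a`; and FA/MD
#' for the 42 atlas tracts, with CD-vs-HC shifts planted from
#' `tract_effect_template` and, for the right SLF III FA, a mediation
#' structure cortisol -> ALPS -> FA.
#'
#' `path_a` is the standardized effect of 00:00 cortisol on ALPS within CD
#' (equivalently their correlation). `path_b` is stated on the
#' partial-correlation scale: the generator solves for the structural slope
#' of standardized ALPS in the outcome equation such that the partial
#' correlation between ALPS and SLF III_R FA given cortisol equals `path_b`,
#' while `direct_effect` is the structural cortisol -> FA coefficient
#' bypassing ALPS (0 = full mediation).
#'
#' @param n_cd,n_hc subjects per group.
#' @param covariate_marginals per-group list of `c(mean, sd)` for `age`,
#'   `ed`, `bmi`, `tbv`, plus `sex_male` (male count in the reference group
#'   table, with its reported group size, as `c(males, n)`).
#' @param cortisol_marginals per-group parameters: medians/IQRs for the
#'   log-normal 8 a.m. (and CD 4 p.m.) draws, mean/sd for CD 00:00.
#' @param alps_marginals per-group `c(mean, sd)` of the ALPS index.
#' @param path_a,path_b,direct_effect standardized mediation-path effects
#'   (see above).
#' @param tract_effect_template data frame `tract, fa_shift, md_shift`
#'   covering all 42 tracts exactly once; see [default_tract_effects()].
#' @param tract_baselines data frame `tract, fa_mean, md_mean`; see
#'   [default_tract_baselines()].
#' @param sd_fa,sd_md within-group SD of tract FA and MD (MD in
#'   10^-3 mm^2/s).
#' @param covariate_effects named numeric vectors `alps` and `slf_fa` over
#'   `c("age","sex_male","ed","bmi","tbv")`: standardized covariate effects
#'   added to the CD ALPS and SLF III_R FA equations (defaults all zero so
#'   path recovery is exactly identified).
#' @param seed integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cd = 69L, n_hc = 64L,
                          covariate_marginals = list(
                            cd = list(age = c(40.94, 10.99), ed = c(11.78, 4.28),
                                      bmi = c(26.32, 4.08), tbv = c(1321560.44, 116852.65),
                                      sex_male = c(6L, 66L)),
                            hc = list(age = c(41.91, 12.87), ed = c(10.83, 3.62),
                                      bmi = c(22.78, 3.33), tbv = c(1384686.91, 94080.69),
                                      sex_male = c(5L, 64L))
                          ),
                          cortisol_marginals = list(
                            cd = list(c8 = c(683.36, 524.74, 869.58),
                                      c16 = c(604.28, 482.73, 751.93),
                                      c0 = c(549.46, 221.59)),
                            hc = list(c8 = c(330.36, 268.21, 411.30))
                          ),
                          alps_marginals = list(cd = c(1.69, 0.20), hc = c(1.76, 0.17)),
                          path_a = -0.354, path_b = 0.42, direct_effect = 0,
                          tract_effect_template = default_tract_effects(),
                          tract_baselines = default_tract_baselines(),
                          sd_fa = 0.03, sd_md = 0.03,
                          covariate_effects = NULL,
                          seed = 20260101L) {
  if (n_cd <= 0L || n_hc <= 0L) abort("group sizes must be positive")
  atlas <- tract_atlas()
  for (tab in list(tract_effect_template, tract_baselines)) {
    if (!setequal(tab$tract, atlas$tract) || anyDuplicated(tab$tract))
      abort("tract table must cover the 42 canonical tracts exactly once (missing: %s)",
            paste(setdiff(atlas$tract, tab$tract), collapse = ", "))
  }
  for (g in c("cd", "hc")) for (v in c("age", "ed", "bmi", "tbv")) {
    if (covariate_marginals[[g]][[v]][2] <= 0)
      abort("SD for %s/%s must be positive", g, v)
  }
  if (abs(path_a) >= 1 || abs(path_b) >= 1)
    abort("standardized paths must lie in (-1, 1)")
  chk_scalar(sd_fa, "sd_fa", 0, strict = TRUE)
  chk_scalar(sd_md, "sd_md", 0, strict = TRUE)
  cov_names <- c("age", "sex_male", "ed", "bmi", "tbv")
  if (is.null(covariate_effects))
    covariate_effects <- list(
      alps = stats::setNames(numeric(5L), cov_names),
      slf_fa = stats::setNames(numeric(5L), cov_names))
  structure(list(
    n_cd = as.integer(n_cd), n_hc = as.integer(n_hc),
    covariate_marginals = covariate_marginals,
    cortisol_marginals = cortisol_marginals,
    alps_marginals = alps_marginals,
    path_a = path_a, path_b = path_b, direct_effect = direct_effect,
    tract_effect_template = tract_effect_template,
    tract_baselines = tract_baselines,
    sd_fa = sd_fa, sd_md = sd_md,
    covariate_effects = covariate_effects,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Log-normal parameters matched to a printed median and interquartile range.
lognormal_from_median_iqr <- function(median, q1, q3) {
  list(meanlog = log(median), sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

# Structural slope of standardized ALPS in the outcome equation such that
# the partial correlation between mediator and outcome given treatment
# equals rho, with structural direct effect d and treatment->mediator
# correlation pa (all variables unit-variance). Solves
#   beta^2 (1 - pa^2 + rho^2 pa^2) + 2 rho^2 pa d beta + rho^2 (d^2 - 1) = 0
# and picks the root whose sign matches rho.
structural_b_from_partial <- function(rho, pa, d) {
  if (rho == 0) return(0)
  A <- 1 - pa^2 + rho^2 * pa^2
  B <- 2 * rho^2 * pa * d
  C <- rho^2 * (d^2 - 1)
  disc <- B^2 - 4 * A * C
  if (disc < 0) abort("no structural slope matches partial correlation %g", rho)
  roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
  roots[sign(roots) == sign(rho)][1L]
}

# Normal draw truncated strictly positive (resampling; tails are mild here).
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate the synthetic subject cohort
#'
#' Draws a cohort table from a [cohort_config()] and returns it together
#' with the generating ground truth (realized structural coefficients and
#' the planted tract template).
#'
#' @param config a [cohort_config()].
#' @return A list with `cohort` (data frame: `subject_id`, `group`, `age`,
#'   `sex`, `ed`, `bmi`, `tbv`, `cortisol_8am`, `cortisol_4pm`,
#'   `cortisol_0000`, `alps`, then `<tract>_FA` and `<tract>_MD` for the 42
#'   tracts; HC 4 p.m./00:00 cortisol are `NA`) and `truth` (class
#'   `cohort_truth`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(substream_seed(config$seed, "cohort"))
  atlas <- tract_atlas()
  tmpl <- config$tract_effect_template[match(atlas$tract, config$tract_effect_template$tract), ]
  base <- config$tract_baselines[match(atlas$tract, config$tract_baselines$tract), ]
  ce <- config$covariate_effects

  draw_group <- function(group) {
    cm <- config$covariate_marginals[[tolower(group)]]
    qm <- config$cortisol_marginals[[tolower(group)]]
    am <- config$alps_marginals[[tolower(group)]]
    n <- if (group == "CD") config$n_cd else config$n_hc

    age <- stats::rnorm(n, cm$age[1], cm$age[2])
    ed  <- pmax(stats::rnorm(n, cm$ed[1], cm$ed[2]), 0)
    bmi <- rnorm_pos(n, cm$bmi[1], cm$bmi[2])
    tbv <- rnorm_pos(n, cm$tbv[1], cm$tbv[2])
    n_male <- as.integer(round(n * cm$sex_male[1] / cm$sex_male[2]))
    sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))
    lp8 <- lognormal_from_median_iqr(qm$c8[1], qm$c8[2], qm$c8[3])
    c8 <- stats::rlnorm(n, lp8$meanlog, lp8$sdlog)

    zcov <- cbind(
      age = (age - cm$age[1]) / cm$age[2],
      sex_male = as.numeric(sex == "male"),
      ed = (ed - cm$ed[1]) / cm$ed[2],
      bmi = (bmi - cm$bmi[1]) / cm$bmi[2],
      tbv = (tbv - cm$tbv[1]) / cm$tbv[2])

    fa <- matrix(NA_real_, n, 42L, dimnames = list(NULL, paste0(atlas$tract, "_FA")))
    md <- matrix(NA_real_, n, 42L, dimnames = list(NULL, paste0(atlas$tract, "_MD")))

    if (group == "CD") {
      lp16 <- lognormal_from_median_iqr(qm$c16[1], qm$c16[2], qm$c16[3])
      c16 <- stats::rlnorm(n, lp16$meanlog, lp16$sdlog)
      c0 <- rnorm_pos(n, qm$c0[1], qm$c0[2])
      z0 <- (c0 - qm$c0[1]) / qm$c0[2]
      pa <- config$path_a
      alps <- am[1] + am[2] * (pa * z0 + drop(zcov %*% ce$alps) +
                                 sqrt(max(0, 1 - pa^2)) * stats::rnorm(n))
      zA <- (alps - am[1]) / am[2]
      bb <- structural_b_from_partial(config$path_b, pa, config$direct_effect)
      sig2 <- max(0, 1 - (bb^2 + config$direct_effect^2 + 2 * bb * config$direct_effect * pa))
      yz <- bb * zA + config$direct_effect * z0 + drop(zcov %*% ce$slf_fa) +
        sqrt(sig2) * stats::rnorm(n)
      for (j in seq_len(42L)) {
        mu_fa <- base$fa_mean[j] + tmpl$fa_shift[j] * config$sd_fa
        if (atlas$tract[j] == "SLF III_R") {
          fa[, j] <- mu_fa + config$sd_fa * yz
        } else {
          fa[, j] <- stats::rnorm(n, mu_fa, config$sd_fa)
        }
        md[, j] <- stats::rnorm(n, base$md_mean[j] + tmpl$md_shift[j] * config$sd_md,
                                config$sd_md)
      }
      extras <- list(c16 = c16, c0 = c0, beta_b = bb, sigma_y = sqrt(sig2))
    } else {
      alps <- stats::rnorm(n, am[1], am[2])
      for (j in seq_len(42L)) {
        fa[, j] <- stats::rnorm(n, base$fa_mean[j], config$sd_fa)
        md[, j] <- stats::rnorm(n, base$md_mean[j], config$sd_md)
      }
      extras <- list(c16 = rep(NA_real_, n), c0 = rep(NA_real_, n))
    }

    df <- data.frame(
      subject_id = sprintf("%s%04d", group, seq_len(n)),
      group = group, age = age, sex = sex, ed = ed, bmi = bmi, tbv = tbv,
      cortisol_8am = c8, cortisol_4pm = extras$c16, cortisol_0000 = extras$c0,
      alps = alps, stringsAsFactors = FALSE)
    list(df = cbind(df, as.data.frame(fa, check.names = FALSE),
                    as.data.frame(md, check.names = FALSE)),
         extras = extras)
  }

  cd <- draw_group("CD")
  hc <- draw_group("HC")
  cohort <- rbind(cd$df, hc$df)
  rownames(cohort) <- NULL
  truth <- structure(list(
    config = config,
    beta_b = cd$extras$beta_b,
    sigma_y = cd$extras$sigma_y,
    tract_effect_template = tmpl,
    tract_baselines = base
  ), class = "cohort_truth")
  list(cohort = cohort, truth = truth)
}
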