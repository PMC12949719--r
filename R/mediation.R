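#' Specification of a simple mediation model
#'
#' Single-mediator linear mediation without exposure-mediator interaction:
#' a mediator model `M ~ X + C` and an outcome model `Y ~ X + M + C`, both
#' ordinary least squares. The default analysis takes 00:00 serum cortisol
#' as the treatment, the DTI-ALPS index as the mediator and right SLF III FA
#' as the outcome, adjusting both models for the study covariates.
#'
#' @param treatment treatment (exposure) column name.
#' @param mediator mediator column name.
#' @param outcome outcome column name.
#' @param covariates covariate column names included in both models.
#' @param n_boot bootstrap replicates (>= 100).
#' @param ci_level confidence level for the percentile intervals.
#' @param standardize z-score treatment, mediator and outcome on the
#'   analysis sample before fitting, so effects are on the standardized
#'   scale; set `FALSE` for raw-scale coefficients.
#' @param seed integer seed for the bootstrap resampling.
#' @return An object of class `mediation_spec`.
#' @export
mediation_spec <- function(treatment = "cortisol_0000",
                           mediator = "alps",
                           outcome = "SLF III_R_FA",
                           covariates = c("age", "sex", "ed", "bmi", "tbv"),
                           n_boot = 5000L, ci_level = 0.95,
                           standardize = TRUE, seed = 1L) {
  if (n_boot < 100L) abort("'n_boot' must be >= 100")
  if (ci_level <= 0 || ci_level >= 1) abort("'ci_level' must be in (0, 1)")
  structure(list(treatment = treatment, mediator = mediator, outcome = outcome,
                 covariates = covariates, n_boot = as.integer(n_boot),
                 ci_level = ci_level, standardize = standardize,
                 seed = as.integer(seed)),
            class = "mediation_spec")
}

# Point estimates from prepared matrices: a and b coefficients, ACME = a*b,
# ADE = c' (treatment in the outcome model), TE = c (treatment in Y ~ X + C).
mediation_point <- function(x, m, y, C) {
  Xm <- cbind(1, x, C)
  a <- stats::lm.fit(Xm, m)$coefficients[2L]
  Xy <- cbind(1, x, m, C)
  fy <- stats::lm.fit(Xy, y)$coefficients
  cprime <- fy[2L]; b <- fy[3L]
  cc <- stats::lm.fit(Xm, y)$coefficients[2L]
  c(acme = unname(a * b), ade = unname(cprime), te = unname(cc),
    a = unname(a), b = unname(b))
}

#' Fit a simple mediation model with bootstrap confidence intervals
#'
#' Product-of-coefficients mediation: `ACME = a * b`, `ADE = c'`, and
#' `TE = c` from the reduced model; for nested OLS models these satisfy
#' `TE = ACME + ADE` exactly. Uncertainty comes from a nonparametric
#' bootstrap (rows resampled with replacement, fixed seed): percentile
#' confidence intervals and two-sided p-values
#' `2 * min(frac <= 0, frac >= 0)`, floored at `2 / n_boot`. A degenerate
#' resample (constant treatment, mediator or outcome) is redrawn and
#' counted. Variables are z-scored on the analysis sample when the spec
#' says so; covariates enter both models untransformed (sex as a male
#' indicator).
#'
#' @param cohort cohort data frame (commonly the CD group only; rows with
#'   missing values in any used column are dropped).
#' @param spec a [mediation_spec()].
#' @return A list of class `mediation_result`: `acme`, `ade`, `te`,
#'   `prop_mediated`, `a_path`, `b_path`, `ci` (3 x 2 matrix), `p` (named
#'   vector), `classification`, `n_used`, `n_boot`, `n_degenerate`,
#'   `standardized`.
#' @export
fit_mediation <- function(cohort, spec = mediation_spec()) {
  stopifnot(inherits(spec, "mediation_spec"))
  for (v in c(spec$treatment, spec$mediator, spec$outcome))
    if (!v %in% names(cohort)) abort("column '%s' not in cohort", v)
  x <- as.numeric(cohort[[spec$treatment]])
  m <- as.numeric(cohort[[spec$mediator]])
  y <- as.numeric(cohort[[spec$outcome]])
  C <- if (length(spec$covariates)) build_design(cohort, spec$covariates) else NULL
  keep <- stats::complete.cases(cbind(x, m, y, C))
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  C <- if (is.null(C)) matrix(nrow = sum(keep), ncol = 0L) else C[keep, , drop = FALSE]
  n <- length(x)
  npar <- 3L + ncol(C)
  if (n < npar + 5L) abort("too few complete rows (%d) for mediation", n)
  check_full_rank(cbind(1, x, m, C))
  if (spec$standardize) {
    zs <- function(v) (v - mean(v)) / stats::sd(v)
    x <- zs(x); m <- zs(m); y <- zs(y)
  }

  pt <- mediation_point(x, m, y, C)
  if (abs(pt[["te"]] - (pt[["acme"]] + pt[["ade"]])) > 1e-10)
    abort("internal error: TE != ACME + ADE beyond tolerance")

  set.seed(spec$seed)
  draws <- matrix(NA_real_, spec$n_boot, 3L,
                  dimnames = list(NULL, c("acme", "ade", "te")))
  n_degen <- 0L
  for (i in seq_len(spec$n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) > 0 && stats::sd(m[idx]) > 0 && stats::sd(y[idx]) > 0) break
      n_degen <- n_degen + 1L
    }
    draws[i, ] <- mediation_point(x[idx], m[idx], y[idx], C[idx, , drop = FALSE])[1:3]
  }

  alpha <- 1 - spec$ci_level
  ci <- t(apply(draws, 2L, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2)))
  pboot <- apply(draws, 2L, function(d)
    max(2 * min(mean(d <= 0), mean(d >= 0)), 2 / spec$n_boot))

  res <- structure(list(
    acme = pt[["acme"]], ade = pt[["ade"]], te = pt[["te"]],
    prop_mediated = if (pt[["te"]] != 0) pt[["acme"]] / pt[["te"]] else NA_real_,
    a_path = pt[["a"]], b_path = pt[["b"]],
    ci = ci, p = pboot, classification = NA_character_,
    n_used = n, n_boot = spec$n_boot, n_degenerate = n_degen,
    standardized = spec$standardize, spec = spec
  ), class = "mediation_result")
  res$classification <- classify_mediation(res)
  res
}

#' Classify a mediation result as full, partial or none
#'
#' Confidence-interval rule: "full" when the ACME interval excludes zero and
#' the ADE interval includes it; "partial" when both exclude zero; "none"
#' when the ACME interval includes zero.
#'
#' @param result a `mediation_result`, or any list carrying a `ci` matrix
#'   with rows `acme` and `ade`.
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
classify_mediation <- function(result) {
  ci <- result$ci
  if (is.null(ci)) abort("result carries no confidence intervals")
  excludes0 <- function(r) ci[r, 1] > 0 || ci[r, 2] < 0
  if (!excludes0("acme")) "none"
  else if (excludes0("ade")) "partial"
  else "full"
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n = %d, %s scale, %d bootstrap reps\n",
              x$n_used, if (x$standardized) "standardized" else "raw", x$n_boot))
  for (e in c("acme", "ade", "te"))
    cat(sprintf("  %-4s %8.4f  [%8.4f, %8.4f]  p = %.4f\n",
                toupper(e), x[[e]], x$ci[e, 1], x$ci[e, 2], x$p[[e]]))
  cat(sprintf("  classification: %s mediation\n", x$classification))
  invisible(x)
}
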