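#' Demographics and clinical comparison table
#'
#' Group comparison of the demographic/clinical variables in the style of a
#' cohort Table 1. Continuous variables are screened for normality per group
#' (Shapiro-Wilk at alpha = 0.05) and routed to a Welch two-sample t test
#' when both groups pass, otherwise to a Mann-Whitney U test (normal
#' approximation with tie correction). The categorical sex variable is
#' tested by Pearson's chi-square, with Yates continuity correction applied
#' only when some expected cell count is below 5. Summaries are mean +/- SD
#' for normal variables and median (IQR) otherwise; variables absent in one
#' group (e.g. afternoon/midnight cortisol in controls) are summarised for
#' the group that has them, with no test.
#'
#' @param cohort cohort data frame (see [generate_cohort()]).
#' @param variables continuous variables to test.
#' @param pooled_t logical; use the pooled-variance Student t instead of
#'   Welch for normality-routed variables.
#' @return A data frame with one row per variable: `variable`, `summary_cd`,
#'   `summary_hc`, `test`, `statistic`, `p`, `n_cd`, `n_hc`.
#' @export
demographics_table <- function(cohort,
                               variables = c("age", "ed", "bmi", "tbv",
                                             "cortisol_8am", "cortisol_4pm",
                                             "cortisol_0000", "alps"),
                               pooled_t = FALSE) {
  if (!all(cohort$group %in% c("CD", "HC"))) abort("group must be CD or HC")
  if (!any(cohort$group == "CD") || !any(cohort$group == "HC"))
    abort("both groups must be non-empty")

  fmt_norm <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  fmt_med  <- function(x) sprintf("%.2f (%.2f, %.2f)", stats::median(x),
                                  stats::quantile(x, 0.25), stats::quantile(x, 0.75))
  rows <- list()

  for (v in variables) {
    if (!v %in% names(cohort)) abort("variable '%s' not in cohort", v)
    x <- cohort[[v]][cohort$group == "CD"]; x <- x[!is.na(x)]
    y <- cohort[[v]][cohort$group == "HC"]; y <- y[!is.na(y)]
    if (length(x) && length(y)) {
      if (length(x) < 3L || length(y) < 3L)
        abort("variable '%s' has a group with < 3 observations", v)
      normal <- shapiro_ok(x) && shapiro_ok(y)
      if (normal) {
        tt <- stats::t.test(x, y, var.equal = pooled_t)
        rows[[v]] <- data.frame(variable = v, summary_cd = fmt_norm(x),
                                summary_hc = fmt_norm(y),
                                test = if (pooled_t) "Student t" else "Welch t",
                                statistic = unname(tt$statistic), p = tt$p.value,
                                n_cd = length(x), n_hc = length(y))
      } else {
        wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
        rows[[v]] <- data.frame(variable = v, summary_cd = fmt_med(x),
                                summary_hc = fmt_med(y),
                                test = "Mann-Whitney U",
                                statistic = unname(wt$statistic), p = wt$p.value,
                                n_cd = length(x), n_hc = length(y))
      }
    } else {
      summ <- function(z) if (!length(z)) "—"
        else if (shapiro_ok(z)) fmt_norm(z) else fmt_med(z)
      rows[[v]] <- data.frame(variable = v, summary_cd = summ(x),
                              summary_hc = summ(y), test = "none",
                              statistic = NA_real_, p = NA_real_,
                              n_cd = length(x), n_hc = length(y))
    }
  }

  if ("sex" %in% names(cohort)) {
    tab <- table(factor(cohort$group, c("CD", "HC")),
                 factor(cohort$sex, c("female", "male")))
    expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$expected)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = any(expected < 5)))
    rows[["sex"]] <- data.frame(
      variable = "sex",
      summary_cd = sprintf("%dF/%dM", tab["CD", "female"], tab["CD", "male"]),
      summary_hc = sprintf("%dF/%dM", tab["HC", "female"], tab["HC", "male"]),
      test = "chi-square", statistic = unname(ct$statistic), p = ct$p.value,
      n_cd = sum(tab["CD", ]), n_hc = sum(tab["HC", ]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shapiro-Wilk normality screen at alpha = 0.05 (test capped at its n = 5000
# implementation limit; essentially-constant samples are treated as
# non-normal rather than erroring).
shapiro_ok <- function(x, alpha = 0.05) {
  if (length(x) < 3L) return(FALSE)
  if (stats::sd(x) < .Machine$double.eps^0.5 * max(1, abs(mean(x)))) return(FALSE)
  if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
  stats::shapiro.test(x)$p.value >= alpha
}

#' Welch t test from printed summary statistics
#'
#' Two-sample Welch t with Satterthwaite degrees of freedom, computed from
#' group means, SDs and sizes only — lets published summary tables be
#' re-tested without subject-level data.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return A list with `t`, `df`, `p` (two-tailed).
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) abort("SDs must be positive")
  if (n1 < 2 || n2 < 2) abort("group sizes must be >= 2")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Internal: design matrix for covariate-adjusted models. Sex is coded as a
# male indicator (female = 0). Listwise deletion of incomplete rows.
build_design <- function(cohort, columns) {
  cols <- lapply(columns, function(v) {
    if (!v %in% names(cohort)) abort("column '%s' not in cohort", v)
    x <- cohort[[v]]
    if (v == "sex") as.numeric(x == "male") else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- ifelse(columns == "sex", "sex_male", columns)
  X
}

# Internal: full-rank check naming the collinear columns.
check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    abort("design matrix is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  invisible(q)
}

#' Covariate-adjusted group difference for one outcome
#'
#' Ordinary least squares of the outcome on a CD indicator plus covariates;
#' reports the group coefficient (the adjusted CD-vs-HC difference), its t
#' statistic and two-tailed p. Rows with any missing value in the used
#' columns are dropped and the remaining n recorded.
#'
#' @param cohort cohort data frame.
#' @param outcome outcome column name.
#' @param covariates covariate column names (default the study's adjustment
#'   set: age, sex, ED, BMI, TBV).
#' @return A one-row data frame of class `group_comparison`: `variable`,
#'   `adjusted_effect`, `t_statistic`, `p_raw`, `p_fdr` (`NA` until a panel
#'   applies FDR), `direction`, `n_used`.
#' @export
adjusted_group_difference <- function(cohort, outcome,
                                      covariates = c("age", "sex", "ed", "bmi", "tbv")) {
  y <- as.numeric(cohort[[outcome]])
  if (is.null(cohort[[outcome]])) abort("outcome '%s' not in cohort", outcome)
  grp <- as.numeric(cohort$group == "CD")
  X <- cbind(`(Intercept)` = 1, group_cd = grp,
             if (length(covariates)) build_design(cohort, covariates))
  keep <- stats::complete.cases(cbind(y, X))
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  if (nrow(X) < ncol(X) + 2L)
    abort("too few complete rows (%d) for %d parameters", nrow(X), ncol(X))
  check_full_rank(X)
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  dfree <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / dfree
  XtXi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXi[2L, 2L])
  beta <- fit$coefficients[["group_cd"]]
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), dfree)
  structure(data.frame(
    variable = outcome, adjusted_effect = beta, t_statistic = tstat,
    p_raw = p, p_fdr = NA_real_,
    direction = if (beta >= 0) "increase" else "decrease",
    n_used = nrow(X), stringsAsFactors = FALSE
  ), class = c("group_comparison", "data.frame"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")` with input
#' validation): sort ascending, take the running minimum of `p * m / rank`
#' from the largest rank down, cap at 1, return in input order.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
fdr_bh <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    abort("p-values must be numeric in [0, 1] with no missing values")
  stats::p.adjust(p_values, method = "BH")
}

#' Covariate-adjusted group comparison across the 42-tract panel
#'
#' Runs [adjusted_group_difference()] per tract for the chosen metric and
#' applies Benjamini-Hochberg FDR within that 42-test family; tracts with
#' `p_fdr < alpha` are flagged, with the direction of the adjusted effect.
#'
#' @param cohort cohort data frame with `<tract>_FA` / `<tract>_MD` columns.
#' @param metric `"FA"` or `"MD"`.
#' @param covariates adjustment set.
#' @param alpha FDR threshold for the `significant` flag.
#' @return A data frame with one row per tract: the [adjusted_group_difference()]
#'   fields plus `tract`, `p_fdr`, `significant`.
#' @export
tract_panel_comparison <- function(cohort, metric = c("FA", "MD"),
                                   covariates = c("age", "sex", "ed", "bmi", "tbv"),
                                   alpha = 0.05) {
  metric <- match.arg(metric)
  atlas <- tract_atlas()
  cols <- paste0(atlas$tract, "_", metric)
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    abort("cohort lacks tract columns: %s", paste(missing, collapse = ", "))
  rows <- lapply(cols, function(cl)
    adjusted_group_difference(cohort, cl, covariates))
  out <- do.call(rbind, rows)
  out$tract <- atlas$tract
  out$p_fdr <- fdr_bh(out$p_raw)
  out$significant <- out$p_fdr < alpha
  rownames(out) <- NULL
  out[, c("tract", "variable", "adjusted_effect", "t_statistic",
          "p_raw", "p_fdr", "direction", "significant", "n_used")]
}

#' Covariate-adjusted (partial) Pearson correlation
#'
#' Residualises `x` and `y` on the covariates (with intercept) by OLS and
#' takes the Pearson correlation of the residuals; the p-value comes from
#' `t = r sqrt(df / (1 - r^2))` with `df = n - #covariates - 2`. With an
#' empty covariate set this is the plain Pearson correlation. Rows with any
#' missing value among the used columns are dropped.
#'
#' @param cohort cohort data frame (commonly pre-filtered to one group).
#' @param x,y column names to correlate.
#' @param covariates covariate column names (possibly empty).
#' @return A one-row data frame of class `partial_correlation`: `x`, `y`,
#'   `covariates`, `r`, `p_raw`, `p_fdr` (`NA` until a panel applies FDR),
#'   `n`, `df`.
#' @export
partial_correlation <- function(cohort, x, y, covariates = character()) {
  xv <- as.numeric(cohort[[x]]); yv <- as.numeric(cohort[[y]])
  if (is.null(cohort[[x]]) || is.null(cohort[[y]]))
    abort("columns '%s'/'%s' not both in cohort", x, y)
  C <- cbind(`(Intercept)` = rep(1, length(xv)),
             if (length(covariates)) build_design(cohort, covariates))
  keep <- stats::complete.cases(cbind(xv, yv, C))
  xv <- xv[keep]; yv <- yv[keep]; C <- C[keep, , drop = FALSE]
  k <- length(covariates)
  if (length(xv) <= k + 3L)
    abort("too few complete rows (%d) for %d covariates", length(xv), k)
  check_full_rank(C)
  rx <- stats::residuals(stats::lm.fit(C, xv))
  ry <- stats::residuals(stats::lm.fit(C, yv))
  r <- stats::cor(rx, ry)
  dfree <- length(xv) - k - 2L
  tstat <- r * sqrt(dfree / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), dfree)
  structure(data.frame(
    x = x, y = y, covariates = paste(covariates, collapse = "+"),
    r = r, p_raw = p, p_fdr = NA_real_, n = length(xv), df = dfree,
    stringsAsFactors = FALSE
  ), class = c("partial_correlation", "data.frame"))
}

#' Panel of covariate-adjusted correlations with FDR
#'
#' [partial_correlation()] of `x` against each outcome in `y_names`, with
#' Benjamini-Hochberg adjustment across the panel.
#'
#' @inheritParams partial_correlation
#' @param y_names character vector of outcome columns (the FDR family).
#' @param alpha FDR threshold for the `significant` flag.
#' @return A data frame with one row per outcome, including `p_fdr` and
#'   `significant`.
#' @export
correlation_panel <- function(cohort, x, y_names, covariates = character(),
                              alpha = 0.05) {
  rows <- lapply(y_names, function(y) partial_correlation(cohort, x, y, covariates))
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_bh(out$p_raw)
  out$significant <- out$p_fdr < alpha
  rownames(out) <- NULL
  out
}
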