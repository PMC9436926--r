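# Deterministic statistical kernels shared by every analysis stage.

test_result <- function(estimate, statistic, df, p, two_sided = TRUE, ...) {
  tibble(estimate = estimate, statistic = statistic, df = df, p = p,
         two_sided = two_sided, ...)
}

#' Tail probability of the t distribution
#'
#' Maps a t statistic and its residual degrees of freedom to a p-value;
#' every (statistic, DF, p) triple reported by the pipeline passes through
#' this function, so reported p-values are internally consistent by
#' construction.
#'
#' @param statistic t statistic (finite; vectorised).
#' @param df Residual degrees of freedom, `>= 1`. May be non-integer (the
#'   moderated-t stage produces fractional total degrees of freedom) or
#'   infinite (normal limit).
#' @param two_sided If `TRUE` (default) returns `P(|T| >= |statistic|)`,
#'   else the upper tail `P(T >= statistic)`.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' t_tail_p(2.717, 59) # the Ch1-3 qT1 case-control example
#' @export
t_tail_p <- function(statistic, df, two_sided = TRUE) {
  check_numeric(statistic, "statistic")
  if (any(is.na(statistic))) {
    bft_stop("`statistic` contains missing values.", "bftrans_error_invalid_argument")
  }
  if (!is.numeric(df) || any(is.na(df)) || any(df < 1)) {
    bft_stop("`df` must be numeric and >= 1.", "bftrans_error_invalid_argument")
  }
  if (two_sided) {
    2 * pt(abs(statistic), df, lower.tail = FALSE)
  } else {
    pt(statistic, df, lower.tail = FALSE)
  }
}

#' Pearson correlation with t-based test
#'
#' Complete pairs only; the test statistic is `r * sqrt(df / (1 - r^2))`
#' with `df = n - 2`, referred to the t distribution.
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values are
#'   dropped, and at least 3 complete, non-constant pairs are required.
#' @return One-row tibble: `estimate` (r), `statistic`, `df`, `p`,
#'   `two_sided`, `n_used`.
#' @export
pearson_r_test <- function(x, y) {
  check_numeric(x, "x", finite = FALSE)
  check_numeric(y, "y", finite = FALSE)
  if (length(x) != length(y)) {
    bft_stop("`x` and `y` must have equal length.", "bftrans_error_invalid_argument")
  }
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    bft_stop("Need at least 3 complete pairs.", "bftrans_error_insufficient_data")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    bft_stop("Correlation undefined for constant input.",
             "bftrans_error_constant_input")
  }
  r <- cor(x, y)
  df <- n - 2
  if (abs(r) >= 1) {
    stat <- sign(r) * Inf
    p <- 0
  } else {
    stat <- r * sqrt(df / (1 - r^2))
    p <- t_tail_p(stat, df)
  }
  test_result(estimate = r, statistic = stat, df = df, p = p, n_used = n)
}

#' Ordinary least squares with per-predictor t-tests
#'
#' Multiple linear regression used for all covariate-adjusted analyses.
#' Rows with any missing value are dropped listwise and the used n is
#' reported. Rank deficiency is an error naming the offending columns.
#'
#' @param y Numeric response.
#' @param design Data frame of predictors (numeric, logical, or factor).
#' @return Object of class `bft_ols` with `tidy()`/`glance()` methods;
#'   elements `coefficients` (tibble: term, estimate, std_error, statistic,
#'   df, p), `r_squared`, `adj_r_squared`, `df_residual`, `n_used`,
#'   `n_dropped`.
#' @export
ols_fit <- function(y, design) {
  check_numeric(y, "y", finite = FALSE)
  design <- as.data.frame(design)
  if (nrow(design) != length(y)) {
    bft_stop("`design` must have one row per observation.",
             "bftrans_error_invalid_argument")
  }
  dat <- cbind(data.frame(.y = y), design)
  keep <- complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  n <- nrow(dat)
  p_terms <- ncol(design)
  if (n <= p_terms + 1) {
    bft_stop("Too few complete rows for the requested design.",
             "bftrans_error_insufficient_data")
  }
  fit <- lm(.y ~ ., data = dat)
  if (fit$rank < length(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    bft_stop(paste0("Design is rank deficient; aliased columns: ",
                    paste(bad, collapse = ", ")),
             "bftrans_error_collinearity")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  out <- tibble(
    term = rownames(co),
    estimate = unname(co[, 1]),
    std_error = unname(co[, 2]),
    statistic = unname(co[, 3]),
    df = fit$df.residual,
    p = unname(t_tail_p(co[, 3], fit$df.residual))
  )
  structure(
    list(coefficients = out,
         r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared,
         df_residual = fit$df.residual,
         n_used = n,
         n_dropped = sum(!keep),
         fit = fit),
    class = "bft_ols"
  )
}

#' @export
print.bft_ols <- function(x, ...) {
  cat(sprintf("<bft_ols> n = %d (%d dropped), residual df = %d, R^2 = %.4f\n",
              x$n_used, x$n_dropped, x$df_residual, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' Diagnosis-by-predictor interaction model
#'
#' Tests whether the slope of `y` on `x` differs between two groups
#' (the decoupling test): `y ~ x * group + covariates`, returning the
#' t-test of the product term.
#'
#' @param y,x Numeric vectors.
#' @param group Two-level factor (or coercible); both levels must be present.
#' @param covariates Optional data frame of additional covariates.
#' @return One-row tibble as [pearson_r_test()], for the interaction term.
#' @export
interaction_model <- function(y, x, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2L) {
    bft_stop("`group` must have exactly two levels present.",
             "bftrans_error_invalid_argument")
  }
  design <- data.frame(x = x, group = group)
  if (!is.null(covariates)) design <- cbind(design, as.data.frame(covariates))
  design$x_by_group <- x * (as.integer(group) - 1L)
  fit <- ols_fit(y, design)
  row <- fit$coefficients[fit$coefficients$term == "x_by_group", ]
  test_result(estimate = row$estimate, statistic = row$statistic,
              df = row$df, p = row$p, n_used = fit$n_used)
}

#' Levene / Brown-Forsythe test of equal variances
#'
#' One-way ANOVA on absolute deviations from the group centre; the centre is
#' the group median by default (Brown-Forsythe) with the mean as an option.
#'
#' @param values Numeric vector.
#' @param group Two-level (or multi-level) grouping factor; every group needs
#'   at least 2 observations.
#' @param center `"median"` (default) or `"mean"`.
#' @return One-row tibble: `statistic` (F), `df_num`, `df` (denominator),
#'   `p`, `center`.
#' @export
levene_test <- function(values, group, center = c("median", "mean")) {
  center <- match.arg(center)
  keep <- complete.cases(values, group)
  values <- values[keep]
  group <- factor(group[keep])
  sizes <- table(group)
  if (any(sizes < 2)) {
    bft_stop("Each group needs at least 2 observations.",
             "bftrans_error_invalid_argument")
  }
  ctr_fun <- if (center == "median") median else mean
  ctr <- tapply(values, group, ctr_fun)
  d <- abs(values - ctr[group])
  k <- nlevels(group)
  n <- length(d)
  gm <- mean(d)
  ss_between <- sum(sizes * (tapply(d, group, mean) - gm)^2)
  ss_within <- sum((d - tapply(d, group, mean)[group])^2)
  df1 <- k - 1
  df2 <- n - k
  f <- if (ss_within == 0) {
    if (ss_between == 0) 0 else Inf
  } else {
    (ss_between / df1) / (ss_within / df2)
  }
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  tibble(statistic = f, df_num = df1, df = df2, p = p, center = center)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values in input order, plus the Bonferroni threshold
#' for the family.
#'
#' @param p_raw Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise alpha used for the Bonferroni threshold
#'   (default 0.05).
#' @return List of class `bft_fdr`: `p_raw`, `q`, `p_bonf_threshold`
#'   (`alpha / n_tests`), `n_tests`.
#' @export
bh_fdr <- function(p_raw, alpha = 0.05) {
  check_numeric(p_raw, "p_raw", finite = FALSE)
  if (any(is.na(p_raw)) || any(p_raw < 0 | p_raw > 1)) {
    bft_stop("`p_raw` must lie in [0, 1] with no missing values.",
             "bftrans_error_invalid_argument")
  }
  structure(
    list(p_raw = p_raw,
         q = p.adjust(p_raw, method = "BH"),
         p_bonf_threshold = alpha / length(p_raw),
         n_tests = length(p_raw)),
    class = "bft_fdr"
  )
}

#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests in the family.
#' @param alpha Family-wise alpha (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) bft_stop("`n_tests` must be >= 1.", "bftrans_error_invalid_argument")
  alpha / n_tests
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (default) or Welch variant, for comparing groups when only
#' means and standard deviations are available (demographic tables).
#'
#' @param mean1,sd1,n1 Summary statistics for group 1.
#' @param mean2,sd2,n2 Summary statistics for group 2.
#' @param var_equal Pooled variance if `TRUE` (default), Welch otherwise.
#' @return One-row tibble: `estimate` (mean1 - mean2), `statistic`, `df`,
#'   `p`, `two_sided`, `variant`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) {
    bft_stop("Each group needs n >= 2.", "bftrans_error_invalid_argument")
  }
  diff <- mean1 - mean2
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  stat <- diff / se
  test_result(estimate = diff, statistic = stat, df = df,
              p = t_tail_p(stat, df),
              variant = if (var_equal) "pooled" else "welch")
}

# Covariate-adjusted association: t-test of the predictor-of-interest
# coefficient in outcome ~ predictor + covariates. This is how "accounting
# for covariates" is implemented for all adjusted correlations.
adjusted_assoc <- function(y, x, covariates) {
  design <- cbind(data.frame(x = x), as.data.frame(covariates))
  fit <- ols_fit(y, design)
  row <- fit$coefficients[fit$coefficients$term == "x", ]
  test_result(estimate = row$estimate, statistic = row$statistic,
              df = row$df, p = row$p, n_used = fit$n_used)
}
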