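#' ANCOVA group effect size (Cohen's f) with a noncentral-F interval
#'
#' Fits a least-squares model of the outcome on the group factor plus
#' covariates and summarizes the group effect as Cohen's f,
#' `f = sqrt(eta2 / (1 - eta2))`, where `eta2` is the partial eta squared
#' of the group term with type-II sums of squares (the group effect
#' adjusted for the covariates, with no interactions in the model). The
#' 95% interval comes from inverting the noncentral-F distribution on the
#' noncentrality parameter and mapping it back through
#' `eta2 = ncp / (ncp + df1 + df2 + 1)`.
#'
#' @param y Numeric outcome vector.
#' @param group Factor (or coercible) of group labels, at least 2 levels.
#' @param covariates Optional data frame or matrix of numeric covariates
#'   (e.g. age and sex coded 0/1).
#' @param conf_level Confidence level, default 0.95.
#' @return A list of class `effect_size` with `cohens_f`, `eta2_partial`,
#'   `ci_low`, `ci_high`, `f_statistic`, `df1`, `df2`, `n`, `covariates`.
#' @export
ancova_cohens_f <- function(y, group, covariates = NULL, conf_level = 0.95) {
  y <- as.numeric(y)
  group <- factor(group)
  if (nlevels(group) < 2L) stop("at least 2 groups are required")
  dat <- data.frame(.y = y, .group = group)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  n <- nrow(dat)
  rhs_cov <- if (length(cov_names)) paste(cov_names, collapse = " + ") else "1"
  full <- stats::lm(stats::reformulate(c(cov_names, ".group"), ".y"),
                    data = dat)
  if (any(is.na(stats::coef(full)))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "))
  }
  reduced <- stats::lm(stats::reformulate(rhs_cov, ".y"), data = dat)
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(reduced)^2)
  df1 <- nlevels(droplevels(dat$.group)) - 1L
  df2 <- full$df.residual
  if (n <= length(stats::coef(full))) stop("too few observations for the model")
  ss_group <- rss_red - rss_full
  f_stat <- (ss_group / df1) / (rss_full / df2)
  eta2 <- ss_group / (ss_group + rss_full)
  cohens_f <- sqrt(eta2 / (1 - eta2))
  ci <- ncp_interval(f_stat, df1, df2, conf_level)
  eta_from_ncp <- function(ncp) ncp / (ncp + df1 + df2 + 1)
  f_from_ncp <- function(ncp) {
    e <- eta_from_ncp(ncp)
    sqrt(e / (1 - e))
  }
  structure(
    list(cohens_f = cohens_f, eta2_partial = eta2,
         ci_low = f_from_ncp(ci[1]), ci_high = f_from_ncp(ci[2]),
         f_statistic = f_stat, df1 = df1, df2 = df2, n = n,
         covariates = cov_names, conf_level = conf_level),
    class = "effect_size"
  )
}

# confidence interval for the noncentrality parameter of an observed F
ncp_interval <- function(f_stat, df1, df2, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  p_at <- function(ncp) stats::pf(f_stat, df1, df2, ncp = ncp)
  upper_bracket <- function(target) {
    hi <- max(4 * df1 * f_stat, 10)
    while (p_at(hi) > target && hi < 1e8) hi <- hi * 2
    hi
  }
  lo <- if (p_at(0) < 1 - a) 0 else {
    stats::uniroot(function(l) p_at(l) - (1 - a), c(0, upper_bracket(1 - a)),
                   tol = 1e-8)$root
  }
  hi <- if (p_at(0) < a) 0 else {
    stats::uniroot(function(l) p_at(l) - a, c(0, upper_bracket(a)),
                   tol = 1e-8)$root
  }
  c(lo, hi)
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's f = %.3f, %g%% CI [%.3f, %.3f] (F(%d,%d) = %.2f, n = %d)\n",
              x$cohens_f, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$df1, x$df2, x$f_statistic, x$n))
  invisible(x)
}

#' Spearman rank correlation with asymptotic p-value
#'
#' Average ranks for ties; two-sided p-value from the asymptotic t
#' approximation.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A list with `estimate` (rho), `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("Spearman correlation is undefined for constant input")
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Steiger's test for two dependent overlapping correlations
#'
#' Compares `cor(j, k)` with `cor(j, h)` measured on the same n subjects
#' (variable j shared), e.g. a tau network measure's and a regional
#' measure's correlation with the same memory score. Uses Fisher-z
#' transforms with the covariance term evaluated at the back-transformed
#' mean of the two Fisher z values (Steiger's Z1*).
#'
#' @param r_jk Correlation of the shared variable with the first measure.
#' @param r_jh Correlation of the shared variable with the second measure.
#' @param r_kh Correlation between the two measures.
#' @param n Sample size (> 3).
#' @return A list with `z` and two-sided `p_value`.
#' @export
steiger_test <- function(r_jk, r_jh, r_kh, n) {
  rs <- c(r_jk, r_jh, r_kh)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)")
  }
  if (n <= 3) stop("n must exceed 3")
  fisher <- function(r) atanh(r)
  z_jk <- fisher(r_jk)
  z_jh <- fisher(r_jh)
  r_bar <- tanh((z_jk + z_jh) / 2)       # back-transformed mean correlation
  num <- r_kh * (1 - 2 * r_bar^2) - 0.5 * r_bar^2 *
    (1 - 2 * r_bar^2 - r_kh^2)
  cov_term <- num / (1 - r_bar^2)^2
  z <- sqrt(n - 3) * (z_jk - z_jh) / sqrt(2 - 2 * cov_term)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction, as used for group-by-category
#' demographics tables.
#'
#' @param table Matrix of nonnegative integer counts.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table must hold nonnegative integer counts")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("zero expected count; drop empty rows/columns")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' ROC AUC with DeLong interval and Youden operating point
#'
#' AUC via the Mann-Whitney identity (probability that a positive scores
#' above a negative, ties counted half), the 95% confidence interval by
#' DeLong's method, and the operating point maximizing Youden's J.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or two-level factor).
#' @return A list with `auc`, `ci_low`, `ci_high`, `sensitivity`,
#'   `specificity`, `threshold`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- if (is.factor(labels)) as.integer(labels) - 1L
            else as.integer(as.logical(as.numeric(labels)))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in `labels`")
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1L, , drop = FALSE]       # deterministic pick among J ties
  list(auc = as.numeric(pROC::auc(r)), ci_low = ci[1], ci_high = ci[3],
       sensitivity = best$sensitivity, specificity = best$specificity,
       threshold = best$threshold)
}
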