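#' Regression between depletion scores of two screens
#'
#' Ordinary least squares of screen B's per-region scores on screen A's,
#' with a t-test on the slope and Pearson r. With
#' `remove_outliers = TRUE` the studentized-residual outlier test is run
#' first and the model refit once without the flagged regions
#' (flag, remove, refit — not iterated).
#'
#' @param x,y Per-region depletion scores from the two screens (aligned).
#' @param remove_outliers Refit after removing mean-shift outliers.
#' @param alpha Bonferroni level for the outlier flag.
#' @return List: beta, intercept, p_slope, r, n, outliers_removed (ids
#'   of removed indices), fit (the `lm` object).
#' @export
fit_score_regression <- function(x, y, remove_outliers = FALSE, alpha = 0.1) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0) stop("zero variance in x")
  removed <- integer(0)
  if (remove_outliers) {
    tab <- detect_outlier_regions(x, y, alpha = alpha)
    removed <- which(tab$outlier)
    if (length(removed)) {
      x <- x[-removed]; y <- y[-removed]
    }
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(beta = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_slope = sm$coefficients[2, 4],
       r = stats::cor(x, y),
       n = length(x),
       outliers_removed = removed,
       fit = fit)
}

#' Mean-shift outlier test on cross-screen regression
#'
#' Flags regions whose essentiality differs between two screens:
#' externally studentized residuals from the regression of y on x are
#' referred to a t distribution with n - 3 degrees of freedom (two
#' sided), Bonferroni-adjusted by the number of regions, and flagged
#' when the adjusted p falls below `alpha`. Equivalent to testing a
#' per-point mean-shift dummy regressor.
#'
#' @param x,y Aligned per-region depletion scores (n >= 5).
#' @param region_id Optional region labels.
#' @param locus Optional locus labels carried into the output.
#' @param alpha Bonferroni threshold for the outlier flag (default 0.1).
#' @param essential_threshold Per-region p (or score) threshold used to
#'   set the `essential_a` / `essential_b` convenience flags; scores at
#'   or below the threshold are called essential.
#' @return A comparative table: region_id, score_a, score_b, residual,
#'   studentized_t, bonferroni_p, outlier, locus, essential_a,
#'   essential_b.
#' @export
detect_outlier_regions <- function(x, y, region_id = NULL, locus = NULL,
                                   alpha = 0.1, essential_threshold = 0.05) {
  n <- length(x)
  stopifnot(n == length(y), n >= 5)
  fit <- stats::lm(y ~ x)
  t <- stats::rstudent(fit)
  p_raw <- 2 * stats::pt(-abs(t), df = n - 3)
  bonf <- pmin(1, n * p_raw)
  data.frame(
    region_id = region_id %||% sprintf("r%03d", seq_len(n)),
    score_a = x, score_b = y,
    residual = stats::residuals(fit),
    studentized_t = t,
    bonferroni_p = bonf,
    outlier = bonf < alpha,
    locus = locus %||% NA_character_,
    essential_a = x <= essential_threshold,
    essential_b = y <= essential_threshold,
    stringsAsFactors = FALSE)
}

#' Combine dependent p-values by the empirical Brown's method
#'
#' Fisher's statistic `sum(-2 log p)` referred to a scaled chi-square
#' whose degrees of freedom and scale are calibrated from the empirical
#' covariance of the underlying data: each condition's scores are
#' transformed to `w = -2 log(empirical right-tail CDF)`, the covariance
#' of w across conditions gives the variance of the summed statistic,
#' and `f = 2 * (2k)^2 / var`, `c = var / (4k)` (capped at Fisher's
#' `f = 2k`, `c = 1` when the empirical variance undershoots
#' independence). With independent conditions the method reduces to
#' Fisher's; with perfectly correlated conditions a duplicated p is
#' returned unchanged.
#'
#' @param p Numeric vector of k p-values in (0, 1], one per condition.
#' @param data k x n matrix of the conditions' underlying scores
#'   (rows aligned with `p`).
#' @return List: p_combined, fisher_p, f (df), c (scale), statistic.
#' @export
combine_pvalues_browns <- function(p, data) {
  stopifnot(all(p > 0), all(p <= 1))
  k <- length(p)
  X <- sum(-2 * log(p))
  fisher_p <- stats::pchisq(X, df = 2 * k, lower.tail = FALSE)
  if (k == 1)
    return(list(p_combined = p, fisher_p = p, f = 2, c = 1, statistic = X))
  data <- as.matrix(data)
  stopifnot(nrow(data) == k)
  if (any(apply(data, 1, stats::sd) == 0))
    stop("degenerate (constant) data row")
  n <- ncol(data)
  W <- t(apply(data, 1, function(x) {
    rt <- vapply(x, function(v) sum(x >= v), numeric(1)) / n
    -2 * log(rt)
  }))
  S <- stats::cov(t(W))
  sigma2 <- sum(S)
  mu <- 2 * k
  f <- 2 * mu^2 / sigma2
  c <- sigma2 / (2 * mu)
  if (f > 2 * k) { f <- 2 * k; c <- 1 }
  list(p_combined = stats::pchisq(X / c, df = f, lower.tail = FALSE),
       fisher_p = fisher_p, f = f, c = c, statistic = X)
}

#' Chi-square test for locus enrichment of essential regions
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table
#' of regions inside/outside a locus crossed with essential/not under an
#' explicit threshold rule. When any expected cell falls below 1 the
#' result is flagged and Fisher's exact p is reported alongside.
#'
#' @param table Comparative table (needs `locus` plus an essentiality
#'   flag column) or any data frame with those columns.
#' @param locus Locus label to test.
#' @param essential Logical vector (or column name, default
#'   `"essential_a"`) marking essential regions.
#' @return List: statistic, p, table (2x2 counts), essential_rule,
#'   low_expected (flag), fisher_p (when flagged).
#' @export
locus_enrichment_test <- function(table, locus, essential = "essential_a") {
  ess <- if (is.character(essential) && length(essential) == 1)
    table[[essential]] else essential
  stopifnot(length(ess) == nrow(table))
  inloc <- table$locus == locus
  if (!any(inloc) || all(inloc))
    stop("need regions both inside and outside the locus")
  tab <- base::table(factor(inloc, c(TRUE, FALSE), c("in", "out")),
                     factor(ess, c(TRUE, FALSE), c("essential", "not")))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(E == tab)) {
    res <- list(statistic = 0, p = 1)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- list(statistic = unname(ct$statistic), p = ct$p.value)
  }
  res$table <- tab
  res$essential_rule <- if (is.character(essential)) essential else "explicit"
  res$low_expected <- any(E < 1)
  if (res$low_expected) {
    warning("expected cell below 1; Fisher's exact p reported alongside")
    res$fisher_p <- stats::fisher.test(tab)$p.value
  }
  res
}
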