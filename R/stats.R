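#' Normality screen
#'
#' Shapiro-Wilk test at alpha = 0.05, deciding whether a variable is
#' summarised as mean +/- SD (normal) or median (IQR) (non-normal) and which
#' omnibus test branch is used. For n > 5000 a deterministic evenly spaced
#' subsample of 5000 values is tested. A constant vector cannot be tested
#' and is classified `non_normal` with a warning.
#'
#' @param values Numeric vector, n >= 3.
#' @return List with `class` (`"normal"`/`"non_normal"`) and `p`.
#' @export
normality_screen <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop("normality screen needs n >= 3")
  if (stats::sd(values) == 0) {
    warning("constant vector: classified non_normal (Shapiro-Wilk undefined)")
    return(list(class = "non_normal", p = NA_real_))
  }
  if (n > 5000L) {
    values <- values[unique(round(seq(1, n, length.out = 5000)))]
  }
  p <- stats::shapiro.test(values)$p.value
  list(class = if (p > 0.05) "normal" else "non_normal", p = p)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. The exact null distribution is used when
#' `n1 * n2 <= 400` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' The reported `U` counts pairs in which `x` exceeds `y` (ties 0.5).
#'
#' @param x,y Numeric samples, each nonempty.
#' @return List with `U`, `p`, `n` and `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n = c(length(x), length(y)),
       method = if (exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis omnibus test with Dunn post hoc comparisons
#'
#' Omnibus H test across three groups followed by Dunn's z tests on the
#' pooled average ranks (tie-corrected), with Bonferroni-adjusted pairwise
#' p-values capped at 1 (the SPSS convention, which is why identical group
#' pairs print an adjusted p of exactly 1).
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) with exactly 3 levels.
#' @return List with `H`, `df`, `p` and a data frame `pairwise`
#'   (`group1`, `group2`, `z`, `p_raw`, `p_adj`).
#' @export
kruskal_wallis_posthoc <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 3L) {
    stop("needs exactly 3 groups; use mann_whitney() for 2")
  }
  if (any(table(groups) < 1L)) stop("every group must be nonempty")
  kw <- stats::kruskal.test(values, groups)

  r <- rank(values)
  N <- length(values)
  tie <- table(values)
  sigma2 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
  lev <- levels(groups)
  cmb <- utils::combn(lev, 2L)
  pw <- lapply(seq_len(ncol(cmb)), function(j) {
    g1 <- cmb[1L, j]; g2 <- cmb[2L, j]
    n1 <- sum(groups == g1); n2 <- sum(groups == g2)
    z <- (mean(r[groups == g1]) - mean(r[groups == g2])) /
      sqrt(sigma2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = g1, group2 = g2, z = z, p_raw = p,
               p_adj = min(1, ncol(cmb) * p))
  })
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = do.call(rbind, pw))
}

#' Spearman correlation with Bonferroni adjustment
#'
#' Spearman's rho on average ranks with the asymptotic two-sided p-value,
#' Bonferroni-adjusted for a family of `m` tests (capped at 1). When `x` is
#' a data frame, every column is correlated against `y` and the family size
#' defaults to the number of columns.
#'
#' @param x Numeric vector or data frame of numeric columns.
#' @param y Numeric vector, paired with (each column of) `x`.
#' @param m Bonferroni family size (recorded in the output so alternative
#'   family definitions remain auditable).
#' @return Data frame with `variable`, `rho`, `p_raw`, `p_adj`, `m`, `n`.
#' @export
spearman_bonferroni <- function(x, y, m = NULL) {
  if (is.data.frame(x)) {
    if (is.null(m)) m <- ncol(x)
    out <- lapply(names(x), function(v) spearman_bonferroni(x[[v]], y, m))
    out <- do.call(rbind, out)
    out$variable <- names(x)
    return(out)
  }
  if (is.null(m)) m <- 1L
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("Spearman correlation needs n >= 3")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  data.frame(variable = NA_character_, rho = unname(ct$estimate),
             p_raw = ct$p.value, p_adj = min(1, m * ct$p.value),
             m = m, n = length(x))
}

#' Two-way random-effects intraclass correlation for two readers
#'
#' ICC(2,1): two-way random effects, absolute agreement, single measures --
#' the standard index for interobserver reproducibility of a measurement.
#' The 95% confidence interval follows the McGraw-Wong F-based construction.
#'
#' @param x Numeric matrix or data frame, subjects x 2 readers, no missing
#'   cells, >= 5 subjects.
#' @param conf Confidence level.
#' @return List with `icc`, `ci` (length 2) and the mean squares.
#' @export
icc_two_reader <- function(x, conf = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("expected a subjects x 2 readers matrix")
  if (nrow(x) < 5L) stop("ICC needs >= 5 subjects")
  if (any(!is.finite(x))) stop("missing or non-finite cells are not allowed")
  n <- nrow(x); k <- ncol(x)
  rm_ <- rowMeans(x); cm <- colMeans(x); gm <- mean(x)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) -
                matrix(cm, n, k, byrow = TRUE) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  if (mse == 0 && msc == 0) {
    ci <- c(icc, icc)  # perfect agreement, interval degenerates
  } else {
    alpha <- 1 - conf
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci = ci, msr = msr, msc = msc, mse = mse)
}

#' ROC analysis with Youden-optimal threshold
#'
#' Empirical ROC via \pkg{pROC} with a DeLong confidence interval for the
#' AUC and a DeLong z-test of AUC = 0.5 (Bonferroni-adjustable). The
#' operating threshold maximises the Youden index (first optimum on ties).
#' `direction = "lower"` encodes markers that are lower in disease (the rule
#' "marker <= threshold predicts disease"); `"auto"` lets the data choose.
#'
#' @param marker Numeric marker values.
#' @param is_case Logical (or 0/1): `TRUE` for diseased subjects. Both
#'   classes must be present.
#' @param direction `"auto"`, `"lower"` (cases lower) or `"higher"`.
#' @param conf Confidence level for the AUC interval.
#' @param adjust_m Bonferroni family size for the AUC p-value.
#' @return List of class `roc_result`: `auc`, `ci`, `youden`, `threshold`,
#'   `rule` (`"<="` or `">"`), `sensitivity`, `specificity`, `p_raw`,
#'   `p_adj`, `n`, and `curve` (threshold/sensitivity/specificity points).
#' @export
roc_analysis <- function(marker, is_case,
                         direction = c("auto", "lower", "higher"),
                         conf = 0.95, adjust_m = 1L) {
  direction <- match.arg(direction)
  is_case <- as.logical(is_case)
  if (length(marker) != length(is_case)) stop("lengths differ")
  if (!any(is_case) || !any(!is_case)) stop("both classes must be present")
  dir <- switch(direction, auto = "auto", lower = ">", higher = "<")
  r <- pROC::roc(response = factor(is_case, levels = c(FALSE, TRUE)),
                 predictor = marker, direction = dir, quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  # pROC warns that the DeLong variance/CI degenerate when AUC = 1; that
  # case is handled explicitly below
  ci <- suppressWarnings(as.numeric(
    pROC::ci.auc(r, conf.level = conf, method = "delong")))[c(1, 3)]
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  if (v > 0) {
    z <- (auc - 0.5) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    p <- if (abs(auc - 0.5) < .Machine$double.eps^0.5) 1 else 0
  }
  cc <- pROC::coords(r, x = "all", transpose = FALSE,
                     ret = c("threshold", "sensitivity", "specificity"))
  youden_all <- cc$sensitivity + cc$specificity - 1
  best <- which.max(youden_all)  # first optimum on ties
  sens <- cc$sensitivity[best]; spec <- cc$specificity[best]
  structure(list(
    auc = auc, ci = ci, youden = sens + spec - 1,
    threshold = cc$threshold[best],
    rule = if (r$direction == ">") "<=" else ">",
    sensitivity = sens, specificity = spec,
    p_raw = p, p_adj = min(1, adjust_m * p),
    n = c(controls = sum(!is_case), cases = sum(is_case)),
    curve = cc
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (%.3f-%.3f), Youden %.3f at %s %.4g (se %.1f%%, sp %.1f%%), p' = %.3g\n",
    x$auc, x$ci[1], x$ci[2], x$youden, x$rule, x$threshold,
    100 * x$sensitivity, 100 * x$specificity, x$p_adj))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Classical (uncorrected) chi-square statistic with
#' df = (rows - 1)(cols - 1).
#'
#' @param tab Matrix of nonnegative integer counts with positive marginals.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_counts <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("`tab` must contain nonnegative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
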