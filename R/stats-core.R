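# Statistical machinery used throughout the analysis: Pearson correlation
# with Fisher z confidence intervals, independent two-sample tests,
# chi-square independence, the pooled two-proportion z statistic, and
# Benjamini-Hochberg adjustment. Model fits are delegated to base stats;
# the conventions (CI rounding, absolute z, F = t^2 reporting) are local.

#' Fisher z confidence interval for a Pearson correlation
#'
#' `z = atanh(r)`, half-width `q / sqrt(n - 3)` with `q = qnorm(0.975) =
#' 1.959964` at the default level, back-transformed through `tanh` and
#' reported to 3 decimals.
#'
#' @param r correlation, `|r| < 1`.
#' @param n sample size, `>= 4`.
#' @param level confidence level, default 0.95.
#' @return numeric vector `c(ci_low, ci_high)`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (!is.finite(r) || abs(r) >= 1)
    stop("fisher_ci requires |r| < 1 (transform undefined at |r| = 1)")
  if (n < 4) stop("fisher_ci requires n >= 4")
  z <- atanh(r)
  hw <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  round(tanh(c(z - hw, z + hw)), 3)
}

#' Pearson correlation with Fisher confidence interval
#'
#' Standard Pearson r with the two-sided p-value from the t transform on
#' `n - 2` degrees of freedom (via [stats::cor.test()]); the confidence
#' interval comes from [fisher_ci()].
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both non-constant.
#' @param level confidence level for the interval.
#' @return object of class `mpd_cor`: list with `r`, `n`, `ci_low`,
#'   `ci_high`, `p`, `p_adj` (NA until a family is adjusted).
#' @export
pearson_r <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) stop("pearson_r: unequal lengths")
  n <- length(x)
  if (n < 3L) stop("pearson_r requires n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("pearson_r: non-finite values")
  if (var(x) == 0 || var(y) == 0) stop("pearson_r: constant input")
  ct <- cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  ci <- if (abs(r) < 1 && n >= 4) fisher_ci(r, n, level) else c(NA_real_, NA_real_)
  structure(list(r = r, n = n, ci_low = ci[1L], ci_high = ci[2L],
                 p = ct$p.value, p_adj = NA_real_),
            class = "mpd_cor")
}

#' Independent two-sample t test
#'
#' Welch's t by default; pooled-variance t with `equal_var = TRUE`.
#' Because two-group tables in this field are often printed with an "F"
#' column, `f = t^2` on `(1, df)` is also reported. If both groups have
#' zero variance and equal means the degenerate result `t = 0, p = 1` is
#' returned.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param equal_var pool the variances?
#' @return object of class `mpd_test`: list with `statistic`,
#'   `statistic_name = "t"`, `df`, `p`, plus `f` and `f_df`.
#' @export
independent_t <- function(a, b, equal_var = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("independent_t requires n >= 2 in each group")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("independent_t: non-finite values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      df <- length(a) + length(b) - 2
      return(structure(list(statistic = 0, statistic_name = "t", df = df,
                            p = 1, f = 0, f_df = c(1, df)),
                       class = "mpd_test"))
    }
    stop("independent_t: zero variance in both groups with unequal means")
  }
  tt <- t.test(a, b, var.equal = equal_var)
  t <- unname(tt$statistic)
  df <- unname(tt$parameter)
  structure(list(statistic = t, statistic_name = "t", df = df,
                 p = tt$p.value, f = t^2, f_df = c(1, df)),
            class = "mpd_test")
}

#' Chi-square test of independence
#'
#' Pearson X^2 without continuity correction on a 2 x k table of counts.
#'
#' @param tab integer matrix of non-negative counts with all row and
#'   column margins positive.
#' @return object of class `mpd_test` with `statistic_name = "chi2"`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("chi_square_independence: counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi_square_independence: zero row or column margin")
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(res$statistic), statistic_name = "chi2",
                 df = unname(res$parameter), p = res$p.value),
            class = "mpd_test")
}

#' Two-proportion z test (pooled standard error)
#'
#' `z = |p1 - p2| / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with the pooled
#' proportion `phat = (k1 + k2) / (n1 + n2)` and no continuity
#' correction; the two-sided p comes from the normal distribution. The
#' reported z is the absolute value, with the direction available from
#' `p1` and `p2`.
#'
#' @param k1,n1,k2,n2 successes and totals, `0 <= k <= n`, `n >= 1`.
#' @return object of class `mpd_overlap_z`: list with `k1,n1,k2,n2`,
#'   `p1,p2`, `z`, `p`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  for (v in list(k1, n1, k2, n2))
    if (!is.finite(v) || v < 0 || v != round(v))
      stop("two_proportion_z: counts must be non-negative integers")
  if (n1 < 1 || n2 < 1 || k1 > n1 || k2 > n2)
    stop("two_proportion_z: need 0 <= k <= n and n >= 1")
  p1 <- k1 / n1; p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1)
    stop("two_proportion_z: pooled proportion is 0 or 1 (SE undefined)")
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- abs(p1 - p2) / se
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                 p1 = p1, p2 = p2, z = z, p = 2 * pnorm(-z)),
            class = "mpd_overlap_z")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone in rank, capped at 1, returned in
#' the original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
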