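## Small inferential utilities shared by the swap and session analyses.

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value. Degenerate inputs (fewer than two values per
#' sample, or both variances zero) are flagged with `NA` statistics rather
#' than an error.
#'
#' @param a,b Numeric samples.
#' @return List of class `test_result`: `statistic`, `df`, `p`, `method`,
#'   and `defined` (FALSE for degenerate input).
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2 || (var(a) == 0 && var(b) == 0)) {
    return(structure(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                          method = "welch", defined = FALSE),
                     class = "test_result"))
  }
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  structure(list(statistic = t, df = df, p = 2 * pt(-abs(t), df),
                 method = "welch", defined = TRUE),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s test> statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}

#' Multiple-comparison adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up FDR adjustment.
#'
#' @param p Numeric vector of raw p values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @return Adjusted p values, same length and order as `p`.
#' @export
adjust_p <- function(p, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = if (method == "bonferroni") "bonferroni" else "BH")
}

#' Two-proportion Z test
#'
#' Pooled-proportion Z statistic for comparing `k1/n1` with `k2/n2`, with a
#' two-sided p value.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @return List of class `test_result`: `statistic` (Z), `p`, `defined`.
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  if (n1 == 0 || n2 == 0) {
    return(structure(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                          method = "two_prop_z", defined = FALSE),
                     class = "test_result"))
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  structure(list(statistic = z, df = NA_real_, p = 2 * pnorm(-abs(z)),
                 method = "two_prop_z", defined = TRUE),
            class = "test_result")
}

#' Simple linear regression with Cohen's f-squared
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, intercept,
#' R-squared, the F-test p value and the effect size
#' `f^2 = R^2 / (1 - R^2)`.
#'
#' @param x,y Numeric vectors (`x` must not be constant; n >= 3).
#' @return List of class `regression_result`: `beta`, `intercept`,
#'   `r_squared`, `p`, `f_squared`, `n`.
#' @export
simple_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (var(x) == 0) stop("x is constant; regression undefined", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # R^2 = 1 is legitimate here
  r2 <- sm$r.squared
  p <- if (r2 >= 1) 0 else {
    f <- sm$fstatistic
    pf(f[[1]], f[[2]], f[[3]], lower.tail = FALSE)
  }
  structure(list(beta = coef(fit)[["x"]], intercept = coef(fit)[["(Intercept)"]],
                 r_squared = r2, p = p,
                 f_squared = if (r2 >= 1) Inf else r2 / (1 - r2),
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<ols> beta = %.4g, intercept = %.4g, R^2 = %.4g, p = %.4g, f^2 = %.4g (n = %d)\n",
              x$beta, x$intercept, x$r_squared, x$p, x$f_squared, x$n))
  invisible(x)
}

## binomial proportion CI: normal approximation, Wilson fallback for small
## counts (k < 5 or n - k < 5)
proportion_ci <- function(k, n, conf_level = 0.95) {
  k <- as.numeric(k)
  n <- rep_len(as.numeric(n), length(k))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- ifelse(n > 0, k / n, NA_real_)
  se <- sqrt(p * (1 - p) / n)
  lower <- p - z * se
  upper <- p + z * se
  small <- !is.na(p) & (k < 5 | (n - k) < 5)
  if (any(small)) {
    den <- 1 + z^2 / n[small]
    ctr <- (p[small] + z^2 / (2 * n[small])) / den
    hw <- z * sqrt(p[small] * (1 - p[small]) / n[small] +
                     z^2 / (4 * n[small]^2)) / den
    lower[small] <- ctr - hw
    upper[small] <- ctr + hw
  }
  list(lower = pmax(lower, 0), upper = pmin(upper, 1))
}

## t-based mean CI helper
mean_ci <- function(x, conf_level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) return(list(mean = NA_real_, lower = NA_real_, upper = NA_real_, n = 0L))
  m <- mean(x)
  if (n == 1) return(list(mean = m, lower = NA_real_, upper = NA_real_, n = 1L))
  half <- qt(1 - (1 - conf_level) / 2, n - 1) * sd(x) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half, n = n)
}
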