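# Regression and rank-test machinery for phantom cohorts and erosion traces.

#' Least-squares trend fit
#'
#' Ordinary least squares for the three model forms used to relate SMI-family
#' measurements: `linear` (`y = b0 + b1 x`), `quadratic`
#' (`y = b0 + b1 x + b2 x^2`) and `quadratic_zero_intercept`
#' (`y = b1 x + b2 x^2`, forced through the origin -- when the concave
#' fraction is 0 the negative SMI component must be 0 too). The p-value is
#' the F-test of the fitted model against the null (intercept-only, or the
#' zero model for the forced-origin form). For models with an intercept,
#' `r_squared = 1 - SS_res / SS_tot` about the mean; the forced-origin model
#' uses the uncentered total sum of squares, keeping it in `[0, 1]`.
#'
#' @param x,y numeric vectors of equal length.
#' @param model one of `"linear"`, `"quadratic"`,
#'   `"quadratic_zero_intercept"`.
#' @return an object of class `regression_result`: `model`, `coefficients`,
#'   `r_squared`, `p_value`, `n`, and the underlying `lm` fit.
#' @export
fit_regression <- function(x, y,
                           model = c("linear", "quadratic",
                                     "quadratic_zero_intercept")) {
  model <- match.arg(model)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  p_coef <- switch(model, linear = 2L, quadratic = 3L,
                   quadratic_zero_intercept = 2L)
  if (length(x) < p_coef + 1L)
    stop("need at least ", p_coef + 1L, " observations for model '", model, "'")
  if (sd(x) == 0) stop("degenerate design: x is constant")
  df <- data.frame(x = x, y = y)
  fit <- switch(model,
                linear = lm(y ~ x, data = df),
                quadratic = lm(y ~ x + I(x^2), data = df),
                quadratic_zero_intercept = lm(y ~ 0 + x + I(x^2), data = df))
  ss_res <- sum(resid(fit)^2)
  ss_tot <- if (model == "quadratic_zero_intercept") sum(y^2)
            else sum((y - mean(y))^2)
  # exact relationships ("essentially perfect fit") are routine on phantoms
  fstat <- suppressWarnings(summary(fit))$fstatistic
  p_value <- if (is.null(fstat)) NA_real_
             else unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(model = model, coefficients = coef(fit),
                 r_squared = 1 - ss_res / ss_tot, p_value = p_value,
                 n = length(x), fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s, n = %d, R^2 = %.4f, p = %.3g\n",
              x$model, x$n, x$r_squared, x$p_value))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided by default. The p-value is exact (by enumeration over rank
#' assignments) when the combined sample size is at most 20 and there are no
#' ties; otherwise the normal approximation with tie correction is used.
#'
#' @param sample_a,sample_b non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return a list with `rank_sum` (sum of ranks of `sample_a`), `u`
#'   (Mann-Whitney U of `sample_a`), `p_value`, `exact` (logical), and
#'   `alternative`.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(sample_a) || !length(sample_b)) stop("samples must be non-empty")
  na <- length(sample_a); nb <- length(sample_b)
  rk <- rank(c(sample_a, sample_b))
  rank_sum <- sum(rk[seq_len(na)])
  u <- rank_sum - na * (na + 1) / 2
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- (na + nb <= 20) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = alternative,
                       exact = exact, correct = !exact)$p.value)
  if (is.nan(p)) p <- 1  # fully tied samples: no evidence of a shift
  list(rank_sum = rank_sum, u = u, p_value = p, exact = exact,
       alternative = alternative)
}
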