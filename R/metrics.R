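# Prediction metrics and the Hotelling-Williams test for dependent
# correlations.

#' Prediction accuracy
#'
#' Pearson correlation between corrected phenotypes and predicted values.
#' If either vector has zero variance the correlation is undefined and a
#' flagged 0 is returned (attribute `undefined`), with a warning.
#'
#' @param yc,pv Numeric vectors of equal length.
#' @return Scalar correlation in \[-1, 1\].
#' @export
accuracy <- function(yc, pv) {
  stopifnot(length(yc) == length(pv))
  if (sd(yc) < 1e-300 || sd(pv) < 1e-300) {
    warn("zero variance in accuracy(); returning flagged 0")
    return(structure(0, undefined = TRUE))
  }
  cor(yc, pv)
}

#' Prediction unbiasedness (dispersion)
#'
#' Ordinary least-squares slope of the regression of corrected phenotypes on
#' predicted values; 1 indicates neither inflation nor deflation.
#'
#' @param yc,pv Numeric vectors of equal length.
#' @return Scalar regression slope.
#' @export
unbiasedness <- function(yc, pv) {
  stopifnot(length(yc) == length(pv))
  v <- var(pv)
  if (v < 1e-300) {
    warn("zero variance in predictions; slope undefined, returning flagged 0")
    return(structure(0, undefined = TRUE))
  }
  cov(yc, pv) / v
}

#' Mean squared and mean absolute error
#'
#' `MSE = mean((f - y)^2)`, `MAE = mean(|f - y|)` over the validation
#' animals.
#'
#' @param yc Observed corrected phenotypes.
#' @param pv Predicted values.
#' @return Named numeric vector `c(mse = , mae = )`.
#' @export
mse_mae <- function(yc, pv) {
  stopifnot(length(yc) == length(pv))
  d <- pv - yc
  c(mse = mean(d^2), mae = mean(abs(d)))
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests equality of `r12 = cor(y, PV1)` and `r13 = cor(y, PV2)` which share
#' the variable `y`, given their intercorrelation `r23 = cor(PV1, PV2)`,
#' using Williams' t statistic
#' `t = (r12 - r13) * sqrt((n - 1)(1 + r23) /
#'     (2 (n - 1)/(n - 3) |R| + rbar^2 (1 - r23)^3))`
#' with `rbar = (r12 + r13)/2` and `|R|` the determinant of the 3x3
#' correlation matrix, on `n - 3` degrees of freedom (two-sided).
#'
#' @param r12,r13 Correlations of the shared variable with each predictor.
#' @param r23 Correlation between the two predictors.
#' @param n Sample size (> 3).
#' @return Tibble with `t`, `df`, `p_value`.
#' @export
hotelling_williams <- function(r12, r13, r23, n) {
  if (n <= 3) abort("Hotelling-Williams test needs n > 3")
  for (r in c(r12, r13, r23)) {
    if (!is.finite(r) || abs(r) >= 1) abort("correlations must lie in (-1, 1)")
  }
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0) abort("incoherent correlation triple (|R| <= 0)")
  rbar <- (r12 + r13) / 2
  tstat <- (r12 - r13) * sqrt(
    (n - 1) * (1 + r23) /
      (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3)
  )
  df <- n - 3
  tibble::tibble(t = tstat, df = df, p_value = 2 * pt(-abs(tstat), df))
}
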