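#' Adjusted R-squared against the training-mean baseline
#'
#' 1 - sum((y - yhat)^2) / sum((y - mu_train)^2): the improvement of the
#' predictions over the constant training-set-mean predictor. Equals 1 for
#' perfect predictions, 0 for the training-mean baseline itself, and can be
#' negative for predictors worse than that baseline. With
#' `mu_train = mean(y_test)` it reduces to the classical R-squared.
#'
#' @param y_test observed test labels.
#' @param y_hat predictions.
#' @param mu_train training-fold label mean.
#' @return scalar adjusted R-squared.
#' @export
adjusted_r2 <- function(y_test, y_hat, mu_train) {
  stopifnot(length(y_test) == length(y_hat), length(y_test) >= 1L)
  denom <- sum((y_test - mu_train)^2)
  if (denom == 0) stop("all test labels equal mu_train; adjusted R2 undefined")
  1 - sum((y_test - y_hat)^2) / denom
}

#' Mean squared error
#' @param y observed labels.
#' @param y_hat predictions.
#' @return scalar MSE.
#' @export
mse <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  if (length(y) == 0L) stop("empty input")
  mean((y - y_hat)^2)
}

#' Spearman rank correlation (average ranks)
#'
#' Pearson correlation of the average-ranked values; ties receive average
#' ranks.
#'
#' @param y,y_hat equal-length numeric vectors, n >= 2.
#' @return scalar in [-1, 1].
#' @export
spearman_rho <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L)
  ry <- rank(y, ties.method = "average")
  rh <- rank(y_hat, ties.method = "average")
  if (stats::sd(ry) == 0 || stats::sd(rh) == 0) {
    stop("Spearman correlation undefined for a constant input vector")
  }
  stats::cov(ry, rh) / (stats::sd(ry) * stats::sd(rh))
}

#' Reduced chi-squared calibration statistic
#'
#' chi2 = 1/(N-1) * sum(((y - yhat) / sigma_hat)^2): residuals normalized by
#' the predictive standard deviations. Approximately 1 for a calibrated
#' Gaussian predictor; > 1 indicates over-confidence (errors larger than
#' claimed), < 1 under-confidence.
#'
#' @param y observed labels.
#' @param y_hat predicted means.
#' @param sigma_hat predictive standard deviations (> 0).
#' @return scalar reduced chi-squared.
#' @export
reduced_chi2 <- function(y, y_hat, sigma_hat) {
  stopifnot(length(y) == length(y_hat), length(y) == length(sigma_hat),
            length(y) >= 2L)
  if (any(sigma_hat <= 0)) stop("sigma_hat must be strictly positive")
  sum(((y - y_hat) / sigma_hat)^2) / (length(y) - 1)
}

#' Calibration curve from probability-integral-transformed residuals
#'
#' For quantile levels p_j = j/q, the empirical coverage at level j is the
#' fraction of observations whose Gaussian CDF value
#' Phi((y_i - yhat_i) / sigma_hat_i) is <= p_j. Perfectly calibrated Gaussian
#' predictions give coverage approximately equal to the levels.
#'
#' @param y observed labels.
#' @param y_hat predicted means.
#' @param sigma_hat predictive standard deviations (> 0).
#' @param q number of quantile levels (default 10); requires n >= q.
#' @return list with `levels` (j/q) and `empirical_coverage`.
#' @export
calibration_curve <- function(y, y_hat, sigma_hat, q = 10L) {
  stopifnot(length(y) == length(y_hat), length(y) == length(sigma_hat))
  if (length(y) < q) stop("need at least q observations")
  if (any(sigma_hat <= 0)) stop("sigma_hat must be strictly positive")
  pit <- stats::pnorm((y - y_hat) / sigma_hat)
  levels <- seq_len(q) / q
  coverage <- vapply(levels, function(p) mean(pit <= p), 0)
  list(levels = levels, empirical_coverage = coverage)
}

#' Expected calibration error
#'
#' Mean absolute deviation of the empirical coverage from the nominal
#' quantile levels: 1/q * sum |coverage_j - level_j|.
#'
#' @param levels nominal levels (j/q).
#' @param empirical_coverage matching empirical coverages.
#' @return scalar in [0, 1].
#' @export
ece <- function(levels, empirical_coverage) {
  stopifnot(length(levels) == length(empirical_coverage))
  mean(abs(empirical_coverage - levels))
}

#' Sharpness of the predictive variances
#'
#' Coefficient of variation of the predictive variances: their sample
#' standard deviation divided by their mean. Scale-invariant; 0 for a
#' homoscedastic predictor.
#'
#' @param sigma_hat_sq predictive variances, n >= 2, positive mean.
#' @return scalar >= 0.
#' @export
sharpness <- function(sigma_hat_sq) {
  stopifnot(length(sigma_hat_sq) >= 2L)
  m <- mean(sigma_hat_sq)
  if (m <= 0) stop("mean predictive variance must be > 0")
  stats::sd(sigma_hat_sq) / m
}

#' Confidence curve: loss over uncertainty-filtered subsets
#'
#' Thresholds h_j are the j/q quantiles of the predictive standard
#' deviations; entry j is the squared-error loss over the retained set
#' {i : sigma_hat_i <= h_j}. By default each entry is the mean loss over the
#' retained points; `literal = TRUE` instead divides every entry by the total
#' N. For a regressor whose uncertainties track its errors the curve is
#' (nearly) non-decreasing; the final entry (full retention) equals the
#' overall MSE in the default normalization.
#'
#' @param y observed labels.
#' @param y_hat predicted means.
#' @param sigma_hat predictive standard deviations.
#' @param q number of thresholds.
#' @param literal divide by total N instead of the retained-set size.
#' @return list with `thresholds` and `loss` (NA where the retained set is
#'   empty).
#' @export
confidence_curve <- function(y, y_hat, sigma_hat, q = 10L, literal = FALSE) {
  stopifnot(length(y) == length(y_hat), length(y) == length(sigma_hat))
  if (length(y) < q) stop("need at least q observations")
  n <- length(y)
  h <- stats::quantile(sigma_hat, probs = seq_len(q) / q, names = FALSE,
                       type = 7)
  loss <- vapply(h, function(hj) {
    keep <- sigma_hat <= hj
    if (!any(keep)) return(NA_real_)
    sum((y[keep] - y_hat[keep])^2) / (if (literal) n else sum(keep))
  }, 0)
  list(thresholds = h, loss = loss)
}

#' Full calibration report for one set of predictions
#'
#' @param y observed labels.
#' @param pred a predictive distribution (list with `mean`, `variance`).
#' @param q number of quantile levels.
#' @return list with the calibration curve, `ece`, `sharpness`, `chi2` and
#'   the confidence curve.
#' @export
calibration_report <- function(y, pred, q = 10L) {
  s <- sqrt(pred$variance)
  cc <- calibration_curve(y, pred$mean, s, q = q)
  list(levels = cc$levels, empirical_coverage = cc$empirical_coverage,
       ece = ece(cc$levels, cc$empirical_coverage),
       sharpness = sharpness(pred$variance),
       chi2 = reduced_chi2(y, pred$mean, s),
       confidence_curve = confidence_curve(y, pred$mean, s, q = q))
}
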