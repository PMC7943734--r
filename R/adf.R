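#' @include AllClasses.R
NULL

# MacKinnon response-surface critical values for the Dickey-Fuller t
# statistic, regression with constant and no trend. Rows: 1%, 5%, 10%.
.adfCrit <- rbind(
  "0.01" = c(-3.43035, -6.5393, -16.786, -79.433),
  "0.05" = c(-2.86154, -2.8903, -4.234, -40.040),
  "0.1"  = c(-2.56677, -1.5384, -2.809, 0))

adfCriticalValue <- function(alpha, nobs) {
  key <- as.character(alpha)
  if (!key %in% rownames(.adfCrit))
    stop("'alpha' must be one of 0.01, 0.05, 0.1")
  b <- .adfCrit[key, ]
  b[1] + b[2] / nobs + b[3] / nobs^2 + b[4] / nobs^3
}

#' Augmented Dickey-Fuller stationarity test
#'
#' Unit-root test of one timeseries with the regression
#' \eqn{\Delta y_t = a + \gamma y_{t-1} + \sum_{i=1}^{k} b_i \Delta y_{t-i}
#' + e_t} (constant, no trend). The t statistic of \eqn{\gamma} is compared
#' with the MacKinnon finite-sample critical value at level `alpha`; a
#' statistic below the critical value rejects the unit root and classifies
#' the series as stationary. The default lag order is the common
#' \eqn{\lfloor (T-1)^{1/3} \rfloor} rule.
#'
#' @param series numeric vector, length at least 25.
#' @param alpha significance level, one of 0.01 (default), 0.05, 0.1.
#' @param lags number of lagged differences k; defaults to
#'   `floor((T-1)^(1/3))`.
#' @return A list with `decision` (`"stationary"` or `"non-stationary"`),
#'   `statistic`, `criticalValue`, `lags` and `alpha`.
#' @examples
#' set.seed(1)
#' adfTest(rnorm(200))$decision          # stationary
#' adfTest(cumsum(rnorm(200)))$decision  # non-stationary
#' @export
adfTest <- function(series, alpha = 0.01, lags = NULL) {
  T <- length(series)
  if (T < 25) stop("'series' must contain at least 25 observations")
  if (stats::var(series) < .Machine$double.eps)
    stop("'series' is (near-)constant; the test is undefined")
  if (is.null(lags)) lags <- floor((T - 1)^(1 / 3))
  lags <- as.integer(lags)
  dy <- diff(series)
  n <- length(dy) - lags
  if (n < lags + 3) stop("series too short for the requested lag order")
  yLag <- series[(lags + 1):(T - 1)]
  resp <- dy[(lags + 1):length(dy)]
  X <- cbind(1, yLag)
  if (lags > 0)
    for (i in seq_len(lags))
      X <- cbind(X, dy[(lags + 1 - i):(length(dy) - i)])
  fit <- stats::lm.fit(X, resp)
  rss <- sum(fit$residuals^2)
  dfres <- n - ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / dfres * XtXinv[2, 2])
  stat <- fit$coefficients[2] / se
  crit <- adfCriticalValue(alpha, n)
  list(decision = if (stat < crit) "stationary" else "non-stationary",
       statistic = unname(stat), criticalValue = unname(crit),
       lags = lags, alpha = alpha, nobs = n)
}
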