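#' Cosinor (harmonic regression) fit of a circadian time series
#'
#' Least-squares fit of `y = mesor + a*cos(2*pi*t/period) +
#' b*sin(2*pi*t/period)`, with replicates treated as independent
#' observations at their circadian time. The half peak-to-trough amplitude
#' is `sqrt(a^2 + b^2)`, the acrophase is the time of the fitted maximum
#' mapped to \[0, period), and the p-value comes from the F-test of the
#' two-parameter harmonic against the intercept-only model with
#' `df = (2, n - 3)`.
#'
#' @param series numeric vector of log2 abundances.
#' @param times circadian times (hours), same length as `series`.
#' @param period oscillation period in hours (default 24; the package tests
#'   circadian rhythmicity only).
#' @return an object of class `cosinor_fit` with components `mesor`,
#'   `amplitude`, `acrophase`, `p_value`, `coefficients` (`mesor`, `a`,
#'   `b`), `fitted.values`, `residuals`, `times`, `series`, `period`,
#'   `f_statistic`, `df`.
#' @examples
#' t <- rep(seq(0, 21, 3), each = 3)
#' y <- 5 + 1 * cos(2 * pi * (t - 7) / 24)
#' fit <- cosinor_fit(y, t)
#' coef(fit)
#' @export
cosinor_fit <- function(series, times, period = 24) {
  if (length(series) != length(times)) {
    stop("series and times must have equal length")
  }
  ok <- is.finite(series) & is.finite(times)
  series <- series[ok]; times <- times[ok]
  n <- length(series)
  if (n < 4L) stop("need at least 4 observations, got ", n)
  if (length(unique(times)) < 2L) stop("all times are identical")
  w <- 2 * pi * times / period
  X <- cbind(mesor = 1, a = cos(w), b = sin(w))
  fit <- stats::lm.fit(X, series)
  cf <- fit$coefficients
  amp <- sqrt(cf["a"]^2 + cf["b"]^2)
  acro <- wrap_ct(atan2(cf["b"], cf["a"]) * period / (2 * pi), period)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((series - mean(series))^2)
  if (rss0 <= .Machine$double.eps * n * max(1, mean(series)^2)) {
    fstat <- 0; p <- 1
  } else {
    fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
    p <- if (!is.finite(fstat)) {
      .Machine$double.xmin
    } else {
      max(stats::pf(fstat, 2, n - 3, lower.tail = FALSE),
          .Machine$double.xmin)
    }
  }
  structure(list(
    mesor = unname(cf["mesor"]), amplitude = unname(amp),
    acrophase = unname(acro), p_value = p,
    coefficients = cf, fitted.values = fit$fitted.values,
    residuals = fit$residuals, times = times, series = series,
    period = period, f_statistic = unname(fstat), df = c(2, n - 3)
  ), class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("Cosinor fit (period ", x$period, " h, n = ", length(x$series),
      ")\n", sep = "")
  cat(sprintf("  mesor %.4g  amplitude %.4g  acrophase CT%.2f\n",
              x$mesor, x$amplitude, x$acrophase))
  cat(sprintf("  F = %.4g on %d and %d df, p = %.3g\n",
              x$f_statistic, x$df[1], x$df[2], x$p_value))
  invisible(x)
}

#' @export
coef.cosinor_fit <- function(object, ...) object$coefficients

#' @export
residuals.cosinor_fit <- function(object, ...) object$residuals

#' @export
fitted.cosinor_fit <- function(object, ...) object$fitted.values

#' @export
predict.cosinor_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) return(object$fitted.values)
  w <- 2 * pi * newtimes / object$period
  cf <- object$coefficients
  unname(cf["mesor"] + cf["a"] * cos(w) + cf["b"] * sin(w))
}

#' @export
plot.cosinor_fit <- function(x, ...) {
  grid <- seq(0, x$period, length.out = 200)
  graphics::plot(x$times, x$series, xlab = "CT (h)", ylab = "log2 abundance",
                 main = sprintf("amplitude %.2f, acrophase CT%.1f",
                                x$amplitude, x$acrophase), ...)
  graphics::lines(grid, predict(x, grid), col = "steelblue")
  invisible(x)
}

# vectorized cosinor over the rows of a series x sample matrix
cosinor_scan <- function(Y, times, period = 24) {
  n <- length(times)
  w <- 2 * pi * times / period
  X <- cbind(1, cos(w), sin(w))
  XtX_inv <- solve(crossprod(X))
  B <- Y %*% X %*% XtX_inv            # series x 3 coefficients
  fitted <- B %*% t(X)
  rss1 <- rowSums((Y - fitted)^2)
  rss0 <- rowSums((Y - rowMeans(Y))^2)
  amp <- sqrt(B[, 2]^2 + B[, 3]^2)
  acro <- wrap_ct(atan2(B[, 3], B[, 2]) * period / (2 * pi), period)
  fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  p <- stats::pf(fstat, 2, n - 3, lower.tail = FALSE)
  flat <- rss0 <= .Machine$double.eps * n
  p[flat] <- 1; fstat[flat] <- 0
  p[!is.finite(p)] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  data.frame(series_id = rownames(Y), mesor = B[, 1], amplitude = amp,
             acrophase = acro, p_param = p, stringsAsFactors = FALSE)
}
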