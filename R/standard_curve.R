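#' Amplification efficiency from a dilution-series slope
#'
#' A standard curve regresses mean Ct on log10 template quantity; for a
#' valid series the slope is negative and the percent efficiency is
#' `E(%) = (10^(-1/slope) - 1) * 100`. A slope of -3.3219 (= -1/log10(2))
#' corresponds to perfect doubling, 100%.
#'
#' @param slope Slope of the Ct vs log10-quantity regression, in cycles per
#'   log10 unit. Must be negative.
#' @return Percent efficiency.
#' @examples
#' efficiency_percent(-3.321928)  # 100
#' @export
efficiency_percent <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0))
    stop("not a valid dilution series: slope must be negative")
  (10^(-1 / slope) - 1) * 100
}

#' @rdname efficiency_percent
#' @param percent Percent efficiency, e.g. 100.1 from an instrument report.
#' @return `efficiency_factor()`: the per-cycle amplification factor
#'   `1 + percent/100`, the form [ct_matrix()] expects.
#' @export
efficiency_factor <- function(percent) {
  if (any(!is.finite(percent)) || any(percent <= 0))
    stop("percent efficiency must be positive")
  1 + percent / 100
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of mean Ct on log10 template quantity across a
#' dilution series, reporting slope, intercept, R-squared (squared sample
#' correlation) and percent amplification efficiency. Used as the QC step
#' behind instrument-reported per-gene efficiencies.
#'
#' @param log10_quantity Numeric vector of log10 template quantities,
#'   strictly increasing or strictly decreasing, length >= 3.
#' @param mean_ct Mean Ct per dilution point, same length.
#' @return An object of class `standard_curve` with fields
#'   `log10_quantity`, `mean_ct`, `slope`, `intercept`, `r_squared`,
#'   `efficiency_percent`.
#' @examples
#' sc <- fit_standard_curve(c(0, -1, -2), c(23.36, 26.68, 30.00))
#' sc$efficiency_percent  # ~100.1
#' @export
fit_standard_curve <- function(log10_quantity, mean_ct) {
  x <- as.numeric(log10_quantity)
  y <- as.numeric(mean_ct)
  if (length(x) != length(y))
    stop("`log10_quantity` and `mean_ct` must have equal length")
  if (length(x) < 3L) stop("at least 3 dilution points are required")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("dilution points must be finite")
  dx <- diff(x)
  if (!(all(dx > 0) || all(dx < 0)))
    stop("log10 quantities must be strictly increasing or decreasing")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("not a valid dilution series: fitted slope is non-negative")
  structure(list(log10_quantity = x, mean_ct = y,
                 slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(x, y)^2,
                 efficiency_percent = efficiency_percent(slope)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: %d points, slope %.4f cycles/log10 unit\n",
              length(x$mean_ct), x$slope))
  cat(sprintf("R-squared %.4f, efficiency %.1f%%\n",
              x$r_squared, x$efficiency_percent))
  invisible(x)
}
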