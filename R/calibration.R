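# Weighted quadratic calibration-curve quantitation for LC-MS assays:
# analyte/internal-standard peak-area ratio vs nominal concentration with
# 1/x weighting, and back-calculation of unknowns.

#' Fit a weighted quadratic calibration curve
#'
#' Fits `ratio = a + b * conc + c * conc^2` by weighted least squares with
#' weights `1/conc` (so low-concentration standards, whose absolute error is
#' smaller, are not swamped by the high end). The fitted curve is checked
#' for monotonicity over the calibrated range and a warning is issued if it
#' turns over.
#'
#' @param concentration nominal standard concentrations, uM; all > 0, at
#'   least 4 distinct values.
#' @param ratio analyte / internal-standard peak-area ratios.
#' @param lloq lower limit of quantitation, uM (default 0.0073, the PLX3397
#'   assay LLOQ).
#' @param weighting `"1/x"` (default) or `"none"`.
#' @return a `calibration_curve`: list with `coefficients` (intercept,
#'   linear, quadratic), `range` (calibrated concentration range), `lloq`,
#'   `weighting`, `monotone`.
#' @export
fit_calibration <- function(concentration, ratio, lloq = 0.0073,
                            weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  if (length(concentration) != length(ratio))
    bad_arg("ratio", "lengths differ from concentration")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    bad_arg("concentration",
            "all standards must be positive (1/x weight undefined at 0)")
  if (length(unique(concentration)) < 4L)
    bad_arg("concentration", "need >= 4 distinct standard concentrations")
  if (lloq <= 0) bad_arg("lloq", "must be > 0")
  w <- if (weighting == "1/x") 1 / concentration else rep(1, length(ratio))
  fit <- lm(ratio ~ concentration + I(concentration^2), weights = w)
  cf <- unname(coef(fit))
  rng <- range(concentration)
  # monotone over range iff derivative b + 2 c x keeps one sign
  dlo <- cf[2] + 2 * cf[3] * rng[1]
  dhi <- cf[2] + 2 * cf[3] * rng[2]
  monotone <- sign(dlo) == sign(dhi) && dlo != 0
  if (!monotone)
    warning("fitted calibration curve is not monotone over the calibrated ",
            "range; back-calculation may be ambiguous", call. = FALSE)
  structure(list(coefficients = c(intercept = cf[1], linear = cf[2],
                                  quadratic = cf[3]),
                 range = rng, lloq = lloq, weighting = weighting,
                 monotone = monotone),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<calibration_curve> ratio = %.5g + %.5g x + %.5g x^2 (w = %s)\n",
              cf[1], cf[2], cf[3], x$weighting))
  cat(sprintf("  range %.4g - %.4g uM, LLOQ %.4g uM, monotone: %s\n",
              x$range[1], x$range[2], x$lloq, x$monotone))
  invisible(x)
}

#' Predict response ratio at given concentrations
#'
#' @param object a `calibration_curve`.
#' @param newdata concentrations, uM.
#' @param ... unused.
#' @return predicted ratios.
#' @export
predict.calibration_curve <- function(object, newdata, ...) {
  cf <- object$coefficients
  cf[1] + cf[2] * newdata + cf[3] * newdata^2
}

#' Back-calculate concentration from a response ratio
#'
#' Inverts the fitted quadratic: solves `a + b x + c x^2 = ratio` and
#' returns the non-negative real root within the calibrated span (zero up to
#' the top standard, with a small extrapolation allowance above it). Values
#' below the LLOQ are returned but flagged, never silently dropped.
#'
#' @param curve a `calibration_curve` from [fit_calibration()].
#' @param ratio response ratio(s).
#' @param extrapolate fractional allowance above the calibrated range when
#'   selecting the root (default 0.05).
#' @return data frame: `ratio`, `concentration_uM`, `below_lloq`.
#' @export
back_calculate <- function(curve, ratio, extrapolate = 0.05) {
  stopifnot(inherits(curve, "calibration_curve"))
  cf <- curve$coefficients
  lo <- -1e-12
  hi <- curve$range[2] * (1 + extrapolate)
  conc <- vapply(ratio, function(y) {
    a <- cf[3]; b <- cf[2]; cc <- cf[1] - y
    roots <- if (abs(a) < 1e-12 * max(1, abs(b))) {
      if (b == 0) numeric(0) else -cc / b
    } else {
      disc <- b^2 - 4 * a * cc
      if (disc < 0) numeric(0)
      else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    }
    roots <- roots[roots >= lo & roots <= hi]
    if (length(roots) == 0)
      stop(sprintf(paste0("ratio %.5g has no real root within the ",
                          "calibrated range [%.4g, %.4g] uM"),
                   y, curve$range[1], curve$range[2]), call. = FALSE)
    # monotone curves have exactly one in-range root; otherwise take the
    # root closest to the calibrated interior
    roots[which.min(abs(roots - mean(curve$range)))]
  }, numeric(1))
  data.frame(ratio = ratio, concentration_uM = conc,
             below_lloq = conc < curve$lloq * (1 - 1e-9))
}
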