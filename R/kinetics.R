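#' Fit a linear carboxyhaemoglobin washout
#'
#' Ordinary least squares on the above-baseline part of the washout series.
#' Points at or below baseline + baselineSd are excluded (the measured
#' saturation clamps at baseline, which would bias the slope); at least 3
#' usable points are required and the fitted slope must be negative. The
#' half-life is the time for the above-baseline saturation to halve under the
#' linear model: (S0 - baseline) / (2 |slope|), with S0 the fitted value at
#' t = 0.
#'
#' @param times minutes, strictly increasing
#' @param saturations percent CO-Hb, same length as \code{times}; a
#'   data.frame from \code{\link{generateWashoutSeries}} may be passed as
#'   \code{times} instead, in which case \code{saturations} and
#'   \code{baseline} default from it
#' @param baseline baseline percent CO-Hb saturation
#' @param baselineSd uncertainty of the baseline; points at or below
#'   baseline + baselineSd are excluded from the fit
#' @return a \linkS4class{WashoutFit}
#' @examples
#' ws <- generateWashoutSeries(54.8, 4.57, -0.7176, times = seq(0, 60, 5))
#' fitWashout(ws)  # half-life about 35 min
#' @export
fitWashout <- function(times, saturations = NULL, baseline = NULL,
                       baselineSd = 0) {
  if (is.data.frame(times)) {
    if (is.null(baseline)) baseline <- attr(times, "baseline")
    saturations <- times$co_sat_pct
    times <- times$time_min
  }
  if (is.null(baseline)) stop("baseline is required")
  if (length(times) != length(saturations))
    stop("times and saturations differ in length")
  if (is.unsorted(times, strictly = TRUE)) stop("times must strictly increase")
  use <- saturations > baseline + baselineSd
  if (sum(use) < 3L)
    stop("fewer than 3 points above baseline: cannot fit washout")
  fit <- stats::lm(saturations[use] ~ times[use])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= 0)
    stop("no washout: fitted slope is not negative")
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits trip summary.lm
  halfLife <- (intercept - baseline) / (2 * abs(slope))
  new("WashoutFit", slope = slope, intercept = intercept, rSquared = r2,
      halfLife = halfLife, baseline = baseline, nUsed = sum(use))
}

#' Housekeeping-normalized relative expression
#'
#' Target quantity divided by the housekeeping (ribosomal protein S12 or L28)
#' quantity of the same sample. Scale-equivariant: multiplying both
#' quantities by a constant leaves the ratio unchanged.
#'
#' @param target target-gene quantity, relative units
#' @param housekeeping housekeeping-gene quantity, relative units (> 0)
#' @return the normalized expression ratio
#' @examples relativeExpression(3.0, 1.5)
#' @export
relativeExpression <- function(target, housekeeping) {
  if (any(housekeeping <= 0)) stop("housekeeping quantity must be positive")
  target / housekeeping
}

#' Fold change over a reference
#'
#' @param a quantity
#' @param b positive reference quantity
#' @return a / b
#' @examples foldChange(7.5, 1.5)
#' @export
foldChange <- function(a, b) {
  if (any(b <= 0)) stop("reference quantity must be positive")
  a / b
}

#' Tagging fraction of a condition relative to a reference
#'
#' Percent of reference-tagged cells also tagged under the condition:
#' 100 * tagged_condition / tagged_reference. The raw percentage is returned;
#' for report text round to the nearest integer (e.g. 13300 / 50000 = 26.6,
#' reported as ~27).
#'
#' @param taggedCondition cells per mouse under the condition
#' @param taggedReference cells per mouse under the reference stimulus (> 0)
#' @return percentage (raw, unrounded)
#' @examples taggingFraction(13300, 50000)
#' @export
taggingFraction <- function(taggedCondition, taggedReference) {
  if (any(taggedReference <= 0)) stop("reference count must be positive")
  100 * taggedCondition / taggedReference
}
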