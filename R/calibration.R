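# Sensory-instrumental calibration: regress panel doneness scores on a
# texture parameter, then invert the fitted line (and its 95% confidence
# bands) at the adopted doneness score to obtain instrument-space thresholds.

# Reporting precision per parameter for the adopted threshold.
threshold_precision <- c(APF = 0.05, AAPF = 0.05, GAPF = 0.01)

# Column carrying each parameter in the sensory.csv schema.
sensory_column <- c(APF = "apf_N", AAPF = "aapf_Ns", GAPF = "gapf_Nps")

#' Fit a sensory-on-texture calibration line
#'
#' Ordinary least squares of an organoleptic score (tactile or chewiness,
#' 1-9 scale) on one texture-analyzer parameter, pooled over all records.
#'
#' @param records Sensory data frame in the `sensory.csv` schema (see
#'   [read_sensory()] / [simulate_sensory()]).
#' @param parameter `"APF"`, `"AAPF"` or `"GAPF"`.
#' @param modality `"tactile"` or `"chewiness"`.
#' @param ci_level Confidence level for threshold bands (default 0.95).
#' @return An object of class `calibration_line`: the underlying `lm` fit
#'   plus slope, intercept, Pearson r, n, residual sd and modality metadata.
#' @export
fit_calibration <- function(records, parameter = "APF",
                            modality = c("tactile", "chewiness"),
                            ci_level = 0.95) {
  parameter <- match_parameter(parameter)
  modality <- match.arg(modality)
  xcol <- sensory_column[[parameter]]
  ycol <- paste0(modality, "_score")
  stopifnot(xcol %in% names(records), ycol %in% names(records))
  x <- records[[xcol]]
  y <- records[[ycol]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("calibration needs at least 3 records (got ", length(x), ")")
  if (length(unique(x)) < 2)
    stop("degenerate design: all texture values identical")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  cf <- stats::coef(fit)
  smry <- suppressWarnings(summary(fit)) # exact fits trip summary.lm
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  structure(
    list(parameter = parameter, modality = modality,
         slope = unname(cf[2]), intercept = unname(cf[1]),
         r = r, n = length(x),
         residual_sd = smry$sigma,
         slope_p = smry$coefficients[2, 4],
         ci_level = ci_level, fit = fit),
    class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf(
    "Calibration: %s score = %.4f %+.4f x %s  (n = %d, r = %.3f, s = %.3f)\n",
    x$modality, x$intercept, x$slope, x$parameter, x$n, x$r, x$residual_sd))
  invisible(x)
}

#' @export
coef.calibration_line <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_line <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata = data.frame(x = newdata), ...)
}

# Invert the mean line at a score: x with intercept + slope*x = score.
invert_mean_line <- function(line, score) {
  (score - line$intercept) / line$slope
}

# Invert one pointwise confidence band (lower or upper mean-response band) at
# a score by bisection over a bracket around the mean-line inversion.
invert_band <- function(line, score, which = c("lwr", "upr")) {
  which <- match.arg(which)
  x0 <- invert_mean_line(line, score)
  f <- function(x) {
    p <- stats::predict(line$fit, newdata = data.frame(x = x),
                        interval = "confidence", level = line$ci_level)
    p[1, which] - score
  }
  # bands are monotone where the line is; bracket around x0
  span <- max(abs(x0), diff(range(line$fit$model$x)), 1e-3)
  lo <- x0 - 2 * span; hi <- x0 + 2 * span
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Derive instrument-space doneness thresholds
#'
#' Inverts one or two calibration lines (tactile and/or chewiness) at the
#' adopted doneness score. The adopted threshold is the arithmetic midpoint of
#' the per-modality mean-line inversions, rounded to the parameter's reporting
#' precision (APF 0.05 N, AAPF 0.05 N·s, GAPF 0.01 N·s⁻¹); the low/high
#' thresholds are the extremes of the inverted confidence-band crossings over
#' all modalities.
#'
#' @param lines A `calibration_line` or list of them (same parameter).
#' @param doneness_score Adopted doneness score (default 6.5 on the 1-9
#'   scale).
#' @return An object of class `threshold_set` with `threshold_low`,
#'   `threshold_adopted`, `threshold_high` (parameter units).
#' @export
derive_threshold <- function(lines, doneness_score = 6.5) {
  if (inherits(lines, "calibration_line")) lines <- list(lines)
  stopifnot(length(lines) >= 1)
  param <- unique(vapply(lines, `[[`, "", "parameter"))
  if (length(param) != 1)
    stop("all calibration lines must share one texture parameter")
  for (ln in lines) {
    if (ln$slope >= 0)
      stop("orientation error: calibration slope must be negative ",
           "(the scale runs soft-high)")
    alpha <- 1 - ln$ci_level
    if (ln$slope_p > alpha)
      stop("calibration slope not significantly nonzero (p = ",
           signif(ln$slope_p, 3), ")")
    yr <- range(ln$fit$model$y)
    if (doneness_score < yr[1] || doneness_score > yr[2])
      warning("doneness score ", doneness_score,
              " outside the observed score range [", yr[1], ", ", yr[2],
              "]; threshold is an extrapolation")
  }
  points <- vapply(lines, invert_mean_line, 0, score = doneness_score)
  bands <- unlist(lapply(lines, function(ln)
    c(invert_band(ln, doneness_score, "lwr"),
      invert_band(ln, doneness_score, "upr"))))
  bands <- bands[!is.na(bands)]
  all_x <- c(points, bands)
  prec <- threshold_precision[[param]]
  adopted <- round(mean(points) / prec) * prec
  structure(
    list(parameter = param, doneness_score = doneness_score,
         threshold_low = max(0, min(all_x)),
         threshold_high = max(0, max(all_x)),
         threshold_adopted = max(0, adopted),
         modality_inversions = stats::setNames(
           points, vapply(lines, `[[`, "", "modality"))),
    class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "%s threshold at doneness %.1f: %.3g (range %.3g-%.3g)\n",
    x$parameter, x$doneness_score, x$threshold_adopted,
    x$threshold_low, x$threshold_high))
  invisible(x)
}

#' Default adopted doneness thresholds
#'
#' The adopted instrument thresholds at doneness score 6.5 when no sensory
#' data are supplied: APF 0.80 N, AAPF 4.45 N·s, GAPF 0.10 N·s⁻¹.
#'
#' @param parameter Optionally, one parameter code; otherwise all three.
#' @return Named numeric vector of thresholds (parameter units).
#' @export
default_thresholds <- function(parameter = NULL) {
  th <- c(APF = 0.80, AAPF = 4.45, GAPF = 0.10)
  if (is.null(parameter)) th else th[[match_parameter(parameter)]]
}
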