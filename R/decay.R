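# Model 1: exponential softening kinetics. Texture summaries over cooking
# time are fitted with value = y0 + a*exp(-k*t); the optimal cooking time is
# either bracketed between observed times or predicted by inverting the
# fitted curve at the calibrated threshold. Predictions outside the observed
# range are first-class censored values, never clamped numbers.

#' Censored-aware OCT estimate
#'
#' Container for an optimal-cooking-time estimate: a point value in minutes,
#' a bracket between observed times, or a left/right-censored marker
#' (printed `"<t"` / `">t"`).
#'
#' @param method `"bracket"`, `"decay_inversion"` or `"sigmoid"`.
#' @param value Point estimate in minutes (`NA` when bracketed/censored).
#' @param bracket_low,bracket_high Bracket endpoints (observed times).
#' @param censored `"none"`, `"left"` or `"right"`.
#' @param censor_at Time the censoring refers to.
#' @param threshold_used Threshold (parameter units) the estimate refers to.
#' @param parameter Texture parameter code.
#' @param flags Character vector of diagnostic flags.
#' @return An object of class `oct_estimate`.
#' @export
oct_estimate <- function(method, value = NA_real_,
                         bracket_low = NA_real_, bracket_high = NA_real_,
                         censored = c("none", "left", "right"),
                         censor_at = NA_real_,
                         threshold_used = NA_real_, parameter = NA_character_,
                         flags = character()) {
  censored <- match.arg(censored)
  if (!is.na(bracket_low) && !is.na(bracket_high) &&
      bracket_low >= bracket_high)
    stop("bracket_low must be < bracket_high")
  structure(
    list(method = method, value = value,
         bracket_low = bracket_low, bracket_high = bracket_high,
         censored = censored, censor_at = censor_at,
         threshold_used = threshold_used, parameter = parameter,
         flags = flags),
    class = "oct_estimate")
}

#' @export
format.oct_estimate <- function(x, ...) {
  if (x$censored == "left") return(sprintf("<%g min", x$censor_at))
  if (x$censored == "right") return(sprintf(">%g min", x$censor_at))
  if (!is.na(x$bracket_low) || !is.na(x$bracket_high))
    return(sprintf("(%g, %g] min", x$bracket_low, x$bracket_high))
  sprintf("%.1f min", x$value)
}

#' @export
print.oct_estimate <- function(x, ...) {
  cat(sprintf("OCT estimate (%s): %s", x$method, format(x)))
  if (!is.na(x$threshold_used))
    cat(sprintf("  [threshold %g %s]", x$threshold_used,
                if (is.na(x$parameter)) "" else x$parameter))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Fit an exponential softening-decay curve
#'
#' Least-squares fit of `value = y0 + a*exp(-k*t)` by Levenberg-Marquardt,
#' initialized at `y0 = min(value)`, `a = max - min`, `k = 1/range(t)`, with
#' up to 5 restarts at jittered `k` on non-convergence. `r2` is
#' `1 - SSres/SStot`; the p-value is the regression F-test against the
#' constant-mean model (df 2, n - 3).
#'
#' @param time Cooking times (min), at least 4 distinct values.
#' @param value Texture summary values (parameter units).
#' @param input_kind `"plain"` or `"weighted"` (metadata only).
#' @param parameter Texture parameter code (metadata only).
#' @return An object of class `decay_fit`.
#' @export
fit_decay <- function(time, value, input_kind = c("plain", "weighted"),
                      parameter = NA_character_) {
  input_kind <- match.arg(input_kind)
  stopifnot(length(time) == length(value))
  ok <- stats::complete.cases(time, value)
  time <- time[ok]; value <- value[ok]
  if (length(unique(time)) < 4)
    stop("decay fit needs at least 4 distinct time points")
  df <- data.frame(t = time, y = value)
  if (diff(range(value)) <= 1e-8 * max(1, abs(mean(value)))) {
    # constant series: no decay signal; report a flat fit rather than
    # failing, flagged so downstream stages can reject it
    return(structure(
      list(y0 = mean(value), a = 0, k = 1 / diff(range(time)), r2 = 0,
           p_value = NA_real_, n_points = nrow(df),
           input_kind = input_kind, parameter = parameter,
           flags = "constant_series", fit = NULL, data = df),
      class = "decay_fit"))
  }
  k0 <- 1 / diff(range(time))
  start <- list(y0 = min(value), a = max(value) - min(value), k = k0)
  if (start$a <= 0) start$a <- max(abs(value), 1e-6) * 0.1
  fit <- NULL
  jitter_mult <- c(1, 0.3, 3, 0.1, 10)
  for (j in jitter_mult) {
    s <- start; s$k <- k0 * j
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ y0 + a * exp(-k * t), data = df, start = s,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("decay fit failed to converge after ", length(jitter_mult),
         " restarts (n = ", nrow(df), ", range = ",
         paste(signif(range(value), 4), collapse = "-"), ")")
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((value - mean(value))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  n <- nrow(df)
  p_value <- regression_f_pvalue(ss_tot, ss_res, df_model = 2,
                                 df_resid = n - 3)
  flags <- character()
  if (cf[["k"]] <= 0) flags <- c(flags, "non_monotone")
  if (r2 < 0.1 && abs(cf[["a"]]) < 1e-6 * max(abs(value)))
    flags <- c(flags, "constant_series")
  structure(
    list(y0 = cf[["y0"]], a = cf[["a"]], k = cf[["k"]],
         r2 = max(0, min(1, r2)), p_value = p_value, n_points = n,
         input_kind = input_kind, parameter = parameter,
         flags = flags, fit = fit, data = df),
    class = "decay_fit")
}

# F-test of a fitted curve against the constant-mean model.
regression_f_pvalue <- function(ss_tot, ss_res, df_model, df_resid) {
  if (df_resid <= 0 || ss_res <= 0) return(NA_real_)
  f <- ((ss_tot - ss_res) / df_model) / (ss_res / df_resid)
  stats::pf(f, df_model, df_resid, lower.tail = FALSE)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit (%s): f(t) = %.4g + %.4g * exp(-%.4g t)\n",
    x$input_kind, x$y0, x$a, x$k))
  cat(sprintf("  n = %d, r2 = %.4f, p = %s%s\n", x$n_points, x$r2,
              format.pval(x$p_value, digits = 3),
              if (length(x$flags)) paste0(", flags: ",
                                          paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(y0 = object$y0, a = object$a, k = object$k)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$t else newdata
  object$y0 + object$a * exp(-object$k * t)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' Bracket the OCT between observed cooking times
#'
#' Returns the interval `(t_i, t_{i+1}]` between the last observed time with
#' value above the threshold and the first with value at or below it;
#' left-censored at the first time when the series starts at or below the
#' threshold, right-censored at the last when it never reaches it. On a
#' non-monotone series the first downward crossing is used and a
#' `multi_crossing` flag set.
#'
#' @param time Observed cooking times (min), sorted ascending.
#' @param value Texture summary values at those times.
#' @param threshold Doneness threshold (parameter units).
#' @param parameter Texture parameter code (metadata only).
#' @return An [oct_estimate()] with `method = "bracket"`.
#' @export
bracket_oct <- function(time, value, threshold, parameter = NA_character_) {
  stopifnot(length(time) == length(value), length(time) >= 2)
  if (is.unsorted(time, strictly = TRUE)) stop("times must be sorted, distinct")
  below <- value <= threshold
  flags <- character()
  crossings <- which(diff(below) != 0)
  if (length(crossings) > 1) flags <- c(flags, "multi_crossing")
  if (below[1])
    return(oct_estimate("bracket", censored = "left", censor_at = time[1],
                        threshold_used = threshold, parameter = parameter,
                        flags = flags))
  first_below <- which(below)[1]
  if (is.na(first_below))
    return(oct_estimate("bracket", censored = "right",
                        censor_at = time[length(time)],
                        threshold_used = threshold, parameter = parameter,
                        flags = flags))
  oct_estimate("bracket",
               bracket_low = time[first_below - 1],
               bracket_high = time[first_below],
               threshold_used = threshold, parameter = parameter,
               flags = flags)
}

#' Predict the OCT by inverting a decay fit at a threshold
#'
#' Solves `y0 + a*exp(-k*t) = threshold` for t:
#' `t* = -log((threshold - y0)/a)/k`. A threshold at or below the plateau
#' `y0` is unattainable (right-censored); a threshold at or above `y0 + a`
#' is already met at t = 0 (left-censored at 0).
#'
#' @param fit A [fit_decay()] result with `k > 0`.
#' @param threshold Doneness threshold (parameter units).
#' @return An [oct_estimate()] with `method = "decay_inversion"`.
#' @export
invert_decay <- function(fit, threshold) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$k <= 0) stop("fit rejected: non-positive decay rate k")
  if (fit$a <= 0) stop("inversion error: non-positive amplitude a")
  tmax <- max(fit$data$t)
  if (threshold <= fit$y0)
    return(oct_estimate("decay_inversion", censored = "right",
                        censor_at = tmax, threshold_used = threshold,
                        parameter = fit$parameter))
  if (threshold - fit$y0 >= fit$a)
    return(oct_estimate("decay_inversion", censored = "left", censor_at = 0,
                        threshold_used = threshold,
                        parameter = fit$parameter))
  t_star <- -log((threshold - fit$y0) / fit$a) / fit$k
  oct_estimate("decay_inversion", value = t_star,
               threshold_used = threshold, parameter = fit$parameter)
}
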