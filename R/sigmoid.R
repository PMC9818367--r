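# Model 2: the cooked-seed-fraction statistic and its sigmoid model. At each
# cooking time, the proportion of measured intact readings at or below the
# doneness threshold is scaled to the full intact seed count, overcooked
# seeds count as cooked by definition, and the resulting percentage of the
# whole subsample is modelled over time with a three-parameter logistic
# anchored at (0 min, 0 %). The optimal cooking time is the curve's crossing
# of a target cooked percentage.

#' Cooked-seed fraction of one trial
#'
#' `p_within` is the proportion of measured intact readings within
#' `[0, threshold]`; the cooked percentage scales it to the trial's full
#' intact count and adds all overcooked seeds:
#' `100 * (p_within * n_intact_total + n_overcooked) / n_seeds_initial`.
#'
#' @param trial A [cooking_trial()] with at least one intact reading.
#' @param parameter Texture parameter code.
#' @param threshold Doneness threshold (parameter units, > 0).
#' @return One-row data frame (class `cooked_fraction_point`): cooking time,
#'   `pct_cooked`, and the counts entering it.
#' @export
cooked_fraction <- function(trial, parameter = "APF",
                            threshold = default_thresholds("APF")) {
  stopifnot(inherits(trial, "cooking_trial"))
  parameter <- match_parameter(parameter)
  if (threshold <= 0) stop("threshold must be > 0")
  v <- trial$readings[[reading_column[[parameter]]]]
  intact <- trial$readings$status == "intact"
  if (!any(intact)) stop("trial has no intact readings")
  p_within <- mean(v[intact] <= threshold)
  n_total <- trial$n_seeds_initial
  n_over <- trial$n_overcooked
  n_intact_total <- n_total - n_over
  pct <- 100 * (p_within * n_intact_total + n_over) / n_total
  out <- data.frame(
    lot_id = trial$lot_id, maturity = trial$maturity,
    cooking_time = trial$cooking_time_min, parameter = parameter,
    pct_cooked = pct, n_within = sum(v[intact] <= threshold),
    n_intact_measured = sum(intact), n_overcooked = n_over,
    n_total = n_total, range_low = 0, range_high = threshold,
    stringsAsFactors = FALSE)
  class(out) <- c("cooked_fraction_point", class(out))
  out
}

#' Cooked-fraction curve over an experiment
#'
#' Computes the cooked percentage at every cooking time, pooling replicate
#' subsamples (and, for `maturity = "TOTAL"`, both maturities) by summing
#' reading and seed counts before forming the percentage.
#'
#' @param trials List of [cooking_trial()] objects.
#' @param parameter Texture parameter code.
#' @param threshold Doneness threshold (parameter units).
#' @param maturity `"MB"`, `"IMG"` or `"TOTAL"` (pooled).
#' @return Data frame of per-time cooked-fraction points.
#' @export
cooked_fraction_curve <- function(trials, parameter = "APF",
                                  threshold = default_thresholds("APF"),
                                  maturity = "TOTAL") {
  maturity <- match.arg(maturity, MATURITY_ALL)
  keep <- if (maturity == "TOTAL") trials else
    Filter(function(tr) tr$maturity == maturity, trials)
  if (!length(keep)) stop("no trials for maturity ", maturity)
  times <- sort(unique(vapply(keep, `[[`, 0, "cooking_time_min")))
  rows <- lapply(times, function(t) {
    sub <- Filter(function(tr) tr$cooking_time_min == t, keep)
    pts <- do.call(rbind, lapply(sub, cooked_fraction,
                                 parameter = parameter,
                                 threshold = threshold))
    # pooled percentage: scale each subsample's p_within by its own counts
    n_int_tot <- pts$n_total - pts$n_overcooked
    p_within <- pts$n_within / pts$n_intact_measured
    pct <- 100 * sum(p_within * n_int_tot + pts$n_overcooked) /
      sum(pts$n_total)
    data.frame(lot_id = pts$lot_id[1], maturity = maturity,
               cooking_time = t, parameter = pts$parameter[1],
               pct_cooked = pct, n_within = sum(pts$n_within),
               n_intact_measured = sum(pts$n_intact_measured),
               n_overcooked = sum(pts$n_overcooked),
               n_total = sum(pts$n_total),
               range_low = 0, range_high = threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit a three-parameter sigmoid to cooked-fraction points
#'
#' Least-squares fit of `f(t) = a / (1 + exp(-(t - x0)/b))` by
#' Levenberg-Marquardt. By default the anchor point (0 min, 0 %) is appended
#' with the same weight as the observed points, encoding that all seeds are
#' uncooked at the start of the procedure.
#'
#' @param points Data frame with columns `cooking_time` and `pct_cooked`
#'   (from [cooked_fraction_curve()]), or a two-column time/percentage frame.
#' @param anchor_origin Append the (0, 0) anchor (default `TRUE`).
#' @return An object of class `sigmoid_fit` with `a` (asymptote, %),
#'   `x0` (inflection, min), `b` (scale, min), `r2`, `p_value` and flags.
#' @export
fit_sigmoid <- function(points, anchor_origin = TRUE) {
  t <- points$cooking_time
  y <- points$pct_cooked
  stopifnot(length(t) == length(y))
  if (anchor_origin && !any(t == 0)) {
    t <- c(0, t); y <- c(0, y)
  }
  if (length(unique(t)) < 4)
    stop("sigmoid fit needs at least 4 distinct points after anchoring")
  df <- data.frame(t = t, y = y)
  flags <- character()
  if (diff(range(y)) < 1e-8) {
    flags <- c(flags, "degenerate_constant")
    stop("degenerate cooked-fraction series: all points equal (",
         signif(y[1], 4), ")")
  }
  a0 <- max(y)
  x00 <- t[which.min(abs(y - a0 / 2))]
  b0 <- max(diff(range(t)) / 6, 1)
  fit <- NULL
  for (mult in c(1, 0.5, 2, 0.25, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a / (1 + exp(-(t - x0) / b)), data = df,
                        start = list(a = a0, x0 = x00, b = b0 * mult),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("sigmoid fit failed to converge after 5 restarts")
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  n <- nrow(df)
  p_value <- regression_f_pvalue(ss_tot, ss_res, 2, n - 3)
  if (cf[["a"]] < max(y) - 20) flags <- c(flags, "asymptote_below_data")
  if (cf[["a"]] <= 0 || cf[["b"]] <= 0) flags <- c(flags, "invalid_shape")
  structure(
    list(a = cf[["a"]], x0 = cf[["x0"]], b = cf[["b"]],
         r2 = max(0, min(1, r2)), p_value = p_value, n_points = n,
         anchored_at_origin = anchor_origin, flags = flags,
         fit = fit, data = df),
    class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Sigmoid fit: f(t) = %.4g / (1 + exp(-(t - %.4g)/%.4g))\n",
              x$a, x$x0, x$b))
  cat(sprintf("  n = %d%s, r2 = %.4f, p = %s%s\n", x$n_points,
              if (x$anchored_at_origin) " (incl. origin anchor)" else "",
              x$r2, format.pval(x$p_value, digits = 3),
              if (length(x$flags)) paste0(", flags: ",
                                          paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(a = object$a, x0 = object$x0, b = object$b)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$t else newdata
  object$a / (1 + exp(-(t - object$x0) / object$b))
}

#' Predict the OCT from a sigmoid fit at a target cooked percentage
#'
#' Absolute mode solves `f(t) = target`:
#' `t* = x0 + b*log(target/(a - target))`; normalized mode solves
#' `f(t)/a = target/100`: `t* = x0 + b*log(target/(100 - target))`. A target
#' at or above the asymptote (absolute mode) is unattainable and yields a
#' right-censored estimate, not an error.
#'
#' @param fit A [fit_sigmoid()] result.
#' @param target_pct Target cooked percentage (default 99).
#' @param mode `"absolute"` or `"normalized"`.
#' @return An [oct_estimate()] with `method = "sigmoid"`.
#' @export
predict_oct <- function(fit, target_pct = 99,
                        mode = c("absolute", "normalized")) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  mode <- match.arg(mode)
  if (fit$a <= 0 || fit$b <= 0) stop("fit rejected: invalid sigmoid shape")
  if (target_pct <= 0) stop("target_pct must be > 0")
  tmax <- max(fit$data$t)
  if (mode == "absolute") {
    if (target_pct >= fit$a)
      return(oct_estimate("sigmoid", censored = "right", censor_at = tmax,
                          threshold_used = target_pct,
                          flags = "target_above_asymptote"))
    t_star <- fit$x0 + fit$b * log(target_pct / (fit$a - target_pct))
  } else {
    if (target_pct >= 100)
      return(oct_estimate("sigmoid", censored = "right", censor_at = tmax,
                          threshold_used = target_pct))
    t_star <- fit$x0 + fit$b * log(target_pct / (100 - target_pct))
  }
  oct_estimate("sigmoid", value = t_star, threshold_used = target_pct)
}

#' Observed vs fitted correlation report
#'
#' Pearson correlation between observed cooked percentages and the fitted
#' sigmoid evaluated at the same times.
#'
#' @param points Cooked-fraction points (as passed to [fit_sigmoid()]).
#' @param fit A [fit_sigmoid()] result.
#' @return List with `r`, `r2` and `n`.
#' @export
experimental_vs_predicted <- function(points, fit) {
  obs <- points$pct_cooked
  if (length(obs) < 3) stop("need at least 3 points")
  pred <- predict(fit, newdata = points$cooking_time)
  r <- stats::cor(obs, pred)
  list(r = r, r2 = r^2, n = length(obs))
}

#' Validate a predicted OCT on trials cooked at that time
#'
#' Computes the cooked percentage and count-weighted texture mean of
#' validation trials cooked at a single applied time, plus mean panel scores
#' when sensory records are supplied. The prediction passes when the cooked
#' percentage reaches `min_pct_cooked` and the weighted mean does not exceed
#' the threshold.
#'
#' @param new_trials List of [cooking_trial()] objects cooked at one time.
#' @param threshold Doneness threshold (parameter units).
#' @param parameter Texture parameter code.
#' @param sensory Optional sensory data frame (scores averaged if given).
#' @param min_pct_cooked Pass criterion on the cooked percentage (default
#'   95).
#' @return List of class `oct_validation`: applied time, `pct_cooked`,
#'   `weighted_mean`, optional sensory means, and `pass`.
#' @export
validate_oct <- function(new_trials, threshold = default_thresholds("APF"),
                         parameter = "APF", sensory = NULL,
                         min_pct_cooked = 95) {
  parameter <- match_parameter(parameter)
  times <- unique(vapply(new_trials, `[[`, 0, "cooking_time_min"))
  if (length(times) != 1)
    stop("validation trials must share a single applied cooking time")
  pts <- cooked_fraction_curve(new_trials, parameter = parameter,
                               threshold = threshold, maturity = "TOTAL")
  summaries <- summarize_trials(new_trials, parameter = parameter)
  tot <- summaries[summaries$maturity == "TOTAL", ]
  if (nrow(tot) == 0) tot <- summaries # single-maturity validation set
  out <- list(applied_time = times, parameter = parameter,
              threshold = threshold,
              pct_cooked = pts$pct_cooked[1],
              weighted_mean = tot$mean_weighted[1],
              tactile_mean = if (!is.null(sensory))
                mean(sensory$tactile_score) else NA_real_,
              chewiness_mean = if (!is.null(sensory))
                mean(sensory$chewiness_score) else NA_real_,
              min_pct_cooked = min_pct_cooked)
  out$pass <- out$pct_cooked >= min_pct_cooked &&
    out$weighted_mean <= threshold
  class(out) <- "oct_validation"
  out
}

#' @export
print.oct_validation <- function(x, ...) {
  cat(sprintf(
    "Validation at %g min: %.1f%% cooked, weighted %s %.3g (threshold %g): %s\n",
    x$applied_time, x$pct_cooked, x$parameter, x$weighted_mean, x$threshold,
    if (x$pass) "PASS" else "FAIL"))
  if (!is.na(x$tactile_mean))
    cat(sprintf("  panel: tactile %.1f, chewiness %.1f\n",
                x$tactile_mean, x$chewiness_mean))
  invisible(x)
}
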