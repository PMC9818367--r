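# Trial-level descriptive summaries: water uptake, overcooked percentage,
# lot composition ratio, and plain vs count-weighted texture means in which
# overcooked seeds are carried at their (near-zero) measured force — or at an
# imputed 0 N when counted but not measured.

#' Percentage mass increase of a cooked subsample
#'
#' @param trial A [cooking_trial()].
#' @return `100 * (cooked - initial) / initial` (%).
#' @export
mass_increase_percent <- function(trial) {
  stopifnot(inherits(trial, "cooking_trial"))
  if (trial$initial_mass_g <= 0) stop("initial mass must be positive")
  100 * (trial$cooked_mass_g - trial$initial_mass_g) / trial$initial_mass_g
}

#' Percentage of overcooked seeds in a trial
#'
#' @param trial A [cooking_trial()].
#' @return `100 * n_overcooked / n_seeds_initial` (%).
#' @export
overcooked_percent <- function(trial) {
  stopifnot(inherits(trial, "cooking_trial"))
  if (trial$n_seeds_initial <= 0) stop("trial has no seeds")
  100 * trial$n_overcooked / trial$n_seeds_initial
}

#' Maturity composition ratio of a lot
#'
#' The MB:IMG seed-count ratio, reported at one decimal. A lot with no IMG
#' seeds yields `Inf` (an explicit infinite-ratio signal, not an error).
#'
#' @param lot A [seed_lot()].
#' @return `pct_mb / pct_img` rounded to one decimal.
#' @export
composition_ratio <- function(lot) {
  stopifnot(inherits(lot, "seed_lot"))
  img <- lot$cat_percent[["IMG"]]
  if (img == 0) return(Inf)
  round(lot$cat_percent[["MB"]] / img, 1)
}

reading_column <- c(APF = "apf", AAPF = "aapf", GAPF = "gapf")

#' Plain and count-weighted texture summary of one trial
#'
#' `mean_plain` is the simple mean over all available readings (intact plus
#' the few measured overcooked seeds). `mean_weighted` scales the intact and
#' overcooked means by the trial's full seed counts:
#' `(mean_intact * n_intact_total + mean_overcooked * n_overcooked_total) /
#' n_seeds_initial`. When overcooked seeds were counted but none measured,
#' the overcooked mean is imputed as 0 (they offer no penetration
#' resistance) and the summary is flagged `imputed`.
#'
#' @param trial A [cooking_trial()] with at least one intact reading.
#' @param parameter `"APF"`, `"AAPF"` or `"GAPF"`.
#' @param impute_overcooked If `FALSE`, a weighted mean that would need the
#'   0-force imputation raises an error instead.
#' @return An object of class `texture_summary` (a one-row data frame).
#' @export
texture_summary <- function(trial, parameter = "APF",
                            impute_overcooked = TRUE) {
  stopifnot(inherits(trial, "cooking_trial"))
  parameter <- match_parameter(parameter)
  v <- trial$readings[[reading_column[[parameter]]]]
  status <- trial$readings$status
  v_int <- v[status == "intact"]
  v_ovr <- v[status == "overcooked"]
  if (length(v_int) == 0) stop("trial has no intact readings")
  n_int_total <- trial$n_seeds_initial - trial$n_overcooked
  n_ovr_total <- trial$n_overcooked
  imputed <- FALSE
  if (n_ovr_total > 0 && length(v_ovr) == 0) {
    if (!impute_overcooked)
      stop("overcooked seeds counted but none measured and imputation disabled")
    mean_ovr <- 0
    imputed <- TRUE
  } else {
    mean_ovr <- if (length(v_ovr)) mean(v_ovr) else NA_real_
  }
  mean_int <- mean(v_int)
  mean_weighted <- if (n_ovr_total == 0) mean_int else
    (mean_int * n_int_total + mean_ovr * n_ovr_total) /
    (n_int_total + n_ovr_total)
  out <- data.frame(
    lot_id = trial$lot_id, maturity = trial$maturity,
    cooking_time = trial$cooking_time_min, parameter = parameter,
    mean_plain = mean(v), mean_weighted = mean_weighted,
    mean_intact = mean_int, mean_overcooked = mean_ovr,
    n_intact_measured = length(v_int), n_overcooked_measured = length(v_ovr),
    n_intact_total = n_int_total, n_overcooked_total = n_ovr_total,
    sd = stats::sd(v), imputed = imputed,
    stringsAsFactors = FALSE)
  class(out) <- c("texture_summary", class(out))
  out
}

#' Combine the two maturity summaries into a TOTAL summary
#'
#' The TOTAL plain mean pools the readings of both maturities (a
#' reading-count-weighted mean of the two plain means); the TOTAL weighted
#' mean combines intact and overcooked means across maturities by their full
#' seed counts.
#'
#' @param summary_mb,summary_img [texture_summary()] rows for the MB and IMG
#'   subsamples of the same lot, cooking time and parameter.
#' @return A `texture_summary` row with `maturity = "TOTAL"`.
#' @export
total_summary <- function(summary_mb, summary_img) {
  s <- rbind(as.data.frame(summary_mb), as.data.frame(summary_img))
  if (length(unique(s$cooking_time)) != 1 ||
      length(unique(s$parameter)) != 1 || length(unique(s$lot_id)) != 1)
    stop("summaries must share lot, cooking time and parameter")
  n_meas <- s$n_intact_measured + s$n_overcooked_measured
  mean_plain <- sum(s$mean_plain * n_meas) / sum(n_meas)
  m_ovr <- ifelse(is.na(s$mean_overcooked), 0, s$mean_overcooked)
  num <- sum(s$mean_intact * s$n_intact_total + m_ovr * s$n_overcooked_total)
  den <- sum(s$n_intact_total + s$n_overcooked_total)
  out <- data.frame(
    lot_id = s$lot_id[1], maturity = "TOTAL",
    cooking_time = s$cooking_time[1], parameter = s$parameter[1],
    mean_plain = mean_plain, mean_weighted = num / den,
    mean_intact = sum(s$mean_intact * s$n_intact_total) /
      sum(s$n_intact_total),
    mean_overcooked = if (sum(s$n_overcooked_total) > 0)
      sum(m_ovr * s$n_overcooked_total) / sum(s$n_overcooked_total)
      else NA_real_,
    n_intact_measured = sum(s$n_intact_measured),
    n_overcooked_measured = sum(s$n_overcooked_measured),
    n_intact_total = sum(s$n_intact_total),
    n_overcooked_total = sum(s$n_overcooked_total),
    sd = NA_real_, imputed = any(s$imputed),
    stringsAsFactors = FALSE)
  class(out) <- c("texture_summary", class(out))
  out
}

#' Texture summaries for a whole experiment
#'
#' Applies [texture_summary()] to every trial, pools replicate subsamples of
#' the same maturity x time cell (readings and counts summed), and appends
#' the TOTAL aggregate per time.
#'
#' @param trials List of [cooking_trial()] objects.
#' @param parameter Texture parameter code.
#' @return Data frame of `texture_summary` rows (maturities MB, IMG, TOTAL).
#' @export
summarize_trials <- function(trials, parameter = "APF") {
  parameter <- match_parameter(parameter)
  key <- vapply(trials, function(tr)
    paste(tr$lot_id, tr$maturity, tr$cooking_time_min, sep = "|"), "")
  pooled <- lapply(split(trials, key), pool_trials)
  rows <- do.call(rbind, lapply(pooled, texture_summary,
                                parameter = parameter))
  totals <- do.call(rbind, lapply(
    split(rows, paste(rows$lot_id, rows$cooking_time)),
    function(grp) {
      if (!all(c("MB", "IMG") %in% grp$maturity)) return(NULL)
      total_summary(grp[grp$maturity == "MB", ], grp[grp$maturity == "IMG", ])
    }))
  out <- rbind(rows, totals)
  out <- out[order(out$lot_id, match(out$maturity, MATURITY_ALL),
                   out$cooking_time), ]
  rownames(out) <- NULL
  out
}

# Merge replicate trials of one maturity x time cell into a single
# cooking_trial with summed masses, counts and concatenated readings.
pool_trials <- function(trials) {
  if (length(trials) == 1) return(trials[[1]])
  t1 <- trials[[1]]
  cooking_trial(
    t1$lot_id, t1$maturity, t1$cooking_time_min,
    sum(vapply(trials, `[[`, 0, "initial_mass_g")),
    sum(vapply(trials, `[[`, 0, "cooked_mass_g")),
    sum(vapply(trials, `[[`, 0L, "n_seeds_initial")),
    sum(vapply(trials, `[[`, 0L, "n_overcooked")),
    readings = do.call(rbind, lapply(trials, `[[`, "readings")))
}
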