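# End-to-end orchestration: simulate (or load) a cooking experiment, derive
# the doneness threshold from sensory records, summarize trials, fit the
# decay and sigmoid models, predict the optimal cooking time, run the
# factorial ANOVA, and validate the prediction by cooking a fresh set of
# subsamples at the predicted time.

#' Pipeline configuration
#'
#' @param rng_seed Integer seed; mandatory when simulation is enabled. Stage
#'   sub-streams are derived from it so toggling one stage does not perturb
#'   another's draws.
#' @param generator A [generator_config()] for the simulation stage, or
#'   `NULL` to disable simulation (then `input_dir` must hold the four CSVs).
#' @param input_dir Directory with `lots.csv`, `trials.csv`, `readings.csv`,
#'   `sensory.csv` when simulation is off.
#' @param parameter Texture parameter driving OCT prediction (default APF).
#' @param target_pct Target cooked percentage for OCT (default 99).
#' @param mode `"absolute"` or `"normalized"` sigmoid inversion.
#' @param doneness_score Adopted doneness score for calibration.
#' @param out_dir Optional output directory for the report and stage CSVs.
#' @param stages Character vector of stages to run, in pipeline order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rng_seed = NULL, generator = NULL,
                            input_dir = NULL, parameter = "APF",
                            target_pct = 99,
                            mode = c("absolute", "normalized"),
                            doneness_score = 6.5, out_dir = NULL,
                            stages = c("simulate", "calibrate", "describe",
                                       "decay", "sigmoid", "anova",
                                       "validate")) {
  mode <- match.arg(mode)
  if ("simulate" %in% stages) {
    if (is.null(generator) && is.null(input_dir))
      stop("configuration error: no input_dir and simulation not configured")
    if (!is.null(generator) && is.null(rng_seed) &&
        is.null(generator$rng_seed))
      stop("rng_seed is mandatory when simulation is enabled")
  } else if (is.null(input_dir)) {
    stop("configuration error: no inputs and simulation disabled")
  }
  structure(list(rng_seed = rng_seed, generator = generator,
                 input_dir = input_dir,
                 parameter = match_parameter(parameter),
                 target_pct = target_pct, mode = mode,
                 doneness_score = doneness_score, out_dir = out_dir,
                 stages = stages),
            class = "pipeline_config")
}

# Derive a deterministic per-stage seed from the master seed, kept below
# 2^31 so it stays a valid R integer.
stage_seed <- function(master, stage) {
  offs <- c(simulate = 101L, calibrate = 211L, describe = 307L,
            decay = 401L, sigmoid = 503L, anova = 601L, validate = 701L)
  as.integer((as.numeric(master) * 1009 + offs[[stage]]) %% 2147483647)
}

#' Run the full OCT-estimation pipeline
#'
#' Executes the enabled stages in order and assembles a consolidated report.
#' Any stage failure aborts with the failing stage named; outputs of the
#' stages already completed are retained in the error condition's `report`
#' field. Identical configuration and seed reproduce an identical report.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with one element per executed
#'   stage plus a `manifest` (seed, configuration echo, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(manifest = list(
    rng_seed = config$rng_seed, parameter = config$parameter,
    target_pct = config$target_pct, mode = config$mode,
    stages = config$stages,
    package_version = as.character(utils::packageVersion("octlens"))))
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      e$message <- paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e))
      e$report <- report
      stop(e)
    })
  }
  lot <- NULL; trials <- NULL; sensory <- NULL

  if ("simulate" %in% config$stages && !is.null(config$generator)) {
    gen <- config$generator
    if (!is.null(config$rng_seed))
      gen$rng_seed <- stage_seed(config$rng_seed, "simulate")
    sim <- run_stage("simulate", function() simulate_experiment(gen))
    lot <- sim$lot; trials <- sim$trials; sensory <- sim$sensory
    report$composition <- list(
      lot_id = lot$lot_id, tsm_whole_g = lot$tsm_whole_g,
      pct_mb = lot$cat_percent[["MB"]], pct_img = lot$cat_percent[["IMG"]],
      ratio_mb_img = composition_ratio(lot))
  } else {
    inp <- run_stage("load", function() {
      lots <- read_lots(file.path(config$input_dir, "lots.csv"))
      readings <- read_readings(file.path(config$input_dir, "readings.csv"))
      trials <- read_trials(file.path(config$input_dir, "trials.csv"),
                            readings = readings)
      spath <- file.path(config$input_dir, "sensory.csv")
      sens <- if (file.exists(spath)) read_sensory(spath) else NULL
      list(lot = lots[[1]], trials = trials, sensory = sens)
    })
    lot <- inp$lot; trials <- inp$trials; sensory <- inp$sensory
    report$composition <- list(
      lot_id = lot$lot_id, tsm_whole_g = lot$tsm_whole_g,
      pct_mb = lot$cat_percent[["MB"]], pct_img = lot$cat_percent[["IMG"]],
      ratio_mb_img = composition_ratio(lot))
  }

  threshold <- default_thresholds(config$parameter)
  if ("calibrate" %in% config$stages && !is.null(sensory) &&
      nrow(sensory) >= 3) {
    cal <- run_stage("calibrate", function() {
      lines <- list(
        fit_calibration(sensory, config$parameter, "tactile"),
        fit_calibration(sensory, config$parameter, "chewiness"))
      derive_threshold(lines, config$doneness_score)
    })
    threshold <- cal$threshold_adopted
    report$calibration <- list(
      parameter = cal$parameter, doneness_score = cal$doneness_score,
      threshold_adopted = cal$threshold_adopted,
      threshold_low = cal$threshold_low,
      threshold_high = cal$threshold_high)
  } else {
    report$calibration <- list(parameter = config$parameter,
                               threshold_adopted = threshold,
                               source = "default")
  }

  summaries <- NULL
  if ("describe" %in% config$stages) {
    summaries <- run_stage("describe", function()
      summarize_trials(trials, parameter = config$parameter))
    report$descriptives <- summaries
  }

  if ("decay" %in% config$stages && !is.null(summaries)) {
    report$decay <- run_stage("decay", function() {
      rows <- lapply(split(summaries, summaries$maturity), function(grp) {
        grp <- grp[order(grp$cooking_time), ]
        out <- list()
        for (kind in c("plain", "weighted")) {
          vals <- if (kind == "plain") grp$mean_plain else grp$mean_weighted
          fit <- fit_decay(grp$cooking_time, vals, input_kind = kind,
                           parameter = config$parameter)
          br <- bracket_oct(grp$cooking_time, vals, threshold,
                            parameter = config$parameter)
          inv <- invert_decay(fit, threshold)
          out[[kind]] <- data.frame(
            maturity = grp$maturity[1], input_kind = kind,
            y0 = fit$y0, a = fit$a, k = fit$k, r2 = fit$r2,
            p_value = fit$p_value, oct_bracket = format(br),
            oct_predicted = format(inv), stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
      })
      do.call(rbind, rows)
    })
  }

  sig_fit <- NULL; oct <- NULL
  if ("sigmoid" %in% config$stages) {
    sig <- run_stage("sigmoid", function() {
      pts <- cooked_fraction_curve(trials, parameter = config$parameter,
                                   threshold = threshold,
                                   maturity = "TOTAL")
      fit <- fit_sigmoid(pts, anchor_origin = TRUE)
      oct <- predict_oct(fit, config$target_pct, config$mode)
      if (config$mode == "absolute" && oct$censored == "right") {
        # asymptote below the absolute target: fall back to the normalized
        # criterion so a usable time is still reported (flagged)
        oct <- predict_oct(fit, config$target_pct, "normalized")
        oct$flags <- c(oct$flags, "absolute_unattainable_normalized_used")
      }
      corr <- experimental_vs_predicted(pts, fit)
      list(points = pts, fit = fit, oct = oct, corr = corr)
    })
    sig_fit <- sig$fit; oct <- sig$oct
    report$sigmoid <- list(
      a = sig_fit$a, x0 = sig_fit$x0, b = sig_fit$b, r2 = sig_fit$r2,
      p_value = sig_fit$p_value, target_pct = config$target_pct,
      mode = config$mode, oct = format(oct),
      oct_min = oct$value, obs_vs_fit_r2 = sig$corr$r2,
      points = sig$points)
  }

  if ("anova" %in% config$stages) {
    report$anova <- run_stage("anova", function() {
      long <- do.call(rbind, lapply(trials, function(tr) {
        rd <- tr$readings[tr$readings$status == "intact", , drop = FALSE]
        if (nrow(rd) == 0) return(NULL)
        data.frame(sample = tr$lot_id, cooking_time = tr$cooking_time_min,
                   maturity = tr$maturity,
                   value = rd[[reading_column[[config$parameter]]]])
      }))
      # one factor level only for 'sample' in a single-lot run: collapse to
      # a two-way layout in that case
      if (length(unique(long$sample)) < 2) {
        fit <- stats::aov(value ~ factor(cooking_time) * maturity,
                          data = long)
        tab <- summary(fit)[[1]]
        ss_total <- sum(tab[["Sum Sq"]])
        data.frame(source = trimws(rownames(tab)), df = tab[["Df"]],
                   ss = tab[["Sum Sq"]],
                   eta2 = 100 * tab[["Sum Sq"]] / ss_total,
                   f_stat = tab[["F value"]], p_value = tab[["Pr(>F)"]],
                   stars = significance_stars(tab[["Pr(>F)"]]),
                   stringsAsFactors = FALSE)
      } else {
        anova_texture(long, "value",
                      factors = c("sample", "cooking_time", "maturity"))
      }
    })
  }

  if ("validate" %in% config$stages && !is.null(oct) &&
      !is.na(oct$value) && !is.null(config$generator)) {
    report$validation <- run_stage("validate", function() {
      gen <- config$generator
      gen$rng_seed <- stage_seed(
        if (!is.null(config$rng_seed)) config$rng_seed else gen$rng_seed,
        "validate")
      set.seed(gen$rng_seed)
      vlot <- make_lot(gen)
      vtrials <- list()
      for (m in MATURITY_RAW) for (r in seq_len(gen$n_replicates))
        vtrials[[length(vtrials) + 1L]] <-
          simulate_trial(vlot, m, oct$value, gen, replicate = r)
      v <- validate_oct(vtrials, threshold = threshold,
                        parameter = config$parameter)
      list(applied_time = v$applied_time, pct_cooked = v$pct_cooked,
           weighted_mean = v$weighted_mean, pass = v$pass)
    })
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(unclass(report), file.path(config$out_dir, "report.json"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("octlens pipeline report\n")
  if (!is.null(x$composition))
    cat(sprintf("  lot %s: MB/IMG ratio %.1f, 1000-seed mass %.2f g\n",
                x$composition$lot_id, x$composition$ratio_mb_img,
                x$composition$tsm_whole_g))
  if (!is.null(x$calibration))
    cat(sprintf("  threshold: %s %.3g\n", x$calibration$parameter,
                x$calibration$threshold_adopted))
  if (!is.null(x$sigmoid))
    cat(sprintf(
      "  sigmoid: a=%.2f x0=%.2f b=%.2f r2=%.4f -> OCT %s (target %g%%, %s)\n",
      x$sigmoid$a, x$sigmoid$x0, x$sigmoid$b, x$sigmoid$r2, x$sigmoid$oct,
      x$sigmoid$target_pct, x$sigmoid$mode))
  if (!is.null(x$validation))
    cat(sprintf("  validation at %.1f min: %.1f%% cooked, weighted %.3g: %s\n",
                x$validation$applied_time, x$validation$pct_cooked,
                x$validation$weighted_mean,
                if (x$validation$pass) "PASS" else "FAIL"))
  invisible(x)
}
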