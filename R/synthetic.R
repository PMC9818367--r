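# Synthetic cooking-experiment generator.
#
# Emulates the statistical structure the analysis assumes: a lot is a mixture
# of mature-brown (MB) and immature-green (IMG) seeds; per-seed penetration
# force decays exponentially with cooking time towards a plateau; seeds
# overcook (torn coat, mashed cotyledon) under a delayed-onset exponential
# hazard that acts faster on MB seeds; subsamples take up water towards a
# saturating asymptote; panel doneness scores are a noisy decreasing linear
# function of force, reported on a 0.5-granular 1-9 scale.

#' Generator configuration
#'
#' Defaults describe a short-cooking-time ("SCT"-like) lot: maturity mix and
#' category 1000-seed masses from the SCT lot characterization, intact-seed
#' APF decay from the SCT average-APF exponential fits (converted to newtons),
#' overcook hazards giving roughly 40% overcooked seeds at 60 min with MB
#' overcooking faster than IMG, and water uptake that doubles subsample mass
#' within the first 20 min and saturates by about 40 min. The sensory link
#' slope is -3.125 score/N so that a doneness score of 6.5 inverts at 0.80 N.
#'
#' @param rng_seed Integer seed; mandatory for reproducible experiments.
#' @param lot_type `"SCT"` or `"LCT"` preset (LCT swaps in the long-cooking
#'   composition and decay parameters).
#' @param cat_mix Named probabilities (MB, IMG) of seed-count composition.
#' @param tsm_by_cat_g Named 1000-seed masses (g).
#' @param subsample_mass_g Mass of one cooked subsample (g).
#' @param cooking_times_min Experimental cooking-time grid (min).
#' @param n_replicates Replicate subsamples per maturity x time cell.
#' @param decay_params List per category of `c(y0, a, k)`: per-seed intact APF
#'   at time t is `y0 + a*exp(-k*t)` (N, N, 1/min) plus measurement noise.
#' @param reading_noise_sd Per-seed APF noise sd (N), constant over time.
#' @param noise_cv Optional amplitude-tracking noise component (default 0):
#'   when positive, the per-seed sd becomes
#'   `noise_cv * a * exp(-k*t) + reading_noise_sd`, emulating dispersion that
#'   shrinks as seeds soften. Off by default because the decay parameters
#'   describe the 20-60 min window only and amplitude-scaled noise
#'   extrapolated to t = 0 would let uncooked seeds read below the doneness
#'   threshold, contradicting the origin-anchored cooked-fraction model.
#' @param overcook_hazard List per category of `c(t0, rate)`: a seed is
#'   overcooked by time t with probability `1 - exp(-rate*max(0, t - t0))`.
#' @param uptake_params `c(u, r)`: cooked mass is
#'   `initial * (1 + u*(1 - exp(-r*t)))`.
#' @param sensory_link `c(intercept, slope, noise_sd)` of the score-on-APF
#'   line; slope must be negative (harder seed, lower doneness).
#' @param n_panelists Panelists emulated per sensory record (scores averaged).
#' @param n_measured_per_cat Seeds measured on the texture analyzer per trial.
#' @param aapf_scale,gapf_scale Scale factors generating AAPF (N·s) and GAPF
#'   (N·s⁻¹) as weakly noised multiples of APF.
#' @param relative_noise Relative sd of the AAPF/GAPF multiplicative noise.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(rng_seed = 1L,
                             lot_type = c("SCT", "LCT"),
                             cat_mix = NULL,
                             tsm_by_cat_g = NULL,
                             subsample_mass_g = 10,
                             cooking_times_min = c(20, 30, 40, 50, 60),
                             n_replicates = 3L,
                             decay_params = NULL,
                             reading_noise_sd = 0.15,
                             noise_cv = 0,
                             overcook_hazard = NULL,
                             uptake_params = c(u = 1.0, r = 0.08),
                             sensory_link = c(intercept = 9, slope = -3.125,
                                              noise_sd = 0.3),
                             n_panelists = 5L,
                             n_measured_per_cat = 15L,
                             aapf_scale = 5.5,
                             gapf_scale = 0.1,
                             relative_noise = 0.05) {
  lot_type <- match.arg(lot_type)
  if (is.null(cat_mix))
    cat_mix <- if (lot_type == "SCT") c(MB = 0.476, IMG = 0.524)
               else c(MB = 0.750, IMG = 0.250)
  if (is.null(tsm_by_cat_g))
    tsm_by_cat_g <- if (lot_type == "SCT") c(MB = 33.35, IMG = 16.65)
                    else c(MB = 33.64, IMG = 35.49)
  if (is.null(decay_params))
    decay_params <- if (lot_type == "SCT")
      list(MB = c(y0 = 0.097, a = 1.100, k = 0.023),
           IMG = c(y0 = 0.385, a = 1.668, k = 0.044))
    else
      list(MB = c(y0 = 0.100, a = 2.440, k = 0.029),
           IMG = c(y0 = 0.478, a = 3.132, k = 0.049))
  if (is.null(overcook_hazard))
    overcook_hazard <- if (lot_type == "SCT")
      list(MB = c(t0 = 10, rate = 0.013), IMG = c(t0 = 15, rate = 0.008))
    else
      list(MB = c(t0 = 15, rate = 0.009), IMG = c(t0 = 20, rate = 0.005))
  cfg <- structure(
    list(rng_seed = as.integer(rng_seed), lot_type = lot_type,
         cat_mix = cat_mix, tsm_by_cat_g = tsm_by_cat_g,
         subsample_mass_g = subsample_mass_g,
         cooking_times_min = cooking_times_min,
         n_replicates = as.integer(n_replicates),
         decay_params = decay_params,
         noise_cv = noise_cv,
         reading_noise_sd = reading_noise_sd,
         overcook_hazard = overcook_hazard,
         uptake_params = uptake_params,
         sensory_link = sensory_link,
         n_panelists = as.integer(n_panelists),
         n_measured_per_cat = as.integer(n_measured_per_cat),
         aapf_scale = aapf_scale, gapf_scale = gapf_scale,
         relative_noise = relative_noise),
    class = "generator_config")
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  mix <- cfg$cat_mix[MATURITY_RAW]
  if (anyNA(mix)) stop("cat_mix must be named with MB and IMG")
  if (all(mix == 0)) stop("cat_mix cannot be all zero")
  if (abs(sum(mix) - 1) > 1e-8) stop("cat_mix probabilities must sum to 1")
  for (cat in MATURITY_RAW) {
    dp <- cfg$decay_params[[cat]]
    if (dp[["k"]] <= 0) stop("decay rate k must be > 0 for ", cat)
    if (dp[["y0"]] < 0) stop("decay plateau y0 must be >= 0 for ", cat)
  }
  if (cfg$reading_noise_sd < 0) stop("reading_noise_sd must be >= 0")
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0")
  if (cfg$sensory_link[["noise_sd"]] < 0) stop("sensory noise sd must be >= 0")
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cooking-experiment configuration (", x$lot_type,
      "-like preset)\n", sep = "")
  cat(sprintf("  mix MB/IMG: %.1f%%/%.1f%%; times: %s min; %d replicate(s)\n",
              100 * x$cat_mix[["MB"]], 100 * x$cat_mix[["IMG"]],
              paste(x$cooking_times_min, collapse = ","), x$n_replicates))
  invisible(x)
}

#' Draw a seed lot from the generator configuration
#'
#' The whole-lot 1000-seed mass is the exact count-percentage-weighted mean of
#' the category masses.
#'
#' @param config A [generator_config()].
#' @param lot_id Identifier for the generated lot.
#' @return A [seed_lot()].
#' @export
make_lot <- function(config, lot_id = paste0("SYN-", config$lot_type)) {
  pct <- 100 * config$cat_mix[MATURITY_RAW]
  tsm_cat <- config$tsm_by_cat_g[MATURITY_RAW]
  tsm_whole <- sum(pct / 100 * tsm_cat)
  seed_lot(lot_id,
           origin_class = if (config$lot_type %in% c("SCT", "LCT"))
             config$lot_type else "OTHER",
           tsm_whole_g = tsm_whole, tsm_by_cat_g = tsm_cat,
           cat_percent = pct, moisture_percent = 13)
}

# Per-category seed count of one subsample: the subsample holds
# subsample_mass / tsm_whole * 1000 seeds, split by count percentage.
seeds_in_subsample <- function(lot, config, maturity) {
  n_total <- config$subsample_mass_g / lot$tsm_whole_g * 1000
  as.integer(round(n_total * lot$cat_percent[[maturity]] / 100))
}

#' Simulate one cooking trial
#'
#' Cooks one maturity subsample for `t` minutes: draws per-seed overcooking
#' from the delayed-onset hazard, per-seed APF from the exponential decay plus
#' Gaussian noise (floored at 0; overcooked seeds are drawn uniformly near 0),
#' derives AAPF/GAPF as scaled noised multiples, and applies saturating water
#' uptake to the subsample mass. Only `n_measured_per_cat` intact seeds (and
#' up to 5 overcooked ones) receive texture readings, as on a real analyzer.
#'
#' @param lot A [seed_lot()].
#' @param maturity `"MB"` or `"IMG"`.
#' @param t Cooking time (min, >= 0).
#' @param config A [generator_config()].
#' @param replicate Replicate index (recorded in seed ids only).
#' @return A [cooking_trial()].
#' @export
simulate_trial <- function(lot, maturity, t, config, replicate = 1L) {
  maturity <- match.arg(maturity, MATURITY_RAW)
  stopifnot(t >= 0)
  n_seeds <- seeds_in_subsample(lot, config, maturity)
  dp <- config$decay_params[[maturity]]
  hz <- config$overcook_hazard[[maturity]]
  p_over <- 1 - exp(-hz[["rate"]] * max(0, t - hz[["t0"]]))
  overcooked <- stats::runif(n_seeds) < p_over
  n_over <- sum(overcooked)

  amp <- dp[["a"]] * exp(-dp[["k"]] * t)
  mean_apf <- dp[["y0"]] + amp
  sd_apf <- config$noise_cv * amp + config$reading_noise_sd
  # measured seeds: sample up to n_measured intact + up to 5 overcooked
  n_int_meas <- min(config$n_measured_per_cat, n_seeds - n_over)
  n_ovr_meas <- min(5L, n_over)
  apf_int <- pmax(0, mean_apf + stats::rnorm(n_int_meas, 0, sd_apf))
  apf_ovr <- stats::runif(n_ovr_meas, 0, 0.1 * 0.80) # near-zero resistance
  apf <- c(apf_int, apf_ovr)
  status <- c(rep("intact", n_int_meas), rep("overcooked", n_ovr_meas))
  rel <- config$relative_noise
  aapf <- apf * config$aapf_scale * (1 + stats::rnorm(length(apf), 0, rel))
  gapf <- apf * config$gapf_scale * (1 + stats::rnorm(length(apf), 0, rel))
  readings <- data.frame(
    seed_id = sprintf("%s-%s-t%g-r%d-s%02d", lot$lot_id, maturity, t,
                      replicate, seq_along(apf)),
    status = status, apf = apf, aapf = pmax(0, aapf), gapf = pmax(0, gapf),
    stringsAsFactors = FALSE)

  initial_mass <- n_seeds * lot$tsm_by_cat_g[[maturity]] / 1000
  up <- config$uptake_params
  cooked_mass <- initial_mass * (1 + up[["u"]] * (1 - exp(-up[["r"]] * t)))
  cooking_trial(lot$lot_id, maturity, t, initial_mass, cooked_mass,
                n_seeds, n_over, readings = readings, replicate = replicate)
}

#' Simulate panel sensory records for a trial
#'
#' Each measured intact seed is scored by an emulated panel: per-panelist
#' score = clip(intercept + slope * APF + noise, 1, 9); the panel mean is
#' rounded to the 0.5 granularity of the scale. Tactile and chewiness draws
#' are independent.
#'
#' @param trial A [cooking_trial()] with intact readings.
#' @param config A [generator_config()].
#' @return Data frame in the `sensory.csv` schema (forces in N).
#' @export
simulate_sensory <- function(trial, config) {
  rd <- trial$readings[trial$readings$status == "intact", , drop = FALSE]
  if (nrow(rd) == 0) stop("trial has no intact readings")
  link <- config$sensory_link
  panel_score <- function(apf) {
    raw <- link[["intercept"]] + link[["slope"]] * apf
    per <- pmin(9, pmax(1, raw +
      stats::rnorm(length(apf) * config$n_panelists, 0,
                   link[["noise_sd"]])))
    m <- rowMeans(matrix(per, nrow = length(apf)))
    pmin(9, pmax(1, round(m * 2) / 2))
  }
  data.frame(
    lot_id = trial$lot_id, seed_id = rd$seed_id, panelist_id = "panel-mean",
    tactile_score = panel_score(rd$apf),
    chewiness_score = panel_score(rd$apf),
    apf_N = rd$apf, aapf_Ns = rd$aapf, gapf_Nps = rd$gapf,
    stringsAsFactors = FALSE)
}

#' Simulate a complete cooking experiment
#'
#' Generates a lot, all maturity x time x replicate trials, and paired sensory
#' records (by default only at the screening time closest to 27 min, as in a
#' calibration screening), seeding the RNG once from `config$rng_seed` so that
#' identical configurations reproduce identical experiments.
#'
#' @param config A [generator_config()].
#' @param sensory_times Cooking times at which sensory records are generated;
#'   default the experimental grid (pooled calibration).
#' @return A list with elements `lot`, `trials` (list of [cooking_trial()])
#'   and `sensory` (data frame).
#' @export
simulate_experiment <- function(config,
                                sensory_times = config$cooking_times_min) {
  set.seed(config$rng_seed)
  lot <- make_lot(config)
  trials <- list()
  sensory <- list()
  for (t in config$cooking_times_min) {
    for (m in MATURITY_RAW) {
      if (config$cat_mix[[m]] == 0) next
      for (r in seq_len(config$n_replicates)) {
        tr <- simulate_trial(lot, m, t, config, replicate = r)
        trials[[length(trials) + 1L]] <- tr
        if (t %in% sensory_times && nrow(tr$readings) > 0)
          sensory[[length(sensory) + 1L]] <- simulate_sensory(tr, config)
      }
    }
  }
  list(lot = lot, trials = trials,
       sensory = if (length(sensory)) do.call(rbind, sensory) else NULL)
}

#' Write a simulated experiment to the four CSV schemas
#'
#' @param experiment Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment_csv <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lot <- experiment$lot
  lots <- data.frame(
    lot_id = lot$lot_id, origin_class = lot$origin_class,
    tsm_whole_g = lot$tsm_whole_g,
    tsm_mb_g = lot$tsm_by_cat_g[["MB"]], tsm_img_g = lot$tsm_by_cat_g[["IMG"]],
    pct_mb = lot$cat_percent[["MB"]], pct_img = lot$cat_percent[["IMG"]],
    L = lot$color_L, a = lot$color_a, b = lot$color_b,
    moisture_pct = lot$moisture_percent)
  trials <- do.call(rbind, lapply(experiment$trials, function(tr)
    data.frame(lot_id = tr$lot_id, maturity = tr$maturity,
               cooking_time_min = tr$cooking_time_min, replicate = tr$replicate,
               initial_mass_g = tr$initial_mass_g,
               cooked_mass_g = tr$cooked_mass_g,
               n_seeds_initial = tr$n_seeds_initial,
               n_overcooked = tr$n_overcooked)))
  readings <- do.call(rbind, lapply(experiment$trials, function(tr) {
    if (nrow(tr$readings) == 0) return(NULL)
    data.frame(lot_id = tr$lot_id, origin_class = lot$origin_class,
               maturity = tr$maturity, cooking_time_min = tr$cooking_time_min,
               replicate = tr$replicate,
               seed_id = tr$readings$seed_id, status = tr$readings$status,
               apf_N = tr$readings$apf, aapf_Ns = tr$readings$aapf,
               gapf_Nps = tr$readings$gapf)
  }))
  paths <- file.path(dir, c("lots.csv", "trials.csv", "readings.csv",
                            "sensory.csv"))
  utils::write.csv(lots, paths[1], row.names = FALSE)
  utils::write.csv(trials, paths[2], row.names = FALSE)
  utils::write.csv(readings, paths[3], row.names = FALSE)
  if (!is.null(experiment$sensory))
    utils::write.csv(experiment$sensory, paths[4], row.names = FALSE)
  invisible(paths)
}
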