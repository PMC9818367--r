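# Synthetic cooking-experiment generator: identities, closed forms,
# determinism and the qualitative maturity contrasts the analysis assumes.

test_that("whole-lot 1000-seed mass is the mix-weighted category mean", {
  cfg <- generator_config(rng_seed = 1, cat_mix = c(MB = 0.75, IMG = 0.25),
                          tsm_by_cat_g = c(MB = 33.64, IMG = 35.49))
  lot <- make_lot(cfg)
  expect_equal(lot$tsm_whole_g, 0.75 * 33.64 + 0.25 * 35.49)
  expect_equal(round(lot$tsm_whole_g, 1), 34.1)
  # degenerate mix: single category
  cfg1 <- generator_config(rng_seed = 1, cat_mix = c(MB = 1, IMG = 0),
                           tsm_by_cat_g = c(MB = 33.64, IMG = 35.49))
  expect_equal(make_lot(cfg1)$tsm_whole_g, 33.64)
  expect_error(generator_config(rng_seed = 1, cat_mix = c(MB = 0, IMG = 0)),
               "sum to 1|all zero")
})

test_that("noiseless intact APF equals the decay curve exactly", {
  cfg <- generator_config(
    rng_seed = 5, reading_noise_sd = 0,
    decay_params = list(MB = c(y0 = 0.2, a = 1.0, k = 0.05),
                        IMG = c(y0 = 0.2, a = 1.0, k = 0.05)),
    overcook_hazard = list(MB = c(t0 = 1e6, rate = 0), # hazard never starts
                           IMG = c(t0 = 1e6, rate = 0)))
  lot <- make_lot(cfg)
  set.seed(1)
  tr <- simulate_trial(lot, "MB", 20, cfg)
  expect_equal(unique(tr$readings$apf), 0.2 + 1.0 * exp(-1),
               tolerance = 1e-12)
  expect_equal(unique(tr$readings$apf), 0.5679, tolerance = 1e-4)
  expect_equal(tr$n_overcooked, 0L)
})

test_that("noiseless generated series refits to the generating parameters", {
  cfg <- generator_config(
    rng_seed = 5, reading_noise_sd = 0,
    decay_params = list(MB = c(y0 = 0.15, a = 1.2, k = 0.035),
                        IMG = c(y0 = 0.15, a = 1.2, k = 0.035)),
    overcook_hazard = list(MB = c(t0 = 1e6, rate = 0),
                           IMG = c(t0 = 1e6, rate = 0)))
  lot <- make_lot(cfg)
  set.seed(1)
  means <- vapply(cfg$cooking_times_min, function(t)
    mean(simulate_trial(lot, "MB", t, cfg)$readings$apf), 0)
  fit <- fit_decay(cfg$cooking_times_min, means)
  expect_equal(coef(fit), c(y0 = 0.15, a = 1.2, k = 0.035),
               tolerance = 1e-6)
})

test_that("hazard before onset yields no overcooked seeds, and MB overcooks
           faster than IMG beyond onset", {
  cfg <- generator_config(rng_seed = 11)
  lot <- make_lot(cfg)
  set.seed(2)
  tr0 <- simulate_trial(lot, "MB", 0, cfg)
  expect_equal(tr0$n_overcooked, 0L)
  # expectation check with many seeds: pool replicates at each time
  big <- generator_config(rng_seed = 11, subsample_mass_g = 50)
  biglot <- make_lot(big)
  set.seed(3)
  for (t in c(30, 60)) {
    mb <- simulate_trial(biglot, "MB", t, big)
    img <- simulate_trial(biglot, "IMG", t, big)
    expect_gt(overcooked_percent(mb), overcooked_percent(img))
  }
  # overcooked fraction non-decreasing in t (in expectation, n >= 500)
  set.seed(4)
  oc <- vapply(c(20, 30, 40, 50, 60), function(t)
    overcooked_percent(simulate_trial(biglot, "MB", t, big)), 0)
  expect_true(all(diff(oc) > -3)) # monotone up to binomial noise
  expect_gt(oc[5], oc[1])
})

test_that("water uptake is monotone, saturating and below the asymptote", {
  cfg <- generator_config(rng_seed = 1)
  lot <- make_lot(cfg)
  set.seed(1)
  masses <- vapply(c(0, 10, 20, 40, 80, 160), function(t) {
    tr <- simulate_trial(lot, "MB", t, cfg)
    tr$cooked_mass_g / tr$initial_mass_g
  }, 0)
  expect_true(all(diff(masses) > 0))
  u <- cfg$uptake_params[["u"]]
  expect_true(all(masses < 1 + u))
  # most of the uptake happens in the first 20 min (seeds roughly double)
  expect_gt(masses[3], 1 + 0.75 * u)
})

test_that("identical seeds give byte-identical experiment CSVs", {
  cfg <- generator_config(rng_seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_experiment_csv(simulate_experiment(cfg), d1)
  write_experiment_csv(simulate_experiment(cfg), d2)
  for (f in c("lots.csv", "trials.csv", "readings.csv", "sensory.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed perturbs the readings
  write_experiment_csv(simulate_experiment(generator_config(rng_seed = 78)),
                       d2)
  expect_false(identical(readLines(file.path(d1, "readings.csv")),
                         readLines(file.path(d2, "readings.csv"))))
})

test_that("sensory link inverts the threshold and clips at the scale ends", {
  cfg <- generator_config(rng_seed = 1,
                          sensory_link = c(intercept = 9, slope = -3.125,
                                           noise_sd = 0))
  tr <- make_trial(c(0.80, 0.80, 0))
  set.seed(1)
  sens <- simulate_sensory(tr, cfg)
  # 9 - 3.125 * 0.80 = 6.5 exactly on the 0.5-granular scale
  expect_equal(sens$tactile_score[1:2], c(6.5, 6.5))
  # equal APF, zero noise -> equal scores; APF 0 clips at 9
  expect_equal(sens$chewiness_score[1], sens$chewiness_score[2])
  expect_equal(sens$tactile_score[3], 9)
  expect_true(all(sens$tactile_score >= 1 & sens$tactile_score <= 9))
})
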