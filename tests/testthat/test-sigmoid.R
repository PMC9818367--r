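# Cooked-seed fraction, sigmoid fitting, OCT prediction and validation.

test_that("cooked fraction scales measured readings to whole-subsample
           counts and counts overcooked seeds as cooked", {
  apf <- c(runif(12, 0.1, 0.7), runif(3, 0.9, 1.3)) # 12 of 15 within
  tr <- make_trial(apf, n_seeds = 200, n_over = 40)
  pt <- cooked_fraction(tr, "APF", threshold = 0.8)
  expect_equal(pt$pct_cooked, 100 * (0.8 * 160 + 40) / 200)
  expect_equal(pt$pct_cooked, 84)
  # all readings within and every seed within or overcooked -> 100%
  all_in <- make_trial(runif(15, 0.1, 0.7), n_seeds = 200, n_over = 40)
  expect_equal(cooked_fraction(all_in, "APF", 0.8)$pct_cooked, 100)
  # nothing within, nothing overcooked -> 0%
  none <- make_trial(runif(15, 0.9, 1.3), n_seeds = 200, n_over = 0)
  expect_equal(cooked_fraction(none, "APF", 0.8)$pct_cooked, 0)
  expect_error(cooked_fraction(none, "APF", 0), "threshold")
  # non-decreasing in threshold
  ths <- seq(0.2, 1.4, 0.1)
  pcts <- vapply(ths, function(h)
    cooked_fraction(tr, "APF", h)$pct_cooked, 0)
  expect_true(all(diff(pcts) >= 0))
})

test_that("noiseless logistic points are recovered to machine accuracy", {
  t <- c(0, 20, 30, 40, 50, 60)
  y <- 100 / (1 + exp(-(t - 30) / 8))
  fit <- fit_sigmoid(data.frame(cooking_time = t, pct_cooked = y),
                     anchor_origin = FALSE)
  expect_equal(coef(fit), c(a = 100, x0 = 30, b = 8), tolerance = 1e-6)
  expect_gte(fit$r2, 1 - 1e-9)
  # a flat series is degenerate
  expect_error(fit_sigmoid(data.frame(cooking_time = t,
                                      pct_cooked = rep(100, 6)),
                           anchor_origin = FALSE),
               "degenerate")
})

test_that("OCT prediction matches the analytic sigmoid inversion", {
  mk <- function(a, x0, b) {
    t <- c(0, 15, 25, 35, 50, 70)
    fit_sigmoid(data.frame(cooking_time = t,
                           pct_cooked = a / (1 + exp(-(t - x0) / b))),
                anchor_origin = FALSE)
  }
  # at the inflection both modes agree when a = 100
  f <- mk(100, 20, 5)
  expect_equal(predict_oct(f, 50, "absolute")$value, 20, tolerance = 1e-6)
  expect_equal(predict_oct(f, 50, "normalized")$value, 20, tolerance = 1e-6)
  # published SCT-total sigmoid parameters under the absolute criterion
  f2 <- mk(103.5, 21.9, 9.4)
  expect_equal(predict_oct(f2, 99, "absolute")$value,
               21.9 + 9.4 * log(99 / (103.5 - 99)), tolerance = 1e-6)
  expect_equal(predict_oct(f2, 99, "absolute")$value, 50.96,
               tolerance = 1e-2)
  # published LCT-total parameters under the normalized 80% criterion
  f3 <- mk(100.27, 44.5, 7.5)
  expect_equal(predict_oct(f3, 80, "normalized")$value,
               44.5 + 7.5 * log(4), tolerance = 1e-6)
  expect_equal(predict_oct(f3, 80, "normalized")$value, 54.90,
               tolerance = 1e-2)
  # a target at or above the asymptote is censored, not an exception
  f4 <- mk(98, 25, 6)
  est <- predict_oct(f4, 99, "absolute")
  expect_equal(est$censored, "right")
})

test_that("predicted OCT is strictly increasing in the target percentage", {
  set.seed(5)
  for (i in 1:25) {
    a <- runif(1, 95, 110); x0 <- runif(1, 15, 45); b <- runif(1, 4, 12)
    t <- c(0, 15, 25, 35, 50, 70)
    fit <- fit_sigmoid(data.frame(
      cooking_time = t, pct_cooked = a / (1 + exp(-(t - x0) / b))),
      anchor_origin = FALSE)
    targets <- c(50, 80, 90, min(99, fit$a - 1))
    for (mode in c("absolute", "normalized")) {
      oct <- vapply(targets, function(tp)
        predict_oct(fit, tp, mode)$value, 0)
      expect_true(all(diff(oct) > 0))
    }
    # absolute is later than normalized whenever the asymptote is below 100
    if (fit$a < 100) {
      tp <- min(95, fit$a - 2)
      expect_gte(predict_oct(fit, tp, "absolute")$value,
                 predict_oct(fit, tp, "normalized")$value)
    }
  }
})

test_that("observed-vs-fitted correlation matches the fit diagnostics", {
  t <- c(0, 20, 30, 40, 50, 60)
  y <- 100 / (1 + exp(-(t - 30) / 8))
  pts <- data.frame(cooking_time = t, pct_cooked = y)
  fit <- fit_sigmoid(pts, anchor_origin = FALSE)
  expect_equal(experimental_vs_predicted(pts, fit)$r, 1, tolerance = 1e-6)
  # noisy case: squared correlation tracks the fit's r2
  set.seed(8)
  pts$pct_cooked <- pmax(0, y + rnorm(6, 0, 3))
  fit <- fit_sigmoid(pts, anchor_origin = FALSE)
  expect_equal(experimental_vs_predicted(pts, fit)$r2, fit$r2,
               tolerance = 0.02)
  # shuffling the observations destroys the correlation on average
  set.seed(9)
  rs <- replicate(200, {
    sh <- pts
    sh$pct_cooked <- sample(sh$pct_cooked)
    experimental_vs_predicted(sh, fit)$r
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("validation echoes the reference cookings and applies the pass
           rule", {
  val <- load_fixture("validation")
  for (i in seq_len(nrow(val))) {
    row <- val[i, ]
    # reconstruct a trial whose summaries reproduce the reported numbers:
    # weighted APF with no overcooked seeds collapses to the intact mean
    n_meas <- 30
    tr <- cooking_trial(row$sample, "MB", row$applied_ct_min, 10, 20,
                        200, 0,
                        readings = data.frame(
                          seed_id = paste0("v", 1:n_meas), status = "intact",
                          apf = rep(row$apf_weighted_N, n_meas),
                          aapf = rep(row$apf_weighted_N * 5.5, n_meas),
                          gapf = rep(row$apf_weighted_N * 0.1, n_meas)))
    # cooked percentage as reported: patch counts so the scaled fraction
    # reproduces the published percentage
    n_within <- round(row$pct_cooked / 100 * n_meas)
    tr$readings$apf[seq_len(n_meas - n_within)] <- 0.85
    tr$readings$apf[(n_meas - n_within + 1):n_meas] <- row$apf_weighted_N
    v <- validate_oct(list(tr), threshold = 0.80, parameter = "APF",
                      min_pct_cooked = 95)
    expect_equal(v$pct_cooked, 100 * n_within / n_meas, tolerance = 0.1)
    expect_lte(abs(v$pct_cooked - row$pct_cooked), 2)
    expect_lte(v$weighted_mean, 0.80)
    expect_true(v$pass)
  }
})

test_that("a lot cooked at its predicted OCT passes validation and at half
           that time fails", {
  cfg <- generator_config(rng_seed = 1)
  ex <- simulate_experiment(cfg)
  pts <- cooked_fraction_curve(ex$trials, "APF", 0.80, "TOTAL")
  fit <- fit_sigmoid(pts)
  oct <- predict_oct(fit, 99, "absolute")
  if (oct$censored == "right") oct <- predict_oct(fit, 99, "normalized")
  cook_at <- function(t_apply) {
    set.seed(101)
    lot <- make_lot(cfg)
    trs <- list()
    for (m in c("MB", "IMG")) for (r in 1:3)
      trs[[length(trs) + 1]] <- simulate_trial(lot, m, t_apply, cfg, r)
    validate_oct(trs, threshold = 0.80, parameter = "APF")
  }
  expect_true(cook_at(oct$value)$pass)
  expect_false(cook_at(oct$value / 2)$pass)
})
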