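# Trial-level descriptives: uptake, overcooking, composition, weighted means.

test_that("mass increase and overcooked percentages are plain ratios", {
  expect_equal(mass_increase_percent(make_trial(0.5, initial = 10,
                                                cooked = 20)), 100)
  expect_equal(mass_increase_percent(make_trial(0.5, initial = 10,
                                                cooked = 10)), 0)
  expect_equal(mass_increase_percent(make_trial(0.5, initial = 8,
                                                cooked = 14)), 75)
  expect_equal(overcooked_percent(make_trial(0.5, n_seeds = 200,
                                             n_over = 0)), 0)
  expect_equal(overcooked_percent(make_trial(0.5, n_seeds = 200,
                                             n_over = 80)), 40)
  expect_equal(overcooked_percent(make_trial(0.5, n_seeds = 200,
                                             n_over = 50)), 25)
  # scale-free: doubling masses and counts changes nothing
  expect_equal(mass_increase_percent(make_trial(0.5, initial = 16,
                                                cooked = 28)), 75)
  expect_equal(overcooked_percent(make_trial(0.5, n_seeds = 400,
                                             n_over = 100)), 25)
})

test_that("composition ratio reproduces the reference lots", {
  lots <- fixture_lots()
  expect_equal(composition_ratio(lots$LCT), 3.0)
  expect_equal(composition_ratio(lots$SCT), 0.9)
  even <- seed_lot("E", "OTHER", 30, c(MB = 30, IMG = 30),
                   c(MB = 50, IMG = 50))
  expect_equal(composition_ratio(even), 1.0)
  pure <- seed_lot("P", "OTHER", 30, c(MB = 30, IMG = 30),
                   c(MB = 100, IMG = 0))
  expect_identical(composition_ratio(pure), Inf)
  # ratio times pct_img returns pct_mb (to the 1-decimal reporting rounding)
  expect_equal(composition_ratio(lots$LCT) * lots$LCT$cat_percent[["IMG"]],
               lots$LCT$cat_percent[["MB"]], tolerance = 0.05 * 25)
})

test_that("weighted texture mean scales status means by full seed counts", {
  # intact mean 0.9 (100 seeds), overcooked mean 0.05 (100 seeds) -> 0.475
  tr <- make_trial(c(rep(0.9, 10), rep(0.05, 5)),
                   status = c(rep("intact", 10), rep("overcooked", 5)),
                   n_seeds = 200, n_over = 100)
  s <- texture_summary(tr, "APF")
  expect_equal(s$mean_weighted, (0.9 * 100 + 0.05 * 100) / 200)
  expect_equal(s$mean_plain, mean(c(rep(0.9, 10), rep(0.05, 5))))
  expect_false(s$imputed)
  # no overcooked seeds: weighted equals the intact mean
  s0 <- texture_summary(make_trial(rep(0.9, 10)), "APF")
  expect_equal(s0$mean_weighted, 0.9)
  # counted-but-unmeasured overcooked seeds impute 0 N and flag it
  tr2 <- make_trial(rep(0.9, 10), n_seeds = 200, n_over = 50)
  s2 <- texture_summary(tr2, "APF")
  expect_true(s2$imputed)
  expect_equal(s2$mean_weighted, 0.9 * 150 / 200)
  expect_error(texture_summary(tr2, "APF", impute_overcooked = FALSE),
               "imputation disabled")
  # no intact readings is an error
  expect_error(texture_summary(
    make_trial(0.02, status = "overcooked", n_over = 10), "APF"),
    "no intact readings")
})

test_that("reference weighted means sit below plain means at every time", {
  df <- load_fixture("texture_means")
  sct_mb <- df[df$sample == "SCT" & df$maturity == "MB" &
                 df$parameter == "APF", ]
  expect_true(all(sct_mb$weighted < sct_mb$average))
})

test_that("TOTAL summaries are count-weighted convex combinations", {
  set.seed(7)
  for (i in 1:20) {
    n_mb <- sample(100:300, 1); n_img <- sample(100:300, 1)
    ov_mb <- sample(0:50, 1); ov_img <- sample(0:50, 1)
    mb <- texture_summary(make_trial(runif(15, 0.2, 1.2), n_seeds = n_mb,
                                     n_over = ov_mb), "APF")
    img <- texture_summary(make_trial(runif(15, 0.2, 1.2), n_seeds = n_img,
                                      n_over = ov_img), "APF")
    tot <- total_summary(mb, img)
    expect_gte(tot$mean_weighted, min(mb$mean_weighted, img$mean_weighted))
    expect_lte(tot$mean_weighted, max(mb$mean_weighted, img$mean_weighted))
    expect_gte(tot$mean_plain, min(mb$mean_plain, img$mean_plain))
    expect_lte(tot$mean_plain, max(mb$mean_plain, img$mean_plain))
  }
  # equal counts, equal status structure: total is the midpoint
  a <- texture_summary(make_trial(rep(0.4, 10), n_seeds = 200), "APF")
  b <- texture_summary(make_trial(rep(0.6, 10), n_seeds = 200), "APF")
  expect_equal(total_summary(a, b)$mean_weighted, 0.5)
  # dominant MB count pulls the total toward the MB mean
  big <- texture_summary(make_trial(rep(0.4, 10), n_seeds = 10000), "APF")
  tot <- total_summary(big, b)
  expect_lt(abs(tot$mean_weighted - 0.4), 0.01)
  # mismatched metadata is refused
  c_other <- texture_summary(make_trial(rep(0.6, 10), t = 40), "APF")
  expect_error(total_summary(a, c_other), "share")
})
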