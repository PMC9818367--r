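# Domain types, unit conversion and CSV round trips.

test_that("force conversion matches the gf definition and round-trips", {
  expect_equal(convert_force(0.80, "N", "gf"), 0.80 * 1000 / 9.80665)
  expect_equal(convert_force(0.80, "N", "gf"), 81.577, tolerance = 1e-4)
  expect_equal(convert_force(0, "N", "gf"), 0)
  expect_equal(convert_force(101.9716, "gf", "N"), 1, tolerance = 1e-5)
  # round-trip identity to 1e-12 relative, linearity, monotonicity
  x <- c(0, 0.37, 0.8, 1.49, 250)
  expect_equal(convert_force(convert_force(x, "N", "gf"), "gf", "N"), x,
               tolerance = 1e-12)
  expect_equal(convert_force(2 * x, "N", "gf"),
               2 * convert_force(x, "N", "gf"))
  expect_true(all(diff(convert_force(x, "N", "gf")) > 0))
  expect_error(convert_force(1, "N", "lbf"))
})

test_that("cooking_trial enforces its invariants", {
  expect_error(make_trial(0.5, cooked = 4),
               "cannot lose mass")
  expect_error(cooking_trial("L", "MB", 20, 10, 12, 100, 101),
               "n_overcooked")
  expect_error(cooking_trial("L", "MB", -1, 10, 12, 100, 0),
               "cooking_time")
  # more overcooked readings than counted overcooked seeds
  expect_error(make_trial(c(0.5, 0.04), status = c("intact", "overcooked"),
                          n_over = 0),
               "overcooked readings")
  # readings must carry all three parameters
  expect_error(
    cooking_trial("L", "MB", 20, 10, 12, 100, 0,
                  readings = data.frame(seed_id = "s1", status = "intact",
                                        apf = 0.5, aapf = NA, gapf = 0.05)),
    "invalid texture reading")
})

test_that("trial reader materializes valid rows and names bad ones", {
  tmp <- withr::local_tempdir()
  trials_csv <- file.path(tmp, "trials.csv")
  df <- data.frame(
    lot_id = "SCT", maturity = "MB",
    cooking_time_min = c(20, 30, 40, 50, 60),
    initial_mass_g = 5, cooked_mass_g = c(9.8, 10.2, 10.4, 10.5, 10.5),
    n_seeds_initial = 200, n_overcooked = c(20, 40, 60, 80, 90))
  write.csv(df, trials_csv, row.names = FALSE)
  trials <- read_trials(trials_csv)
  expect_length(trials, 5)
  expect_s3_class(trials[[1]], "cooking_trial")
  expect_equal(vapply(trials, `[[`, 0, "cooking_time_min"),
               c(20, 30, 40, 50, 60))

  # empty file with valid header -> empty list
  write.csv(df[0, ], trials_csv, row.names = FALSE)
  expect_identical(read_trials(trials_csv), list())

  # invariant violation names the row
  bad <- df
  bad$n_overcooked[3] <- 300
  write.csv(bad, trials_csv, row.names = FALSE)
  expect_error(read_trials(trials_csv), "row 3")

  # missing column -> schema error naming the column
  write.csv(df[, -4], trials_csv, row.names = FALSE)
  expect_error(read_trials(trials_csv), "initial_mass_g")
})

test_that("corrupting one field of a valid readings file is detected", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "readings.csv")
  good <- data.frame(
    lot_id = "SCT", origin_class = "SCT", maturity = "MB",
    cooking_time_min = 20, seed_id = paste0("s", 1:10), status = "intact",
    apf_N = seq(0.3, 1.2, 0.1), aapf_Ns = seq(0.3, 1.2, 0.1) * 5.5,
    gapf_Nps = seq(0.3, 1.2, 0.1) * 0.1)
  corruptions <- list(
    list(col = "status", val = "mushy"),
    list(col = "maturity", val = "TOTAL"),   # aggregate label is not raw data
    list(col = "apf_N", val = -0.2),
    list(col = "gapf_Nps", val = NA),
    list(col = "cooking_time_min", val = -5))
  set.seed(1)
  for (cor in corruptions) {
    df <- good
    row <- sample(nrow(df), 1)
    df[[cor$col]][row] <- cor$val
    write.csv(df, path, row.names = FALSE)
    expect_warning(out <- read_readings(path), "rejected")
    expect_equal(attr(out, "rejected"), row)
    expect_equal(nrow(out), nrow(good) - 1)
  }
  # benign whitespace in a character field is not a corruption
  df <- good
  df$seed_id[2] <- " s2"
  write.csv(df, path, row.names = FALSE)
  expect_silent(out <- read_readings(path))
  expect_equal(nrow(out), nrow(good))
})

test_that("report writing round-trips integers exactly and reals closely", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "report.json")
  results <- list(
    composition = list(lot_id = "SCT", ratio_mb_img = 0.9, n_seeds = 410L),
    decay = data.frame(maturity = c("MB", "IMG"),
                       y0 = c(0.0967341234567891, 0.3851),
                       k = c(0.023, 0.044)))
  paths <- write_report(results, path)
  expect_true(file.exists(path))
  expect_true(any(grepl("decay", paths)))
  back <- read_report(path)
  expect_identical(back$composition$n_seeds, 410L)
  expect_equal(back$composition$ratio_mb_img, 0.9)
  expect_equal(back$decay$y0, results$decay$y0, tolerance = 1e-9)
  # empty results still produce a valid report
  write_report(list(), file.path(tmp, "empty.json"))
  expect_identical(length(read_report(file.path(tmp, "empty.json"))), 0L)
})
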