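# Shared test helpers: a brute-force per-seed cooking oracle independent of
# the analysis pipeline, an exhaustive Duncan-range oracle, and small
# builders for trials and CSV fixtures.

# Brute-force oracle for the time at which `target` of the seeds count as
# cooked (overcooked, or instantaneous APF reading at or below `thr`),
# simulating every seed of the generator's mechanism on a fine time grid.
# Independent of cooked_fraction/fit_sigmoid/predict_oct.
oracle_cooked_time <- function(cfg, thr = 0.8, target = 0.99,
                               n_seeds = 1e4, grid = seq(0, 120, 0.1),
                               seed = 20260101) {
  set.seed(seed)
  mix <- unlist(cfg$cat_mix)
  cats <- sample(names(mix), n_seeds, TRUE, prob = mix)
  t_oc <- numeric(n_seeds)
  for (cat in names(mix)) {
    idx <- which(cats == cat)
    hz <- cfg$overcook_hazard[[cat]]
    t_oc[idx] <- hz[["t0"]] + stats::rexp(length(idx), hz[["rate"]])
  }
  frac <- vapply(grid, function(t) {
    cooked <- t_oc <= t
    for (cat in names(mix)) {
      idx <- which(cats == cat & !cooked)
      if (!length(idx)) next
      dp <- cfg$decay_params[[cat]]
      amp <- dp[["a"]] * exp(-dp[["k"]] * t)
      sd_t <- cfg$noise_cv * amp + cfg$reading_noise_sd
      apf <- pmax(0, dp[["y0"]] + amp + stats::rnorm(length(idx), 0, sd_t))
      cooked[idx] <- apf <= thr
    }
    mean(cooked)
  }, 0)
  sm <- stats::runmed(frac, 21)
  i <- which(sm >= target)[1]
  if (is.na(i)) Inf else grid[i]
}

# Exhaustive Duncan oracle: a range of sorted (descending) means is declared
# non-significant iff SOME containing range (including itself) has
# max - min <= its least significant range; letters are the maximal
# non-significant intervals. Enumerates all ranges directly, independent of
# the step-down recursion in duncan_mrt.
oracle_duncan_letters <- function(means, mse, df_error, n, alpha = 0.05) {
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  lsr <- vapply(2:k, function(p) q_duncan(p, df_error, alpha) *
                  sqrt(mse / n), 0)
  nonsig <- function(i, j) {
    if (i == j) return(TRUE)
    for (a in seq_len(i)) for (b in j:k) {
      span <- b - a + 1
      if (span >= 2 && m[a] - m[b] <= lsr[span - 1]) return(TRUE)
    }
    FALSE
  }
  j_max <- vapply(seq_len(k), function(i) {
    j <- k
    while (j > i && !nonsig(i, j)) j <- j - 1
    as.integer(j)
  }, 0L)
  lab <- character(k)
  last_end <- 0L
  s <- 0L
  for (i in seq_len(k)) {
    if (j_max[i] > last_end) {
      s <- s + 1L
      for (idx in i:j_max[i]) lab[idx] <- paste0(lab[idx], letters[s])
      last_end <- j_max[i]
    }
  }
  stats::setNames(lab, names(m))
}

# quick builder for a cooking trial with given readings
make_trial <- function(apf, status = rep("intact", length(apf)),
                       t = 30, n_seeds = 200, n_over = 0,
                       aapf = apf * 5.5, gapf = apf * 0.1,
                       initial = 5, cooked = 9) {
  cooking_trial("T1", "MB", t, initial, cooked, n_seeds, n_over,
                readings = data.frame(
                  seed_id = paste0("s", seq_along(apf)),
                  status = status, apf = apf, aapf = aapf, gapf = gapf,
                  stringsAsFactors = FALSE))
}

# balanced 2 x 2 x 5 x n factorial frame with the given cell generator
make_factorial <- function(n_rep, cell_fun) {
  grid <- expand.grid(sample = c("S1", "S2"), maturity = c("MB", "IMG"),
                      cooking_time = c(20, 30, 40, 50, 60),
                      rep = seq_len(n_rep), stringsAsFactors = FALSE)
  grid$value <- mapply(cell_fun, grid$sample, grid$maturity,
                       grid$cooking_time)
  grid
}
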