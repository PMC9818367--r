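# Factorial analysis: three-way crossed ANOVA (seed sample x cooking time x
# maturity) with eta-squared effect sizes and significance stars, and
# Duncan's new multiple range test with letter groupings. The design is
# balanced (2 x 2 x 5 with equal replication), where Type I/II/III sums of
# squares coincide; unbalanced input triggers a warning.

#' Significance stars at the conventional thresholds
#' @param p P-value(s).
#' @return `"***"` (p <= 0.001), `"**"` (0.01), `"*"` (0.05) or `"NS"`.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "NS",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "NS"))))
}

#' Three-way factorial ANOVA with eta-squared effect sizes
#'
#' Full-factorial decomposition (three main effects, three two-way and one
#' three-way interaction, residual) of a response over three crossed factors,
#' via `stats::aov`. Effect sizes are reported as
#' `eta2 = 100 * SS_source / SS_total`.
#'
#' @param data Data frame holding the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factors Character vector of the three factor column names, in
#'   reporting order (e.g. seed sample, cooking time, maturity).
#' @return Data frame of class `anova_texture`: one row per source plus
#'   residual, with `df`, `ss`, `eta2`, `f_stat`, `p_value`, `stars`.
#' @export
anova_texture <- function(data, response,
                          factors = c("sample", "cooking_time", "maturity")) {
  stopifnot(length(factors) == 3,
            all(c(response, factors) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  A = factor(data[[factors[1]]]),
                  B = factor(data[[factors[2]]]),
                  C = factor(data[[factors[3]]]))
  d <- d[stats::complete.cases(d), ]
  cell_n <- table(d$A, d$B, d$C)
  if (any(cell_n == 0)) stop("every factor-combination cell needs >= 1 replicate")
  if (any(cell_n < 2))
    stop("three-way interaction untestable with < 2 replicates per cell")
  if (length(unique(as.vector(cell_n))) > 1)
    warning("unbalanced design: SS decomposition is sequential (Type I)")
  fit <- stats::aov(y ~ A * B * C, data = d)
  tab <- summary(fit)[[1]]
  src_map <- c("A" = factors[1], "B" = factors[2], "C" = factors[3],
               "A:B" = paste(factors[1], factors[2], sep = " x "),
               "A:C" = paste(factors[1], factors[3], sep = " x "),
               "B:C" = paste(factors[2], factors[3], sep = " x "),
               "A:B:C" = paste(factors, collapse = " x "),
               "Residuals" = "residual")
  raw <- trimws(rownames(tab))
  ss_total <- sum(tab[["Sum Sq"]])
  out <- data.frame(
    source = unname(src_map[raw]),
    df = tab[["Df"]],
    ss = tab[["Sum Sq"]],
    eta2 = 100 * tab[["Sum Sq"]] / ss_total,
    f_stat = tab[["F value"]],
    p_value = tab[["Pr(>F)"]],
    stringsAsFactors = FALSE)
  out$stars <- ifelse(out$source == "residual", "",
                      significance_stars(out$p_value))
  attr(out, "ss_total") <- ss_total
  attr(out, "mse") <- out$ss[out$source == "residual"] /
    out$df[out$source == "residual"]
  attr(out, "df_error") <- out$df[out$source == "residual"]
  class(out) <- c("anova_texture", class(out))
  out
}

#' @export
print.anova_texture <- function(x, ...) {
  cat("Factorial ANOVA (eta2 = 100 * SS_source / SS_total)\n")
  y <- as.data.frame(x)
  y$ss <- signif(y$ss, 5); y$eta2 <- round(y$eta2, 2)
  y$f_stat <- signif(y$f_stat, 4)
  y$p_value <- signif(y$p_value, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Duncan's critical studentized range
#'
#' The studentized-range quantile at Duncan's protection level: for a span of
#' `p` ordered means the significance level is `1 - (1 - alpha)^(p - 1)`, so
#' the critical value is `qtukey((1 - alpha)^(p - 1), p, df)`.
#'
#' @param p Span (number of ordered means covered), >= 2.
#' @param df Error degrees of freedom.
#' @param alpha Per-comparison significance level (default 0.05).
#' @return Critical studentized range value(s).
#' @export
q_duncan <- function(p, df, alpha = 0.05) {
  stopifnot(all(p >= 2), df >= 1)
  stats::qtukey((1 - alpha)^(p - 1), p, df)
}

#' Duncan's new multiple range test with letter grouping
#'
#' Step-down comparison of sorted group means: the least significant range
#' for a span of `p` means is `q_duncan(p, df_error, alpha) * sqrt(mse / n)`.
#' The full range is tested first; a sub-range is only tested when its parent
#' range was significant (the protection rule), so no sub-range of a
#' non-significant range is ever declared significant. Letters mark maximal
#' stretches of mutually non-separated means.
#'
#' @param means Named numeric vector of group means.
#' @param mse Residual mean square from the ANOVA.
#' @param df_error Error degrees of freedom.
#' @param n_per_group Replicates per group (balanced; unbalanced input is an
#'   error unless `harmonic_fallback = TRUE`, which substitutes the harmonic
#'   mean of the group sizes).
#' @param alpha Significance level (default 0.05).
#' @param harmonic_fallback Allow unbalanced groups via the harmonic-mean n.
#' @return Object of class `duncan_mrt`: sorted means, letters, and the
#'   least-significant-range table.
#' @export
duncan_mrt <- function(means, mse, df_error, n_per_group, alpha = 0.05,
                       harmonic_fallback = FALSE) {
  stopifnot(mse > 0, df_error >= 1, length(means) >= 2)
  if (is.null(names(means))) names(means) <- paste0("g", seq_along(means))
  if (length(n_per_group) > 1) {
    if (length(unique(n_per_group)) > 1) {
      if (!harmonic_fallback)
        stop("unbalanced group sizes; set harmonic_fallback = TRUE to use ",
             "the harmonic-mean n")
      n_per_group <- length(n_per_group) / sum(1 / n_per_group)
    } else n_per_group <- n_per_group[1]
  }
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  se <- sqrt(mse / n_per_group)
  lsr <- vapply(2:k, function(p) q_duncan(p, df_error, alpha) * se, 0)
  names(lsr) <- paste0("span", 2:k)

  # significant[i, j]: means ranked i..j (i < j) are separated. Step-down
  # with protection: a range is tested only if every containing range was
  # significant; here realized top-down by spans.
  sig <- matrix(FALSE, k, k)
  if (k >= 2) {
    for (span in k:2) {
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        # protection: a range may only be declared significant when every
        # containing range was; its immediate parents suffice by induction
        parent_ok <- if (span == k) TRUE else {
          (i == 1 || sig[i - 1, j]) && (j == k || sig[i, j + 1])
        }
        if (!parent_ok) next
        if (m[i] - m[j] > lsr[span - 1]) sig[i, j] <- TRUE
      }
    }
  }
  # Under protection, !sig[i, j] implies !sig[i', j'] for every subrange, so
  # for each i the largest j with a non-significant range is well defined and
  # non-decreasing in i; letters mark the maximal such intervals.
  j_max <- vapply(seq_len(k), function(i) {
    j <- k
    while (j > i && sig[i, j]) j <- j - 1
    as.integer(j)
  }, 0L)
  stretches <- list()
  last_end <- 0L
  for (i in seq_len(k)) {
    if (j_max[i] > last_end || (i > last_end)) {
      stretches[[length(stretches) + 1]] <- c(i, j_max[i])
      last_end <- j_max[i]
    }
  }
  letters_vec <- character(k)
  for (s in seq_along(stretches)) {
    rng <- stretches[[s]]
    lab <- make_letter(s)
    for (idx in rng[1]:rng[2])
      letters_vec[idx] <- paste0(letters_vec[idx], lab)
  }
  structure(
    list(means = m, letters = stats::setNames(letters_vec, names(m)),
         lsr = lsr, alpha = alpha, mse = mse, df_error = df_error,
         n_per_group = n_per_group, significant = sig),
    class = "duncan_mrt")
}

make_letter <- function(i) {
  # a, b, ..., z, aa, ab, ... for pathological numbers of groups
  out <- ""
  i <- i - 1
  repeat {
    out <- paste0(letters[i %% 26 + 1], out)
    i <- i %/% 26 - 1
    if (i < 0) break
  }
  out
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g)\n", x$alpha))
  print(data.frame(mean = signif(x$means, 5), group = x$letters))
  invisible(x)
}
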