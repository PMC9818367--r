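# Domain types and table I/O shared by all pipeline stages.
#
# Conventions: the canonical internal force unit is the newton; cooking time is
# a non-negative real in minutes; maturity categories are "MB" (mature brown)
# and "IMG" (immature green), with "TOTAL" reserved for reporting aggregates
# and never accepted as a raw-data label.

MATURITY_RAW <- c("MB", "IMG")
MATURITY_ALL <- c("MB", "IMG", "TOTAL")

GF_PER_N <- 1000 / 9.80665 # grams-force per newton

#' Texture-analyzer parameters
#'
#' The three scalar parameters extracted from a needle-penetration curve:
#' absolute positive force (APF, N), area to absolute positive force
#' (AAPF, N·s) and gradient to absolute positive force (GAPF, N·s⁻¹).
#'
#' @return A data frame with columns `code` and `unit`.
#' @export
texture_parameters <- function() {
  data.frame(
    code = c("APF", "AAPF", "GAPF"),
    unit = c("N", "N.s", "N/s"),
    stringsAsFactors = FALSE
  )
}

match_parameter <- function(parameter) {
  match.arg(toupper(parameter), texture_parameters()$code)
}

#' Convert between newtons and grams-force
#'
#' Texture-analyzer forces are sometimes reported in grams-force; all internal
#' computation uses newtons (1 N = 1000/9.80665 ≈ 101.97 gf).
#'
#' @param value Non-negative force magnitude(s).
#' @param from,to Unit codes, `"N"` or `"gf"`.
#' @return Converted magnitude(s).
#' @examples
#' convert_force(0.80, "N", "gf") # 81.58
#' @export
convert_force <- function(value, from = c("N", "gf"), to = c("gf", "N")) {
  from <- match.arg(from, c("N", "gf"))
  to <- match.arg(to, c("N", "gf"))
  stopifnot(is.numeric(value), all(value >= 0, na.rm = TRUE))
  if (from == to) return(value)
  if (from == "N") value * GF_PER_N else value / GF_PER_N
}

#' Seed lot metadata
#'
#' @param lot_id Lot identifier.
#' @param origin_class One of `"SCT"` (short cooking time), `"LCT"` (long
#'   cooking time) or `"OTHER"`.
#' @param tsm_whole_g Whole-sample 1000-seed mass (g).
#' @param tsm_by_cat_g Named numeric, 1000-seed mass per maturity category (g),
#'   names `MB` and `IMG`.
#' @param cat_percent Named numeric, percentage of seed count per maturity
#'   category; must sum to 100 within 0.1.
#' @param color_L,color_a,color_b CIELAB color coordinates (optional).
#' @param moisture_percent Seed moisture content (%; optional).
#' @return An object of class `seed_lot`.
#' @export
seed_lot <- function(lot_id, origin_class = c("SCT", "LCT", "OTHER"),
                     tsm_whole_g, tsm_by_cat_g, cat_percent,
                     color_L = NA_real_, color_a = NA_real_, color_b = NA_real_,
                     moisture_percent = NA_real_) {
  origin_class <- match.arg(origin_class)
  tsm_by_cat_g <- tsm_by_cat_g[MATURITY_RAW]
  cat_percent <- cat_percent[MATURITY_RAW]
  if (anyNA(tsm_by_cat_g) || anyNA(cat_percent))
    stop("tsm_by_cat_g and cat_percent must be named with MB and IMG")
  if (abs(sum(cat_percent) - 100) > 0.1)
    stop("cat_percent over {MB, IMG} must sum to 100 (got ", sum(cat_percent), ")")
  if (any(cat_percent < 0) || any(cat_percent > 100))
    stop("cat_percent values must lie in [0, 100]")
  if (tsm_whole_g <= 0 || any(tsm_by_cat_g[cat_percent > 0] <= 0))
    stop("1000-seed masses must be positive")
  structure(
    list(
      lot_id = as.character(lot_id), origin_class = origin_class,
      tsm_whole_g = tsm_whole_g, tsm_by_cat_g = tsm_by_cat_g,
      cat_percent = cat_percent,
      color_L = color_L, color_a = color_a, color_b = color_b,
      moisture_percent = moisture_percent
    ),
    class = "seed_lot"
  )
}

#' @export
print.seed_lot <- function(x, ...) {
  cat("Seed lot", x$lot_id, sprintf("(%s)", x$origin_class), "\n")
  cat(sprintf("  1000-seed mass: %.2f g (MB %.2f, IMG %.2f)\n",
              x$tsm_whole_g, x$tsm_by_cat_g[["MB"]], x$tsm_by_cat_g[["IMG"]]))
  cat(sprintf("  composition: %.1f%% MB / %.1f%% IMG\n",
              x$cat_percent[["MB"]], x$cat_percent[["IMG"]]))
  invisible(x)
}

# Validate a data frame of per-seed texture readings (internal representation
# of TextureReading records). A reading must carry all three parameters.
validate_readings <- function(readings) {
  req <- c("seed_id", "status", "apf", "aapf", "gapf")
  miss <- setdiff(req, names(readings))
  if (length(miss))
    stop("readings missing column(s): ", paste(miss, collapse = ", "))
  bad_status <- !readings$status %in% c("intact", "overcooked")
  bad_force <- !stats::complete.cases(readings[c("apf", "aapf", "gapf")]) |
    readings$apf < 0 | readings$aapf < 0 | readings$gapf < 0
  bad <- which(bad_status | bad_force)
  if (length(bad))
    stop("invalid texture reading(s) at row(s): ", paste(bad, collapse = ", "))
  readings
}

#' One cooking trial (subsample × maturity × cooking time)
#'
#' @param lot_id Lot identifier.
#' @param maturity `"MB"` or `"IMG"`.
#' @param cooking_time_min Cooking time, minutes, >= 0.
#' @param initial_mass_g,cooked_mass_g Subsample mass before/after cooking (g);
#'   the protocol only adds water, so `cooked_mass_g >= initial_mass_g`.
#' @param n_seeds_initial Seed count of the subsample.
#' @param n_overcooked Count of overcooked seeds (torn coat, split/mashed
#'   cotyledon) after cooking.
#' @param readings Data frame of per-seed texture readings with columns
#'   `seed_id`, `status` (`intact`/`overcooked`), `apf`, `aapf`, `gapf`.
#' @param replicate Replicate index of this subsample within its maturity x
#'   time cell.
#' @return An object of class `cooking_trial`.
#' @export
cooking_trial <- function(lot_id, maturity, cooking_time_min,
                          initial_mass_g, cooked_mass_g,
                          n_seeds_initial, n_overcooked,
                          readings = empty_readings(), replicate = 1L) {
  maturity <- match.arg(maturity, MATURITY_RAW)
  if (cooking_time_min < 0) stop("cooking_time_min must be >= 0")
  if (initial_mass_g <= 0) stop("initial_mass_g must be > 0")
  if (cooked_mass_g < initial_mass_g)
    stop("cooked_mass_g < initial_mass_g: seeds cannot lose mass in this protocol")
  if (n_overcooked < 0 || n_overcooked > n_seeds_initial)
    stop("n_overcooked must lie in [0, n_seeds_initial]")
  readings <- validate_readings(readings)
  if (sum(readings$status == "overcooked") > n_overcooked)
    stop("more overcooked readings than counted overcooked seeds")
  structure(
    list(
      lot_id = as.character(lot_id), maturity = maturity,
      cooking_time_min = cooking_time_min,
      initial_mass_g = initial_mass_g, cooked_mass_g = cooked_mass_g,
      n_seeds_initial = as.integer(n_seeds_initial),
      n_overcooked = as.integer(n_overcooked),
      readings = readings, replicate = as.integer(replicate)
    ),
    class = "cooking_trial"
  )
}

#' @export
print.cooking_trial <- function(x, ...) {
  cat(sprintf(
    "Cooking trial: lot %s, %s, %g min; %d seeds (%d overcooked), %d readings\n",
    x$lot_id, x$maturity, x$cooking_time_min, x$n_seeds_initial,
    x$n_overcooked, nrow(x$readings)))
  invisible(x)
}

empty_readings <- function() {
  data.frame(seed_id = character(), status = character(),
             apf = numeric(), aapf = numeric(), gapf = numeric(),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# CSV readers. Schemas (comma-separated, UTF-8, "." decimal, header row):
#   readings.csv: lot_id, origin_class, maturity, cooking_time_min, seed_id,
#                 status, apf_N, aapf_Ns, gapf_Nps
#   trials.csv:   lot_id, maturity, cooking_time_min, initial_mass_g,
#                 cooked_mass_g, n_seeds_initial, n_overcooked
#   sensory.csv:  lot_id, seed_id, panelist_id, tactile_score,
#                 chewiness_score, apf_N, aapf_Ns, gapf_Nps
#   lots.csv:     lot_id, origin_class, tsm_whole_g, tsm_mb_g, tsm_img_g,
#                 pct_mb, pct_img, L, a, b, moisture_pct

read_schema_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Read per-seed texture readings
#'
#' @param path Path to a `readings.csv` file.
#' @param force_unit Unit of the force columns on disk; grams-force inputs are
#'   converted to newtons with a warning.
#' @return A data frame of validated readings (forces in N); rejected row
#'   numbers, if any, are reported via warning and attached as attribute
#'   `"rejected"`.
#' @export
read_readings <- function(path, force_unit = c("N", "gf")) {
  force_unit <- match.arg(force_unit)
  df <- read_schema_csv(path, c("lot_id", "origin_class", "maturity",
                                "cooking_time_min", "seed_id", "status",
                                "apf_N", "aapf_Ns", "gapf_Nps"))
  if (force_unit == "gf") {
    warning("grams-force input detected; converting to newtons")
    for (col in c("apf_N", "aapf_Ns", "gapf_Nps"))
      df[[col]] <- convert_force(df[[col]], "gf", "N")
  }
  bad <- which(
    !df$maturity %in% MATURITY_RAW |
      !df$status %in% c("intact", "overcooked") |
      is.na(df$apf_N) | is.na(df$aapf_Ns) | is.na(df$gapf_Nps) |
      df$apf_N < 0 | df$aapf_Ns < 0 | df$gapf_Nps < 0 |
      df$cooking_time_min < 0
  )
  if (length(bad)) {
    warning("rejected ", length(bad), " invalid reading row(s): ",
            paste(utils::head(bad, 20), collapse = ", "))
    attr_rows <- bad
    df <- df[-bad, , drop = FALSE]
    attr(df, "rejected") <- attr_rows
  }
  df
}

#' Read cooking trials
#'
#' Materializes `trials.csv` rows (optionally joined with per-seed readings)
#' into validated [cooking_trial()] objects. Rows violating a type invariant
#' raise an error naming the row.
#'
#' @param path Path to a `trials.csv` file.
#' @param readings Optional data frame from [read_readings()]; readings are
#'   matched to trials on `lot_id`, `maturity` and `cooking_time_min` (plus
#'   `replicate` when both files carry that column).
#' @return A list of `cooking_trial` objects.
#' @export
read_trials <- function(path, readings = NULL) {
  df <- read_schema_csv(path, c("lot_id", "maturity", "cooking_time_min",
                                "initial_mass_g", "cooked_mass_g",
                                "n_seeds_initial", "n_overcooked"))
  if (nrow(df) == 0) return(list())
  use_rep <- !is.null(readings) && "replicate" %in% names(df) &&
    "replicate" %in% names(readings)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    rds <- empty_readings()
    if (!is.null(readings)) {
      sel <- readings$lot_id == row$lot_id &
        readings$maturity == row$maturity &
        readings$cooking_time_min == row$cooking_time_min
      if (use_rep) sel <- sel & readings$replicate == row$replicate
      if (any(sel)) {
        r <- readings[sel, ]
        rds <- data.frame(seed_id = as.character(r$seed_id), status = r$status,
                          apf = r$apf_N, aapf = r$aapf_Ns, gapf = r$gapf_Nps,
                          stringsAsFactors = FALSE)
      }
    }
    tryCatch(
      cooking_trial(row$lot_id, row$maturity, row$cooking_time_min,
                    row$initial_mass_g, row$cooked_mass_g,
                    row$n_seeds_initial, row$n_overcooked, readings = rds,
                    replicate = if ("replicate" %in% names(df))
                      row$replicate else 1L),
      error = function(e)
        stop("trials.csv row ", i, ": ", conditionMessage(e), call. = FALSE)
    )
  })
}

#' Read paired sensory/texture calibration records
#'
#' @param path Path to a `sensory.csv` file.
#' @return Data frame with panel scores (1-9 scale) and texture readings.
#' @export
read_sensory <- function(path) {
  df <- read_schema_csv(path, c("lot_id", "seed_id", "panelist_id",
                                "tactile_score", "chewiness_score",
                                "apf_N", "aapf_Ns", "gapf_Nps"))
  bad <- which(df$tactile_score < 1 | df$tactile_score > 9 |
                 df$chewiness_score < 1 | df$chewiness_score > 9 |
                 df$apf_N < 0 | df$aapf_Ns < 0 | df$gapf_Nps < 0)
  if (length(bad)) {
    warning("rejected ", length(bad), " invalid sensory row(s): ",
            paste(utils::head(bad, 20), collapse = ", "))
    df <- df[-bad, , drop = FALSE]
    attr(df, "rejected") <- bad
  }
  df
}

#' Read seed-lot metadata
#'
#' @param path Path to a `lots.csv` file.
#' @return A list of [seed_lot()] objects.
#' @export
read_lots <- function(path) {
  df <- read_schema_csv(path, c("lot_id", "origin_class", "tsm_whole_g",
                                "tsm_mb_g", "tsm_img_g", "pct_mb", "pct_img"))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tryCatch(
      seed_lot(row$lot_id, row$origin_class, row$tsm_whole_g,
               c(MB = row$tsm_mb_g, IMG = row$tsm_img_g),
               c(MB = row$pct_mb, IMG = row$pct_img),
               color_L = if ("L" %in% names(df)) row$L else NA_real_,
               color_a = if ("a" %in% names(df)) row$a else NA_real_,
               color_b = if ("b" %in% names(df)) row$b else NA_real_,
               moisture_percent = if ("moisture_pct" %in% names(df))
                 row$moisture_pct else NA_real_),
      error = function(e)
        stop("lots.csv row ", i, ": ", conditionMessage(e), call. = FALSE)
    )
  })
}

# ---------------------------------------------------------------------------

#' Write a consolidated pipeline report
#'
#' Serializes assembled stage outputs to a machine-readable JSON file plus one
#' tidy CSV per data-frame stage. Re-reading reproduces integer values exactly
#' and reals to full double precision.
#'
#' @param results Named list of stage outputs (data frames or lists of
#'   scalars); standard stage names are `composition`, `descriptives`,
#'   `calibration`, `decay`, `sigmoid`, `anova`, `validation`.
#' @param path Output path for the JSON report; CSVs are written next to it as
#'   `<stem>_<stage>.csv`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, path) {
  stopifnot(is.list(results))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  stem <- sub("\\.[^.]*$", "", path)
  written <- path
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]])) {
      p <- paste0(stem, "_", nm, ".csv")
      utils::write.csv(results[[nm]], p, row.names = FALSE)
      written <- c(written, p)
    }
  }
  invisible(written)
}

#' Read back a report written by [write_report()]
#' @param path Path to the JSON report.
#' @return The deserialized report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
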