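# Reference fixtures: machine-readable transcriptions of the published
# characterization of the two study seed lots (SCT and LCT) — lot
# composition, texture means over cooking time, the fitted decay and sigmoid
# model parameters, the adopted doneness thresholds, and the validation
# cookings. Used as regression fixtures and worked-example inputs; the files
# are immutable and checksum-verified on load.
#
# Forces in the texture-mean table are in newtons; the published decay-model
# parameters are on the grams-force scale as printed (see convert_force).
# The published sigmoid functions carry a "1 - exp" sign that makes them
# singular at x = x0; the transcription records that printed sign in a
# `printed_sign` column while the corrected "+" form is what the package
# fits.

fixture_files <- c(
  lots = "reference_lots.csv",
  texture_means = "reference_texture_means.csv",
  decay_models = "reference_decay_models.csv",
  sigmoid_models = "reference_sigmoid_models.csv",
  validation = "reference_validation.csv",
  thresholds = "reference_thresholds.csv"
)

# ids used in the analysis protocol's table numbering, kept as aliases
fixture_aliases <- c(
  table1 = "lots", table3 = "texture_means",
  table4_decay = "decay_models", table4_sigmoid = "sigmoid_models",
  table4 = "decay_models", table5 = "validation"
)

fixture_md5 <- c(
  lots = "195c65f2e4eb2c36e350c4bc360b3d11",
  texture_means = "c41d0d5694e1ff132067c95b3caf2b6f",
  decay_models = "1959e3ed562740c0b80576d5e31750d7",
  sigmoid_models = "87f3a7c6bdc738ed3f40e33a8445c9b1",
  validation = "502538212a9557468ac74a2d2a51edf0",
  thresholds = "e0f23088f506e2ce0eb12e3b8fd80257"
)

#' Load a reference fixture table
#'
#' Returns one of the transcribed reference tables shipped with the package:
#' `"lots"` (lot characterization), `"texture_means"` (average and
#' count-weighted texture means over cooking time, N), `"decay_models"`
#' (published exponential-decay fits, grams-force scale),
#' `"sigmoid_models"` (published cooked-fraction sigmoid fits),
#' `"validation"` (validation cookings at the predicted OCTs) and
#' `"thresholds"` (adopted doneness thresholds). Table-numbering aliases
#' (`"table1"`, `"table3"`, `"table4_decay"`, `"table4_sigmoid"`,
#' `"table5"`) are accepted.
#'
#' @param table_id Fixture identifier (see above).
#' @return A data frame; the source file's md5 is attached as attribute
#'   `"md5"`.
#' @export
load_fixture <- function(table_id) {
  id <- as.character(table_id)
  if (id %in% names(fixture_aliases)) id <- fixture_aliases[[id]]
  if (!id %in% names(fixture_files))
    stop("unknown fixture id: ", table_id, " (known: ",
         paste(names(fixture_files), collapse = ", "), ")")
  path <- system.file("extdata", fixture_files[[id]], package = "octlens",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  expected <- fixture_md5[[id]]
  if (!is.na(expected) && md5 != expected)
    stop("fixture ", id, " failed its checksum: file was modified")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(df, "md5") <- md5
  df
}

#' Seed-lot objects from the lot-characterization fixture
#' @return A named list of two [seed_lot()] objects (`SCT`, `LCT`).
#' @export
fixture_lots <- function() {
  df <- load_fixture("lots")
  lots <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    seed_lot(row$lot_id, row$origin_class, row$tsm_whole_g,
             c(MB = row$tsm_mb_g, IMG = row$tsm_img_g),
             c(MB = row$pct_mb, IMG = row$pct_img),
             color_L = row$L, color_a = row$a, color_b = row$b,
             moisture_percent = row$moisture_pct)
  })
  stats::setNames(lots, df$lot_id)
}

#' One texture-mean series from the texture-means fixture
#'
#' @param sample `"SCT"` or `"LCT"`.
#' @param maturity `"MB"`, `"IMG"` or `"TOTAL"`.
#' @param parameter Texture parameter code.
#' @param kind `"average"` or `"weighted"`.
#' @return Data frame with columns `cooking_time_min` and `value` (N).
#' @export
fixture_series <- function(sample, maturity, parameter = "APF",
                           kind = c("average", "weighted")) {
  kind <- match.arg(kind)
  parameter <- match_parameter(parameter)
  df <- load_fixture("texture_means")
  sel <- df$sample == sample & df$maturity == maturity &
    df$parameter == parameter
  if (!any(sel)) stop("no fixture series for ", sample, "/", maturity,
                      "/", parameter)
  out <- df[sel, c("cooking_time_min", kind)]
  names(out) <- c("cooking_time_min", "value")
  out[order(out$cooking_time_min), ]
}
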