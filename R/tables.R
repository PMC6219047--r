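# Published summary tables bundled as plain-CSV fixtures. The gravimetric
# and imaging experiments behind them (16 step levels, 40 to 640 by 40, five
# replicates each) are instrument work; the package consumes their per-step
# summaries as calibration inputs and as reference values for validation.
# `cv_printed` / `rel_dev_printed` are the values as published (percent),
# kept so recomputed statistics can be compared against them.

read_bundled_table <- function(name) {
  path <- system.file("extdata", name, package = "tipvision", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Bundled study tables
#'
#' Per-step summaries of the reference experiments on the target dispenser:
#'
#' * `pump_mass_table()` — mean and sample SD of the gravimetrically measured
#'   reagent mass at each commanded step count (five replicates per level),
#'   plus the published CV row.
#' * `volume_length_table()` — mean and sample SD of the image-measured
#'   volume length (pixels) at the same step levels, plus the published CV
#'   row.
#' * `step_error_table()` — published RMS deviation of the image-based step
#'   estimates from the commanded steps (`dev`, in steps) and its published
#'   percentage (`rel_dev_printed`).
#'
#' @return A tibble with a `steps` column (40–640 by 40) and the columns
#'   described above.
#' @name study_tables
NULL

#' @rdname study_tables
#' @export
pump_mass_table <- function() read_bundled_table("pump_mass_table.csv")

#' @rdname study_tables
#' @export
volume_length_table <- function() read_bundled_table("volume_length_table.csv")

#' @rdname study_tables
#' @export
step_error_table <- function() read_bundled_table("step_error_table.csv")
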