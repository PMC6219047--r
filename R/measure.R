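# The measurement chain of the monitoring flow: ROI crop -> pure red ->
# median filter -> fixed threshold -> projections -> scalar measurements.

#' Pipeline configuration
#'
#' Bundles everything the measurement chain needs: the two regions of
#' interest (the tip ROI for reagent segmentation and volume length, the
#' holder ROI for the holder-top localisation check), the fixed binarisation
#' threshold on the pure-red channel, the colour-difference sign convention,
#' the luminance threshold below which a pixel counts as the dark holder, the
#' pump-check bound, and optionally a calibration (object or JSON path).
#'
#' Defaults match the default synthetic scene geometry of [scene_spec()].
#'
#' @param tip_roi,holder_roi [roi_spec()] objects.
#' @param threshold Pure-red binarisation threshold in `[0, 255]`. The
#'   default 40 sits far from both a matte background (pure red about 0-10)
#'   and a red reagent (about 100+).
#' @param red_sign `"r_minus_y"` (default) or `"y_minus_r"`; see
#'   [pure_red()].
#' @param holder_luminance_threshold Pixels darker than this count as holder.
#' @param bound_mode,bound_value Pump-check bound; see [check_pump()].
#' @param calibration A `pump_calibration`, a path to a calibration JSON, or
#'   `NULL`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tip_roi = roi_spec(45L, 315L, 5L, 315L),
                            holder_roi = roi_spec(10L, 49L, 5L, 315L),
                            threshold = 40,
                            red_sign = c("r_minus_y", "y_minus_r"),
                            holder_luminance_threshold = 140,
                            bound_mode = c("relative", "absolute"),
                            bound_value = 5,
                            calibration = NULL) {
  red_sign <- match.arg(red_sign)
  bound_mode <- match.arg(bound_mode)
  if (!inherits(tip_roi, "roi_spec") || !inherits(holder_roi, "roi_spec")) {
    abort("`tip_roi` and `holder_roi` must be roi_spec objects.")
  }
  if (threshold < 0 || threshold > 255) abort("`threshold` must be in [0, 255].")
  if (bound_value <= 0) abort("`bound_value` must be positive.")
  if (is.character(calibration)) calibration <- read_calibration(calibration)
  if (!is.null(calibration) && !inherits(calibration, "pump_calibration")) {
    abort("`calibration` must be NULL, a pump_calibration, or a JSON path.")
  }
  structure(
    list(tip_roi = tip_roi, holder_roi = holder_roi, threshold = threshold,
         red_sign = red_sign,
         holder_luminance_threshold = holder_luminance_threshold,
         bound_mode = bound_mode, bound_value = bound_value,
         calibration = calibration),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `tip_roi` / `holder_roi` (each a list `top`, `bottom`,
#' `left`, `right`), `threshold`, `red_sign`, `holder_luminance_threshold`,
#' `bound_mode`, `bound_value`, `calibration` (JSON path, resolved relative
#' to the config file). Missing keys fall back to the defaults of
#' [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- list()
  for (r in c("tip_roi", "holder_roi")) {
    if (!is.null(y[[r]])) {
      args[[r]] <- roi_spec(y[[r]]$top, y[[r]]$bottom, y[[r]]$left, y[[r]]$right)
    }
  }
  for (k in c("threshold", "red_sign", "holder_luminance_threshold",
              "bound_mode", "bound_value")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$calibration)) {
    cal <- y$calibration
    if (!file.exists(cal)) cal <- file.path(dirname(path), cal)
    args$calibration <- cal
  }
  do.call(pipeline_config, args)
}

#' Segment the reagent inside the tip ROI
#'
#' The core preprocessing chain: crop the tip ROI, form the pure-red
#' colour-difference channel, median-filter it 3x3 and binarise at the fixed
#' threshold.
#'
#' @param img A 3-channel frame.
#' @param config A [pipeline_config()].
#' @return A 0/1 mask with the tip ROI's shape.
#' @export
segment_reagent <- function(img, config = pipeline_config()) {
  roi <- crop_roi(img, config$tip_roi)
  binarize(median3x3(pure_red(roi, sign = config$red_sign)), config$threshold)
}

#' Segment the dark holder inside the holder ROI
#'
#' @inheritParams segment_reagent
#' @return A 0/1 mask with the holder ROI's shape.
#' @export
segment_holder <- function(img, config = pipeline_config()) {
  y <- luminance(crop_roi(img, config$holder_roi))
  # holder is dark on a light background: foreground = luminance below threshold
  binarize(median3x3(255 - y), 255 - config$holder_luminance_threshold)
}

#' Measure a frame
#'
#' Runs the full measurement chain on one frame and returns the three scalar
#' observables: the volume length (reagent rows), the tip centre column and
#' the holder top row, the latter two in full-frame coordinates. `NA` in
#' `tip_col` or `holder_row` is the absent-detection outcome.
#'
#' @inheritParams segment_reagent
#' @return A one-row tibble: `volume_length_px`, `tip_col`, `holder_row`.
#' @export
measure_tip <- function(img, config = pipeline_config()) {
  assert_raster(img, channels = 3L)
  rmask <- segment_reagent(img, config)
  hmask <- segment_holder(img, config)
  tip_col <- tip_position(rmask)
  holder_row <- holder_top(hmask)
  tibble(
    volume_length_px = volume_length(rmask),
    tip_col = if (is.na(tip_col)) NA_integer_ else tip_col + config$tip_roi$left - 1L,
    holder_row = if (is.na(holder_row)) NA_integer_ else holder_row + config$holder_roi$top - 1L
  )
}
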