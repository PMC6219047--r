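# Parametric synthetic tip scenes with per-pixel ground truth.
#
# The device images a translucent conical tip, apex down, in front of a matte
# grey background under controlled illumination. The generator reproduces
# exactly those conditions: a red liquid column drawn as the cone
# cross-section up to the height implied by the aspirated volume, light tip
# walls, a dark holder bar, an optional vertical illumination ramp and
# additive Gaussian sensor noise. Every scene carries the geometry it was
# drawn from, so each pipeline stage can be validated against ground truth
# without instrument hardware.

#' Liquid column height in a conical tip
#'
#' For a cone of half-angle `theta` filled from the apex, volume and height
#' obey `V = (pi tan^2(theta) / 3) h^3`; inverting gives
#' `h = (3 V / (pi tan^2 theta))^(1/3)`. With volume in cubic length units
#' (e.g. uL = mm^3) the height comes out in the same length unit and
#' `px_per_unit` converts it to pixels (camera magnification).
#'
#' @param volume Aspirated volume(s), >= 0.
#' @param half_angle Cone half-angle in degrees, in (0, 45].
#' @param px_per_unit Pixels per length unit (default 1: height in length
#'   units).
#' @return Column height(s); strictly increasing in `volume`, 0 at 0.
#' @examples
#' height_from_volume(pi / 3, half_angle = 45) # unit cone: h = 1
#' @export
height_from_volume <- function(volume, half_angle, px_per_unit = 1) {
  if (!is.numeric(half_angle) || length(half_angle) != 1L || is.na(half_angle) ||
      half_angle <= 0 || half_angle > 45) {
    abort("`half_angle` must be in (0, 45] degrees.")
  }
  if (!is.numeric(volume) || anyNA(volume) || any(volume < 0)) {
    abort("`volume` must be non-negative.")
  }
  t2 <- tan(half_angle * pi / 180)^2
  (3 * volume / (pi * t2))^(1 / 3) * px_per_unit
}

#' Synthetic scene specification
#'
#' Defaults describe one fixed, realistic imaging geometry: a 340 x 320
#' frame, tip apex at (row 310, col 160), cone half-angle 30 degrees (wide
#' enough that every liquid row above the apex is at least 3 px across, so
#' the 3x3 median filter cannot erode the column interior), red liquid
#' (180, 30, 30) on a matte grey background (200, 200, 200), 0.184 uL per
#' pump step and 34.5 px per mm. A full-range 640-step aspiration then fills
#' about 240 px of the tip, comparable to the volume lengths a real device
#' produces.
#'
#' @param height,width Frame size in pixels.
#' @param apex_row,apex_col Tip apex position (not on the frame border).
#' @param half_angle Cone half-angle in degrees, in (0, 45).
#' @param tip_top_row Row at which the drawn tip ends (its mouth).
#' @param liquid_color,wall_color,background_color,holder_color RGB triplets
#'   in `[0, 255]`.
#' @param holder_rows,holder_cols Two-element ranges of the holder bar.
#' @param volume Aspirated volume in uL; alternatively give `steps`.
#' @param steps Commanded pump steps; volume is `steps * ul_per_step`.
#' @param ul_per_step Pump displacement per step (uL).
#' @param px_per_unit Camera scale, px per mm.
#' @param illumination_gradient Peak-to-peak amplitude (intensity units) of a
#'   vertical ramp added to all channels; 0 disables.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise per
#'   channel; 0 disables.
#' @param seed Integer seed making the render deterministic.
#' @param tip_present Draw the tip and its contents (FALSE emulates a missing
#'   tip).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(height = 340L, width = 320L,
                       apex_row = 310L, apex_col = 160L,
                       half_angle = 30, tip_top_row = 50L,
                       liquid_color = c(180L, 30L, 30L),
                       wall_color = c(185L, 185L, 190L),
                       background_color = c(200L, 200L, 200L),
                       holder_color = c(80L, 80L, 85L),
                       holder_rows = c(20L, 48L), holder_cols = c(40L, 280L),
                       volume = NULL, steps = NULL, ul_per_step = 0.184,
                       px_per_unit = 34.5,
                       illumination_gradient = 0, noise_sd = 0,
                       seed = 1L, tip_present = TRUE) {
  if (!is.null(steps)) {
    if (!is.null(volume)) abort("Give either `volume` or `steps`, not both.")
    if (!is.numeric(steps) || length(steps) != 1L || steps < 0) abort("`steps` must be a single non-negative number.")
    volume <- steps * ul_per_step
  }
  if (is.null(volume)) volume <- 0
  if (!is.numeric(volume) || length(volume) != 1L || is.na(volume) || volume < 0) {
    abort("`volume` must be a single non-negative number.")
  }
  if (!is.numeric(half_angle) || half_angle <= 0 || half_angle >= 45) {
    abort("`half_angle` must lie strictly between 0 and 45 degrees.")
  }
  if (apex_row <= 1L || apex_row >= height || apex_col <= 1L || apex_col >= width) {
    abort("Degenerate geometry: the tip apex must lie strictly inside the frame.")
  }
  if (tip_top_row < 1L || tip_top_row >= apex_row) {
    abort("`tip_top_row` must lie above the apex row.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  for (col in list(liquid_color, wall_color, background_color, holder_color)) {
    if (length(col) != 3L || any(col < 0) || any(col > 255)) {
      abort("Colours must be RGB triplets in [0, 255].")
    }
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         apex_row = as.integer(apex_row), apex_col = as.integer(apex_col),
         half_angle = half_angle, tip_top_row = as.integer(tip_top_row),
         liquid_color = liquid_color, wall_color = wall_color,
         background_color = background_color, holder_color = holder_color,
         holder_rows = as.integer(holder_rows), holder_cols = as.integer(holder_cols),
         volume = volume, steps = if (is.null(steps)) NA_real_ else steps,
         ul_per_step = ul_per_step, px_per_unit = px_per_unit,
         illumination_gradient = illumination_gradient, noise_sd = noise_sd,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         tip_present = isTRUE(tip_present), aspiration_fraction = 1),
    class = "scene_spec"
  )
}

# Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_local_seed <- function(seed, code) {
  if (is.na(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Render a synthetic scene
#'
#' Deterministic for a fixed `seed`. Drawing order: matte background, dark
#' holder bar, tip walls (two-pixel cone outline), liquid cross-section
#' (triangle from the apex up to the height implied by the volume), then the
#' illumination ramp and Gaussian noise, clamped to `[0, 255]` and rounded.
#'
#' @param scene A [scene_spec()].
#' @return A list with `image` (H x W x 3 array of 8-bit intensities) and
#'   `truth`, itself a list: `liquid_top_row`, `apex_row`,
#'   `column_height_px` (real), `volume_length_px` (rows intersecting
#'   liquid), `tip_center_col`, `holder_top_row`, `liquid_mask` (0/1 matrix,
#'   full frame) and the `scene`.
#' @export
render_scene <- function(scene) {
  if (!inherits(scene, "scene_spec")) abort("`scene` must be a scene_spec.")
  H <- scene$height; W <- scene$width
  # a missing tip holds no liquid, whatever volume was commanded
  vol_eff <- if (scene$tip_present) scene$volume else 0
  h_px <- height_from_volume(vol_eff, scene$half_angle, scene$px_per_unit)
  n_rows <- if (h_px > 0) as.integer(ceiling(h_px)) else 0L
  if (scene$tip_present && n_rows > scene$apex_row - scene$tip_top_row + 1L) {
    abort("Volume exceeds the drawn tip capacity; lower the volume or raise the tip mouth.")
  }

  ch <- lapply(scene$background_color, function(v) matrix(as.numeric(v), H, W))

  hr <- scene$holder_rows; hc <- scene$holder_cols
  for (k in 1:3) ch[[k]][hr[1L]:hr[2L], hc[1L]:hc[2L]] <- scene$holder_color[k]

  tanth <- tan(scene$half_angle * pi / 180)
  if (scene$tip_present) {
    rows <- scene$tip_top_row:scene$apex_row
    dr <- scene$apex_row - rows
    hw <- round(dr * tanth)
    for (i in seq_along(rows)) {
      for (cc in c(scene$apex_col - hw[i] - 1L, scene$apex_col - hw[i],
                   scene$apex_col + hw[i], scene$apex_col + hw[i] + 1L)) {
        if (cc >= 1L && cc <= W) for (k in 1:3) ch[[k]][rows[i], cc] <- scene$wall_color[k]
      }
    }
  }

  liquid_mask <- matrix(0L, H, W)
  liquid_top <- NA_integer_
  if (scene$tip_present && n_rows > 0L) {
    dr_all <- scene$apex_row - seq_len(H)
    in_liq_row <- dr_all >= 0L & dr_all < h_px
    hw_row <- matrix(dr_all * tanth, H, W)
    coldist <- matrix(abs(seq_len(W) - scene$apex_col), H, W, byrow = TRUE)
    liquid_mask[in_liq_row & coldist <= hw_row] <- 1L
    liquid_top <- scene$apex_row - n_rows + 1L
    idx <- liquid_mask == 1L
    for (k in 1:3) ch[[k]][idx] <- scene$liquid_color[k]
  }

  if (scene$illumination_gradient != 0) {
    ramp <- scene$illumination_gradient * ((seq_len(H) - 1) / (H - 1) - 0.5)
    for (k in 1:3) ch[[k]] <- ch[[k]] + ramp
  }
  img <- with_local_seed(scene$seed, {
    if (scene$noise_sd > 0) {
      for (k in 1:3) ch[[k]] <- ch[[k]] + rnorm(H * W, sd = scene$noise_sd)
    }
    array(c(ch[[1L]], ch[[2L]], ch[[3L]]), dim = c(H, W, 3L))
  })
  img <- floor(pmin(pmax(img, 0), 255) + 0.5)

  list(
    image = img,
    truth = list(
      liquid_top_row = liquid_top,
      apex_row = scene$apex_row,
      column_height_px = h_px,
      volume_length_px = n_rows,
      tip_center_col = if (scene$tip_present) scene$apex_col else NA_integer_,
      holder_top_row = scene$holder_rows[1L],
      liquid_mask = liquid_mask,
      scene = scene
    )
  )
}

#' Render a volume sweep
#'
#' One scene per requested volume (or step count), with per-element seeds
#' derived deterministically from the master seed so sweeps are reproducible
#' element-wise.
#'
#' @param volumes Volumes in uL, or `NULL` if `steps` is given.
#' @param steps Optional commanded step counts (converted via the template's
#'   `ul_per_step`).
#' @param scene Template [scene_spec()]; its volume/seed fields are replaced
#'   per element.
#' @param seed Master seed.
#' @return A list with `renders` (list of [render_scene()] results) and
#'   `manifest`, a tibble: `index`, `steps`, `volume`, `seed`,
#'   `column_height_px`, `volume_length_px` (ground truth).
#' @export
render_sweep <- function(volumes = NULL, steps = NULL, scene = scene_spec(), seed = 1L) {
  if (!is.null(steps)) {
    if (!is.null(volumes)) abort("Give either `volumes` or `steps`, not both.")
    volumes <- steps * scene$ul_per_step
  } else {
    steps <- rep(NA_real_, length(volumes))
  }
  if (is.null(volumes) || length(volumes) == 0L) abort("At least one volume is required.")
  if (any(is.na(volumes)) || any(volumes < 0)) abort("Volumes must be non-negative.")
  renders <- purrr::map(seq_along(volumes), function(i) {
    s <- scene
    # honour an injected under-aspiration when the sweep assigns volumes
    s$volume <- volumes[i] * scene$aspiration_fraction
    s$steps <- steps[i]
    s$seed <- as.integer(seed + i)
    render_scene(s)
  })
  manifest <- tibble(
    index = seq_along(volumes),
    steps = steps,
    volume = volumes,
    seed = as.integer(seed + seq_along(volumes)),
    column_height_px = purrr::map_dbl(renders, ~ .x$truth$column_height_px),
    volume_length_px = purrr::map_int(renders, ~ .x$truth$volume_length_px)
  )
  list(renders = renders, manifest = manifest)
}

#' Inject a failure mode into a scene
#'
#' Emulates the malfunctions the camera check is meant to catch: a missing
#' tip, a tip misaligned on its holder, or a pump that aspirates only a
#' fraction of the commanded volume.
#'
#' @param scene A [scene_spec()].
#' @param mode One of `"tip_absent"`, `"holder_misaligned"`,
#'   `"under_aspiration"`.
#' @param fraction For under-aspiration: achieved fraction of the commanded
#'   volume, strictly inside (0, 1).
#' @param offset For misalignment: horizontal tip displacement in pixels.
#' @return The modified `scene_spec`; ground truth of its render reflects the
#'   failure.
#' @export
inject_failure <- function(scene, mode = c("tip_absent", "holder_misaligned", "under_aspiration"),
                           fraction = NULL, offset = 25L) {
  mode <- match.arg(mode)
  if (!inherits(scene, "scene_spec")) abort("`scene` must be a scene_spec.")
  switch(mode,
    tip_absent = {
      scene$tip_present <- FALSE
      scene$volume <- 0
    },
    holder_misaligned = {
      new_col <- scene$apex_col + as.integer(offset)
      if (new_col <= 1L || new_col >= scene$width) {
        abort("Misalignment offset pushes the tip outside the frame.")
      }
      scene$apex_col <- new_col
    },
    under_aspiration = {
      if (is.null(fraction) || !is.numeric(fraction) || length(fraction) != 1L ||
          is.na(fraction) || fraction <= 0 || fraction >= 1) {
        abort("`fraction` must lie strictly between 0 and 1.")
      }
      scene$volume <- scene$volume * fraction
      scene$aspiration_fraction <- fraction
    }
  )
  scene
}

#' Plot a rendered scene
#'
#' @param render A result of [render_scene()].
#' @param show_truth Overlay the ground-truth liquid top and apex rows.
#' @return A ggplot object.
#' @export
plot_scene <- function(render, show_truth = TRUE) {
  img <- render$image
  rgb_m <- grDevices::rgb(img[, , 1L] / 255, img[, , 2L] / 255, img[, , 3L] / 255)
  dim(rgb_m) <- dim(img)[1:2]
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(rgb_m, xmin = 0.5, xmax = ncol(rgb_m) + 0.5,
                               ymin = -(nrow(rgb_m) + 0.5), ymax = -0.5) +
    ggplot2::coord_fixed(xlim = c(0.5, ncol(rgb_m) + 0.5),
                         ylim = c(-(nrow(rgb_m) + 0.5), -0.5), expand = FALSE) +
    ggplot2::labs(x = "column", y = "row (negated)") +
    ggplot2::theme_minimal()
  if (show_truth && !is.na(render$truth$liquid_top_row)) {
    p <- p +
      ggplot2::geom_hline(yintercept = -render$truth$liquid_top_row, linetype = 2) +
      ggplot2::geom_hline(yintercept = -render$truth$apex_row, linetype = 3)
  }
  p
}
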