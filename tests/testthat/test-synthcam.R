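# Synthetic scene generator: geometry, determinism, closure with the
# measurement pipeline, and failure injection.

test_that("height_from_volume follows the cone law", {
  expect_equal(height_from_volume(0, 30), 0)
  # unit cone: half-angle 45 deg, V = pi/3 -> h = 1
  expect_equal(height_from_volume(pi / 3, 45), 1)
  # doubling the volume scales height by 2^(1/3)
  h1 <- height_from_volume(1.7, 30)
  expect_equal(height_from_volume(3.4, 30), h1 * 2^(1 / 3))
  # strictly increasing
  v <- seq(0.1, 5, length.out = 30)
  expect_true(all(diff(height_from_volume(v, 20)) > 0))
  expect_error(height_from_volume(1, 0), "half_angle")
  expect_error(height_from_volume(-1, 30), "non-negative")
})

test_that("scene_spec validates geometry and volume", {
  expect_error(scene_spec(apex_row = 1), "apex")
  expect_error(scene_spec(half_angle = 50), "half_angle")
  expect_error(scene_spec(volume = -2), "non-negative")
  expect_error(scene_spec(volume = 1, steps = 40), "not both")
  sc <- scene_spec(steps = 100)
  expect_equal(sc$volume, 100 * sc$ul_per_step)
})

test_that("rendering is deterministic for a fixed seed", {
  sc <- small_scene(volume = 1.2, noise_sd = 3, illumination_gradient = 8, seed = 17)
  r1 <- render_scene(sc)
  r2 <- render_scene(sc)
  expect_identical(r1$image, r2$image)
  r3 <- render_scene(small_scene(volume = 1.2, noise_sd = 3,
                                 illumination_gradient = 8, seed = 18))
  expect_false(identical(r1$image, r3$image))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(999)
  a <- rnorm(3)
  set.seed(999)
  invisible(render_scene(small_scene(volume = 1, noise_sd = 2, seed = 5)))
  expect_identical(rnorm(3), a)
})

test_that("zero volume renders no liquid and truth agrees", {
  r <- render_scene(small_scene(volume = 0, seed = 1))
  expect_equal(r$truth$volume_length_px, 0L)
  expect_true(all(r$truth$liquid_mask == 0L))
  expect_true(is.na(r$truth$liquid_top_row))
  # no liquid-coloured pixels anywhere
  lc <- small_scene(volume = 0)$liquid_color
  hits <- r$image[, , 1] == lc[1] & r$image[, , 2] == lc[2] & r$image[, , 3] == lc[3]
  expect_equal(sum(hits), 0L)
})

test_that("ground truth is internally consistent with the drawn geometry", {
  r <- render_scene(small_scene(volume = 2.4, seed = 3))
  tr <- r$truth
  expect_equal(tr$volume_length_px, tr$apex_row - tr$liquid_top_row + 1L)
  expect_equal(tr$volume_length_px, ceiling(tr$column_height_px))
  expect_equal(sum(row_profile(tr$liquid_mask)$count > 0), tr$volume_length_px)
  expect_error(render_scene(small_scene(volume = 50)), "capacity")
})

test_that("generator/measurement closure: noise-free lengths within 1 px of truth", {
  cfg <- default_config()
  sw <- render_sweep(steps = round(seq(40, 640, length.out = 20)), seed = 21)
  meas <- vapply(sw$renders, function(x) measure_tip(x$image, cfg)$volume_length_px,
                 integer(1))
  expect_true(all(abs(meas - sw$manifest$volume_length_px) <= 1L))
  expect_true(all(diff(meas) > 0L)) # strictly increasing along the sweep
  # cube of measured lengths is linear in volume
  f <- ols_fit(sw$manifest$volume, meas^3)
  expect_gte(f$r_squared, 0.999)
})

test_that("sweep seeds derive per element and a single sweep matches render_scene", {
  sw <- render_sweep(volumes = 1.1, scene = small_scene(), seed = 40)
  single <- small_scene(volume = 1.1, seed = 41L)
  expect_identical(sw$renders[[1]]$image, render_scene(single)$image)
  expect_error(render_sweep(volumes = numeric(0)), "[Aa]t least one")
  expect_error(render_sweep(volumes = c(1, 2), steps = c(40, 80)), "not both")
})

test_that("failure injection reshapes scene and ground truth", {
  base <- small_scene(volume = 2, seed = 8)

  absent <- inject_failure(base, "tip_absent")
  ra <- render_scene(absent)
  expect_equal(ra$truth$volume_length_px, 0L)
  expect_true(is.na(ra$truth$tip_center_col))
  expect_true(is.na(measure_tip(ra$image, small_config())$tip_col))

  mis <- inject_failure(base, "holder_misaligned", offset = 15L)
  expect_equal(mis$apex_col, base$apex_col + 15L)

  under <- inject_failure(base, "under_aspiration", fraction = 0.7)
  expect_equal(under$volume, base$volume * 0.7)
  expect_error(inject_failure(base, "under_aspiration", fraction = 1), "strictly")
  expect_error(inject_failure(base, "under_aspiration", fraction = 0), "strictly")
})

test_that("end-to-end: noisy calibration recovers held-out commanded steps", {
  cfg <- default_config()
  levels <- seq(40, 640, by = 40)
  cal_rows <- purrr::map(seq_along(levels), function(i) {
    reps <- purrr::map_int(1:5, function(j) {
      sc <- scene_spec(steps = levels[i], noise_sd = 2, seed = 1000L + 10L * i + j)
      measure_tip(render_scene(sc)$image, cfg)$volume_length_px
    })
    tibble::tibble(steps = levels[i], length = as.numeric(reps))
  })
  cal_tbl <- dplyr::bind_rows(cal_rows)
  model <- fit_cube_linear(cal_tbl)
  expect_gte(model$r_squared, 0.999)

  held_out <- c(240, 360, 480, 600)
  rel_dev <- vapply(held_out, function(s) {
    m <- measure_tip(render_scene(scene_spec(steps = s, noise_sd = 2,
                                             seed = 7000L + s))$image, cfg)
    100 * abs(estimate_steps(m$volume_length_px, model) - s) / s
  }, numeric(1))
  expect_true(all(rel_dev < 5))
})
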