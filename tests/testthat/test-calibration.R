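# Replicate statistics, OLS fits, inverse estimation and the pump check.

test_that("replicate_stats computes n-1 SD and percent CV per step level", {
  d <- data.frame(steps = rep(c(40, 80), each = 5),
                  value = c(5.1, 5.3, 5.2, 5.5, 5.4, 11.2, 11.6, 11.4, 11.3, 11.5))
  rs <- replicate_stats(d)
  expect_equal(rs$n, c(5L, 5L))
  expect_equal(rs$mean, c(mean(d$value[1:5]), mean(d$value[6:10])))
  expect_equal(rs$sd, c(sd(d$value[1:5]), sd(d$value[6:10])))
  expect_equal(rs$cv_percent, 100 * rs$sd / rs$mean)

  same <- data.frame(steps = rep(40, 4), value = rep(7, 4))
  expect_equal(replicate_stats(same)$cv_percent, 0)

  single <- data.frame(steps = c(40, 40, 80), value = c(1, 2, 3))
  expect_error(replicate_stats(single), "replicates")
})

test_that("cv_percent reproduces the published per-step CVs at 1 d.p.", {
  expect_equal(round(cv_percent(5.28, 0.26), 1), 4.9) # mass table, 40 steps
  expect_equal(round(cv_percent(72, 1.87), 1), 2.6) # length table, 40 steps
})

test_that("ols_fit recovers exact lines and matches the normal-equations oracle", {
  f <- ols_fit(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  set.seed(19)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- sample(1:200, n)
    y <- rnorm(n, 2 + 0.5 * x, 3)
    fit <- ols_fit(x, y)
    ora <- ols_oracle(x, y)
    expect_equal(fit$slope, ora$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, ora$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, ora$r_squared, tolerance = 1e-9)
  }

  expect_error(ols_fit(rep(3, 4), 1:4), "[Dd]egenerate")
})

test_that("R-squared is invariant under affine rescaling of x and y", {
  set.seed(29)
  for (i in 1:8) {
    x <- sample(1:100, 8); y <- rnorm(8, x, 5)
    r2 <- ols_fit(x, y)$r_squared
    expect_equal(ols_fit(3.2 * x - 7, y)$r_squared, r2)
    expect_equal(ols_fit(x, -0.4 * y + 11)$r_squared, r2)
  }
})

test_that("fit_cube_linear cubes per-step means and pools duplicate levels", {
  # two step levels determine the line exactly
  two <- data.frame(steps = c(100, 200), length = c(50, 63))
  f2 <- fit_cube_linear(two)
  expect_equal(f2$r_squared, 1)
  expect_equal(f2$transform, "cubed volume length")

  # duplicated levels behave as replicates (averaged before cubing)
  dup <- data.frame(steps = c(100, 100, 200), length = c(49, 51, 63))
  expect_equal(fit_cube_linear(dup)$slope, f2$slope)

  # an exact cube-law sweep fits perfectly
  s <- seq(40, 640, by = 40)
  ideal <- data.frame(steps = s, length = (12000 * s + 500)^(1 / 3))
  expect_gte(fit_cube_linear(ideal)$r_squared, 1 - 1e-12)
})

test_that("estimate_steps inverts the calibration and flags misuse", {
  ident <- ols_fit(c(0, 1), c(0, 1), transform = "cubed volume length")
  expect_equal(estimate_steps(4, ident), 64)

  # round trip through a realistic calibration
  cal <- ols_fit(seq(40, 640, 40), 21000 * seq(40, 640, 40) - 20000,
                 transform = "cubed volume length")
  s_hat <- 371.5
  L <- (cal$slope * s_hat + cal$intercept)^(1 / 3)
  expect_equal(estimate_steps(L, cal), s_hat, tolerance = 1e-9)

  mass_fit <- ols_fit(1:5, 1:5, transform = "mass")
  expect_error(estimate_steps(10, mass_fit), "cubed volume length")
  pos_int <- ols_fit(c(1, 2), c(5, 6), transform = "cubed volume length")
  expect_warning(estimate_steps(0, pos_int), "negative") # (0 - 4) / 1 < 0
})

test_that("deviation_stats measures RMS deviation from the true steps", {
  d <- deviation_stats(40, c(40, 40, 40))
  expect_equal(d$dev, 0)
  expect_equal(d$rel_dev_percent, 0)

  one <- deviation_stats(100, 87)
  expect_equal(one$dev, 13)

  # published worked example: Dev 25.3 at 40 steps -> 63.2% (1 d.p.)
  expect_equal(round(100 * 25.3 / 40, 1), 63.2)

  expect_error(deviation_stats(-5, c(1, 2)), "positive")
})

test_that("deviation about the true value dominates deviation about the mean", {
  set.seed(31)
  for (i in 1:10) {
    true <- sample(50:500, 1)
    est <- rnorm(6, true + rnorm(1, 0, 10), 5)
    dev_true <- deviation_stats(true, est)$dev
    dev_mean <- sqrt(mean((est - mean(est))^2))
    expect_gte(dev_true, dev_mean - 1e-12)
    # equality iff the mean error vanishes: dev_true^2 = dev_mean^2 + bias^2
    expect_equal(dev_true^2, dev_mean^2 + (mean(est) - true)^2, tolerance = 1e-9)
  }
})

test_that("check_pump applies a strict bound in both modes", {
  # slope 2.5, intercept 50: L = 10 estimates (1000 - 50) / 2.5 = 380 exactly,
  # i.e. a 5.0% deviation from 400 commanded -> on the bound, strict rule passes
  cal <- new_cal(slope = 2.5, intercept = 50)
  expect_equal(check_pump(400, 10, cal)$verdict, "pass")
  # intercept 52.5 estimates 379: 5.25% -> fail
  expect_equal(check_pump(400, 10, new_cal(2.5, 52.5))$verdict, "fail")
  expect_equal(check_pump(380, 10, cal)$verdict, "pass") # exact match
  # absolute mode: deviation of 20 steps against bounds 20 and 19.9
  expect_equal(check_pump(400, 10, cal, bound_mode = "absolute",
                          bound_value = 20)$verdict, "pass")
  expect_equal(check_pump(400, 10, cal, bound_mode = "absolute",
                          bound_value = 19.9)$verdict, "fail")
  expect_error(check_pump(400, 7, cal, bound_value = -1), "positive")
})

test_that("calibration parameter recovery: slope within 3 SE almost surely", {
  s <- seq(40, 640, by = 40)
  a <- 21500; b <- -30000
  set.seed(101)
  inside <- vapply(1:100, function(i) {
    y <- a * s + b + rnorm(length(s), 0, 5e4)
    fit <- ols_fit(s, y, transform = "cubed volume length")
    se <- tidy(fit)$std.error[2]
    abs(fit$slope - a) <= 3 * se
  }, logical(1))
  expect_gte(sum(inside), 97L)
})

test_that("tidy, glance, print and JSON persistence round-trip the model", {
  fit <- ols_fit(seq(40, 640, 40), 21000 * seq(40, 640, 40) - 1e4 + rnorm(16, 0, 100),
                 transform = "cubed volume length")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "steps"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)

  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(fit, path, extra = list(threshold = 40))
  back <- read_calibration(path)
  expect_equal(back$slope, fit$slope)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$transform, fit$transform)
  expect_equal(estimate_steps(150, back), estimate_steps(150, fit))

  expect_output(print(fit), "R-squared")
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
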