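# Independent oracles and compact scene helpers shared across tests.

# Brute-force 3x3 median with edge replication: explicit 9-element sort.
median3x3_oracle <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- img
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      rows <- pmin(pmax(r + (-1:1), 1L), h)
      cols <- pmin(pmax(c + (-1:1), 1L), w)
      out[r, c] <- sort(as.vector(img[rows, cols]))[5L]
    }
  }
  out
}

# Normal-equations OLS oracle: solve X'X b = X'y directly; R^2 from the
# squared-correlation formula.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  r2 <- sum((x - mean(x)) * (y - mean(y)))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  list(intercept = b[1L], slope = b[2L], r_squared = r2)
}

# A reduced 120 x 100 scene geometry for fast per-operation tests; volumes up
# to ~3 uL keep the column inside the drawn tip.
small_scene <- function(...) {
  scene_spec(height = 120L, width = 100L, apex_row = 100L, apex_col = 50L,
             tip_top_row = 18L, holder_rows = c(2L, 10L), holder_cols = c(10L, 90L),
             ...)
}

small_config <- function(...) {
  pipeline_config(tip_roi = roi_spec(13L, 105L, 1L, 100L),
                  holder_roi = roi_spec(1L, 12L, 1L, 100L), ...)
}

# Full-size default config used by end-to-end tests.
default_config <- function(...) pipeline_config(...)

measure_render <- function(render, config = default_config()) {
  measure_tip(render$image, config)
}

# Calibration object with bit-exact slope/intercept (bypasses lm's QR noise,
# needed when a test sits exactly on a decision boundary).
new_cal <- function(slope, intercept) {
  structure(list(slope = slope, intercept = intercept, r_squared = 1,
                 transform = "cubed volume length", n = 2L, fit = NULL),
            class = "pump_calibration")
}

# Tiny solid RGB image.
flat_rgb <- function(r, g, b, h = 4L, w = 5L) {
  array(rep(c(r, g, b), each = h * w), dim = c(h, w, 3L))
}
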