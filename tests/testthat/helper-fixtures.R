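# Shared fixtures. The spline PSF model is expensive to build (~10 s), so
# it is constructed once per test run from a noise-free calibration stack
# rendered with the default defocus curves, and cached.

fixture_env <- new.env()

test_curves <- function() gaussian_defocus_curves()

test_psf_model <- function() {
  if (is.null(fixture_env$model)) {
    cal <- render_calibration_stack(test_curves(), n_beads = 5,
                                    noise = FALSE, background = 0, seed = 2)
    fixture_env$model <- suppressMessages(
      build_psf_model(cal$stack, detection_threshold = 50))
  }
  fixture_env$model
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# synthetic localization table for tracking tests: positions [beads x 3],
# optional per-frame displacement function disp(t) -> n x 3 matrix
make_locs <- function(pos, n_frames, disp = NULL, sd = 0) {
  do.call(rbind, lapply(seq_len(n_frames), function(t) {
    d <- if (is.null(disp)) matrix(0, nrow(pos), 3) else disp(t)
    data.frame(frame = t - 1L,
               x_nm = pos[, 1] + d[, 1] + rnorm(nrow(pos), 0, sd),
               y_nm = pos[, 2] + d[, 2] + rnorm(nrow(pos), 0, sd),
               z_nm = pos[, 3] + d[, 3] + rnorm(nrow(pos), 0, sd))
  }))
}

# force-balanced Gaussian traction spot pattern on an n x n grid (Pa)
balanced_spots <- function(n, h) {
  xo <- (seq_len(n) - 0.5) * h
  L <- n * h
  cx <- L / 2
  g <- function(x0, y0, s, A)
    A * outer(exp(-(xo - y0)^2 / (2 * s^2)),
              exp(-(xo - x0)^2 / (2 * s^2)))
  list(Sx = g(cx - 2000, cx, 1000, 500) - g(cx + 2000, cx, 1000, 500),
       Sy = g(cx, cx - 2000, 1000, 300) - g(cx, cx + 2000, 1000, 300),
       Sz = g(cx - 1500, cx - 1500, 1000, 150) -
         g(cx + 1500, cx + 1500, 1000, 150),
       grid_spacing = h)
}
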