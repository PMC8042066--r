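test_that("spline model built from rendered beads reproduces the generating PSF", {
  cur <- test_curves()
  m <- test_psf_model()

  # calibration geometry: a 2 um stack at 10 nm steps gives 201 z-knots
  expect_length(m$z_knots, 201)
  expect_equal(range(m$z_knots), c(-1000, 1000))

  # round trip: model patches match direct evaluation of the generating
  # curves to < 1% of the peak across the working range, at off-centre
  # sub-pixel positions
  errs <- vapply(seq(-800, 800, by = 100), function(z) {
    P <- evaluate_psf(m, dx = 13, dy = -27, z = z, window = 21)
    Tr <- render_gaussian_psf(cur, dx = 13, dy = -27, z = z, photons = 1,
                              background = 0, window = 21)
    max(abs(P - Tr)) / max(Tr)
  }, 0)
  expect_lt(max(errs), 0.01)
})

test_that("a single centred bead averages to itself", {
  cur <- test_curves()
  cal <- render_calibration_stack(cur, n_beads = 1, image_px = 80,
                                  min_sep_px = 75, noise = FALSE,
                                  background = 0, seed = 5)
  m1 <- suppressMessages(build_psf_model(cal$stack, detection_threshold = 50))
  z <- 300
  P <- evaluate_psf(m1, 0, 0, z, window = 15)
  Tr <- render_gaussian_psf(cur, 0, 0, z, photons = 1, background = 0,
                            window = 15)
  expect_lt(max(abs(P - Tr)) / max(Tr), 0.01)
})

test_that("width difference is strictly monotone in z (z is decodable)", {
  m <- test_psf_model()
  sel <- abs(m$widths$z) <= 800
  expect_true(all(diff(m$widths$dw[sel]) > 0))
})

test_that("model evaluation is continuous and shift-equivariant", {
  m <- test_psf_model()
  # no jumps at knot boundaries: 0.1 nm z-step changes the patch by O(eps)
  p1 <- evaluate_psf(m, 5, 5, 123.05, window = 13)
  p2 <- evaluate_psf(m, 5, 5, 123.15, window = 13)
  expect_lt(max(abs(p2 - p1)) / max(p1), 1e-3)
  # shifting dx by one pixel shifts the patch by one column
  pa <- evaluate_psf(m, 0, 0, 200, window = 15)
  pb <- evaluate_psf(m, m$pixel_size, 0, 200, window = 15)
  expect_lt(max(abs(pb[, 2:15] - pa[, 1:14])) / max(pa), 1e-6)
})

test_that("normalized patches integrate to one", {
  m <- test_psf_model()
  for (z in c(-600, 0, 400))
    expect_equal(sum(evaluate_psf(m, 7, -9, z, window = 33)), 1,
                 tolerance = 1e-3)
})

test_that("evaluation outside the calibrated range fails explicitly", {
  m <- test_psf_model()
  expect_error(evaluate_psf(m, 0, 0, 1500), "outside the calibrated range")
  expect_error(crlb(m, 1000, z = -1200), "outside")
})

test_that("gaussian defocus rendering conserves flux and encodes z", {
  cur <- test_curves()
  # flux: 4 sigma window captures the photon budget to < 0.1%
  p <- render_gaussian_psf(cur, 0, 0, 0, photons = 1000, background = 0,
                           window = 19)
  expect_equal(sum(p), 1000, tolerance = 1e-3)
  # symmetric at the astigmatic midpoint
  w0 <- atfm:::patch_widths(render_gaussian_psf(cur, 0, 0, 0, photons = 1e4,
                                                background = 0,
                                                window = 21), 60.4)
  expect_equal(unname(w0["wx"]), unname(w0["wy"]), tolerance = 1e-3)
  # elongation flips between +z and -z
  s <- defocus_sigma(cur, c(300, -300))
  expect_gt(s$sx[1], s$sy[1])
  expect_lt(s$sx[2], s$sy[2])
  # widths intersect exactly once (sx = sy at the midpoint only)
  z <- seq(-900, 900, by = 10)
  d <- defocus_sigma(cur, z)
  expect_equal(sum(abs(diff(sign(d$sx - d$sy)))) / 2, 1)
  # uniform background reaches the corners of a wide window
  pb <- render_gaussian_psf(cur, 0, 0, 0, photons = 100, background = 10,
                            window = 25)
  expect_equal(pb[1, 1], 10, tolerance = 1e-3)
  # invalid width curves fail
  expect_error(gaussian_defocus_curves(focal_offset_x = 300,
                                       focal_offset_y = -300),
               "focal_offset_x")
})

test_that("bead detection errors and exclusions during model building", {
  cur <- test_curves()
  cal <- render_calibration_stack(cur, n_beads = 2, image_px = 170,
                                  min_sep_px = 80, noise = FALSE,
                                  background = 0, seed = 3)
  # no beads above an absurd threshold
  expect_error(suppressMessages(
    build_psf_model(cal$stack, detection_threshold = 1e9)), "no beads")
  # beads closer than twice the template size are excluded, the rest used
  z_knots <- seq(-1000, 1000, by = 10)
  vox <- array(0, c(260, 260, length(z_knots)))
  xs <- c(60.5, 120.5, 200.5) * 60.4  # first two only 60 px apart
  ys <- c(60.5, 60.5, 200.5) * 60.4
  for (k in seq_along(z_knots))
    vox[, , k] <- render_frame(260, 260, xs, ys, rep(z_knots[k], 3),
                               rep(5000, 3), 0, cur, 60.4, window_px = 41)
  stk <- psf_calibration_stack(vox, 10, 60.4)
  expect_message(m3 <- build_psf_model(stk, detection_threshold = 50),
                 "closer than 2 x roi_px")
  expect_equal(m3$meta$n_beads, 1)
})

test_that("PSF container round-trips and checks its version", {
  m <- test_psf_model()
  path <- tempfile(fileext = ".psf")
  write_psf_model(m, path)
  m2 <- read_psf_model(path)
  expect_identical(m2$coef, m$coef)
  expect_identical(m2$z_knots, m$z_knots)
  saveRDS(list(format = "atfm-psf", version = "99", model = m), path)
  expect_error(read_psf_model(path), "version mismatch")
  unlink(path)
})
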