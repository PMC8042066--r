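test_that("candidate detection finds isolated beads and applies the separation rule", {
  cur <- test_curves()
  # blank image: no candidates
  expect_equal(nrow(detect_candidates(matrix(0, 50, 50), 10)), 0)
  # two beads 20 px apart are both found within 1 px
  img <- render_frame(64, 64, c(20.5, 40.5) * 60.4, c(32.5, 32.5) * 60.4,
                      c(0, 0), c(5000, 5000), 0, cur, 60.4)
  cand <- detect_candidates(img, 50, min_separation = 7)
  expect_equal(nrow(cand), 2)
  expect_true(all(abs(cand$col - c(21, 41)) <= 1))
  expect_true(all(abs(cand$row - 33) <= 1))
  # two resolvable beads closer than the separation: both suppressed
  img2 <- render_frame(64, 64, c(28.5, 34.5) * 60.4, c(32.5, 32.5) * 60.4,
                       c(0, 0), c(5000, 5000), 0, cur, 60.4)
  expect_equal(nrow(detect_candidates(img2, 50, min_separation = 7)), 0)
  expect_equal(nrow(detect_candidates(img2, 50, min_separation = 4)), 2)
  expect_error(detect_candidates(img - 10, 50), "negative")
})

test_that("noiseless fits recover the ground-truth position to < 1 nm", {
  cur <- test_curves()
  m <- test_psf_model()
  x_true <- 12.5 * 60.4 + 37.2
  y_true <- 12.5 * 60.4 - 81.0
  img <- render_frame(25, 25, x_true, y_true, 250, 5000, 2, cur, 60.4)
  loc <- suppressMessages(
    fit_mle(img, m, detect_candidates(img, 50), window = 13))
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$x_nm - x_true), 1)
  expect_lt(abs(loc$y_nm - y_true), 1)
  expect_lt(abs(loc$z_nm - 250), 1)
  expect_equal(loc$photons, 5000, tolerance = 0.01)
})

test_that("fits are translation-equivariant under integer pixel shifts", {
  cur <- test_curves()
  m <- test_psf_model()
  img <- render_frame(31, 31, 15.5 * 60.4 + 11, 15.5 * 60.4 - 7, 150,
                      5000, 2, cur, 60.4)
  set.seed(4)
  img <- matrix(rpois(length(img), img), nrow(img))
  shifted <- img * 0
  shifted[, 2:31] <- img[, 1:30]  # shift content +1 column (+x)
  l1 <- suppressMessages(fit_mle(img, m, data.frame(row = 16, col = 16)))
  l2 <- suppressMessages(fit_mle(shifted, m, data.frame(row = 16, col = 17)))
  expect_lt(abs((l2$x_nm - l1$x_nm) - 60.4), 0.1)
  expect_lt(abs(l2$y_nm - l1$y_nm), 0.1)
})

test_that("converged fits do not decrease the likelihood and z is unbiased at focus", {
  cur <- test_curves()
  m <- test_psf_model()
  set.seed(11)
  zs <- numeric(150)
  for (i in seq_along(zs)) {
    img <- render_gaussian_psf(cur, 0, 0, 0, photons = 5000,
                               background = 10, window = 13)
    noisy <- matrix(rpois(length(img), img), nrow(img))
    init <- atfm:::moment_init(noisy, 60.4, m$z_lookup, c(-900, 900))
    fit <- atfm:::cpp_fit_mle(noisy, m$coef, m$nf, 200, m$z_min, m$z_step,
                              m$fine_step, 60.4, init, c(-900, 900), 50L,
                              0.01)
    expect_gte(fit$loglik, fit$loglik_init - 1e-6)
    zs[i] <- fit$par[3]
  }
  cr <- crlb(m, 5000, 10, 0)
  expect_lt(abs(mean(zs)), cr["sigma_z"])
})

test_that("CRLB scales with photons and background as Fisher information dictates", {
  m <- test_psf_model()
  # with no background, doubling the photons scales every bound by exactly
  # 1/sqrt(2); a fixed background makes the gain slightly better than that
  # (the signal-to-background ratio improves too), never worse
  l0 <- crlb(m, 2000, 0, z = 100)
  h0 <- crlb(m, 4000, 0, z = 100)
  expect_equal(unname(h0 / l0), rep(1 / sqrt(2), 3), tolerance = 1e-6)
  lo <- crlb(m, 2000, 20, z = 100)
  hi <- crlb(m, 4000, 20, z = 100)
  ratio <- hi / lo
  expect_true(all(ratio > 0.5 & ratio <= 1 / sqrt(2) + 1e-6))
  # background inflates every axis
  noisy <- crlb(m, 2000, 50, z = 100)
  expect_true(all(noisy > lo))
  # axial bound exceeds the lateral bounds at focus
  c0 <- crlb(m, 5000, 2, z = 0)
  expect_gt(c0["sigma_z"], c0["sigma_x"])
  expect_gt(c0["sigma_z"], c0["sigma_y"])
})

test_that("overlap filtering removes close pairs symmetrically", {
  locs <- data.frame(frame = c(0, 0, 0), x_nm = c(0, 400, 5000),
                     y_nm = c(0, 0, 0))
  out <- filter_overlaps(locs, 700)
  expect_equal(nrow(out), 1)
  expect_equal(out$x_nm, 5000)
  # different frames do not interact
  locs2 <- data.frame(frame = c(0, 1), x_nm = c(0, 100), y_nm = c(0, 0))
  expect_equal(nrow(filter_overlaps(locs2, 700)), 2)
  expect_error(filter_overlaps(locs, -1))
})

test_that("surviving density stays at or below the nominal bead density", {
  scene <- generate_scene(synthetic_scene(fov_um = c(20, 20), seed = 8,
                                          n_frames = 1))
  locs <- data.frame(frame = 0, x_nm = scene$beads$x_nm,
                     y_nm = scene$beads$y_nm)
  out <- filter_overlaps(locs, 731)
  expect_lte(nrow(out) / 400, 0.3)
})
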