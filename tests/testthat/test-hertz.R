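test_that("Hertzian surface displacement has the closed-form values and branch continuity", {
  P <- 3e-9; E <- 250; a <- 3e-6
  # central displacement 3P/(4Ea) = 3 um for the calibration parameters
  expect_equal(hertz_uz(0, P = P, E = E, a = a), 3e-6)
  # both branches meet at r = a with value 3P/(8Ea)
  expect_equal(hertz_uz(a, P = P, E = E, a = a), 3 * P / (8 * E * a),
               tolerance = 1e-12)
  expect_equal(hertz_uz(a * (1 + 1e-9), P = P, E = E, a = a),
               hertz_uz(a, P = P, E = E, a = a), tolerance = 1e-6)
  # monotone decay and far field
  r <- seq(0, 300e-6, length.out = 2000)
  uz <- hertz_uz(r, P = P, E = E, a = a)
  expect_true(all(diff(uz) <= 1e-15))
  expect_lt(hertz_uz(100 * a, P = P, E = E, a = a), 0.01 * hertz_uz(0, P = P, E = E, a = a))
  expect_error(hertz_uz(-1e-6, P = P, E = E, a = a), "negative")
})

test_that("sphere load has the closed form and its scalings", {
  F <- sphere_load(70e-6, 2650, 1000, 9.81)
  expect_equal(F * 1e9, 2.907, tolerance = 1e-3)
  expect_equal(sphere_load(70e-6, 1000, 1000), 0)
  expect_equal(sphere_load(140e-6) / sphere_load(70e-6), 8)
  Fb <- sphere_load(70e-6, 800, 1000)
  expect_lt(Fb, 0)
  expect_true(isTRUE(attr(Fb, "buoyant")))
})

test_that("Hertz fits recover load and contact radius", {
  P <- 3e-9; E <- 250; a <- 3e-6
  r <- seq(0, 20e-6, length.out = 300)
  uz <- hertz_uz(r, P = P, E = E, a = a)
  fit <- fit_hertz(r, uz, E)
  expect_lt(abs(fit$P - P) / P, 1e-3)
  expect_lt(abs(fit$a - a) / a, 1e-3)
  # linearity in P: doubling the profile doubles the fitted load
  fit2 <- fit_hertz(r, 2 * uz, E)
  expect_equal(fit2$P / fit$P, 2, tolerance = 1e-6)
  # Monte Carlo with 50 nm height noise: mean load within 5%
  set.seed(9)
  Ps <- replicate(30, fit_hertz(r, uz + rnorm(length(r), 0, 50e-9), E)$P)
  expect_lt(abs(mean(Ps) - P) / P, 0.05)
  # degenerate profiles are flagged
  expect_warning(fit_hertz(r[r > 5e-6], uz[r > 5e-6], E,
                           start = list(P = P, a = a)), "one side")
  expect_error(fit_hertz(r[1:5], uz[1:5], E), "at least 10")
})

test_that("piezo z-stack stitching reconstructs extended surfaces", {
  # flat surface, arbitrary piezo trajectory: constant height recovered;
  # beads on a jittered grid, well separated compared to the cluster gate
  set.seed(10)
  gpos <- expand.grid(gx = seq(1e3, 1.9e4, by = 3e3),
                      gy = seq(1e3, 1.9e4, by = 3e3))[1:30, ]
  nb <- 30
  x <- gpos$gx + runif(nb, -500, 500)
  y <- gpos$gy + runif(nb, -500, 500)
  piezo <- seq(-600, 600, by = 300)
  slices <- lapply(piezo, function(p)
    data.frame(x_nm = x, y_nm = y, z_nm = 120 - p, crlb_z = 10))
  surf <- stitch_zstack(slices, piezo)
  expect_equal(nrow(surf), nb)
  expect_true(all(abs(surf$height_nm - 120) < 1e-9))

  # single slice at zero piezo: heights equal the localized z
  s1 <- stitch_zstack(list(data.frame(x_nm = x, y_nm = y, z_nm = 120 - x / 1e3,
                                      crlb_z = 10)), 0)
  expect_equal(sort(s1$height_nm), sort(120 - x / 1e3))

  # 3 um deep synthetic surface sampled at 100 nm piezo steps with noisy
  # per-slice localizations: 25 nm RMS reconstruction
  heights <- -3000 * exp(-((x - 1e4)^2 + (y - 1e4)^2) / (2 * 6000^2))
  piezo <- seq(-3200, 400, by = 100)
  slices <- lapply(piezo, function(p) {
    z <- heights - p
    vis <- abs(z) <= 900
    data.frame(x_nm = x[vis], y_nm = y[vis],
               z_nm = z[vis] + rnorm(sum(vis), 0, 15),
               crlb_z = 15)
  })
  surf <- suppressMessages(stitch_zstack(slices, piezo))
  idx <- vapply(seq_len(nrow(surf)), function(i)
    which.min((x - surf$x_nm[i])^2 + (y - surf$y_nm[i])^2), 0L)
  err <- surf$height_nm - heights[idx]
  expect_lt(sqrt(mean(err^2)), 25)
})

test_that("indentation profiles locate the centre and baseline", {
  set.seed(12)
  P <- sphere_load(70e-6); E <- 250; a <- 3e-6
  nb <- 400
  x <- runif(nb, 0, 4e4); y <- runif(nb, 0, 4e4)
  ctr <- c(2.1e4, 1.9e4)
  r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2) * 1e-9
  h <- -hertz_uz(r, P = P, E = E, a = a) * 1e9 + rnorm(nb, 0, 22)
  prof <- indentation_profile(data.frame(x_nm = x, y_nm = y, height_nm = h))
  expect_lt(max(abs(attr(prof, "center") - ctr)), 500)
  fit <- fit_indentation(data.frame(x_nm = x, y_nm = y, height_nm = h), E)
  expect_lt(abs(fit$P - P) / P, 0.07)
})
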