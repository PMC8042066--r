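test_that("forward solver matches the Boussinesq point-load solution", {
  gel <- gel_properties(1e4, 0.495)
  n <- 96; h <- 100
  Sz <- matrix(0, n, n)
  Sz[n / 2, n / 2] <- 1e-9 / (h * 1e-9)^2  # 1 nN over one cell
  tr <- list(Sx = matrix(0, n, n), Sy = matrix(0, n, n), Sz = Sz,
             grid_spacing = h)
  u <- displacement_from_traction(tr, gel, pad_factor = 4)
  closed <- function(r_m) 1e-9 * (1 - 0.495^2) / (pi * 1e4 * r_m) * 1e9
  expect_equal(u$uz[n / 2, n / 2 + 10], closed(1e-6), tolerance = 0.02)
  expect_equal(u$uz[n / 2 + 10, n / 2 + 10], closed(sqrt(2) * 1e-6),
               tolerance = 0.02)
  expect_equal(u$uz[n / 2, n / 2 + 30], closed(3e-6), tolerance = 0.02)
  # zero traction, zero displacement; linearity
  z0 <- displacement_from_traction(list(Sx = Sz * 0, Sy = Sz * 0, Sz = Sz * 0,
                                        grid_spacing = h), gel)
  expect_equal(max(abs(z0$uz)), 0)
  tr3 <- list(Sx = Sz, Sy = Sz * 0, Sz = 3 * Sz, grid_spacing = h)
  u3 <- displacement_from_traction(tr3, gel, pad_factor = 4)
  u1 <- displacement_from_traction(list(Sx = Sz / 3, Sy = Sz * 0, Sz = Sz,
                                        grid_spacing = h), gel,
                                   pad_factor = 4)
  expect_equal(u3$uz, 3 * u1$uz, tolerance = 1e-10)
})

test_that("traction inversion round-trips force-balanced spot patterns", {
  gel <- gel_properties(1e4, 0.495)
  T0 <- balanced_spots(256, 100)
  u <- displacement_from_traction(T0, gel)
  u$grid_spacing <- 100
  Th <- traction_from_displacement(u, gel, regularization = 0)
  num <- sum((Th$Sx - T0$Sx)^2 + (Th$Sy - T0$Sy)^2 + (Th$Sz - T0$Sz)^2)
  den <- sum(T0$Sx^2 + T0$Sy^2 + T0$Sz^2)
  expect_lt(sqrt(num / den), 0.05)
  # zero in, zero out
  z <- traction_from_displacement(list(ux = T0$Sx * 0, uy = T0$Sx * 0,
                                       uz = T0$Sx * 0, grid_spacing = 100),
                                  gel)
  expect_equal(max(abs(z$Sz)), 0)
  # a rigid lateral shift of the whole field leaves the stresses unchanged
  ush <- list(ux = u$ux + 250, uy = u$uy - 100, uz = u$uz + 40,
              grid_spacing = 100)
  Tsh <- traction_from_displacement(ush, gel)
  expect_equal(Tsh$Sx, Th$Sx, tolerance = 1e-8)
  expect_equal(Tsh$Sz, Th$Sz, tolerance = 1e-8)
})

test_that("stresses scale linearly with the gel modulus", {
  T0 <- balanced_spots(96, 200)
  gel1 <- gel_properties(1e4)
  gel3 <- gel_properties(3e4)
  u <- displacement_from_traction(T0, gel1)
  u$grid_spacing <- 200
  S1 <- traction_from_displacement(u, gel1)
  S3 <- traction_from_displacement(u, gel3)
  expect_equal(S3$Sx, 3 * S1$Sx, tolerance = 1e-10)
  expect_equal(S3$Sz, 3 * S1$Sz, tolerance = 1e-10)
})

test_that("normal/tangential coupling vanishes in the incompressible limit", {
  n <- 96; h <- 200
  xo <- (1:n - 0.5) * h
  g <- outer(exp(-(xo - n * h / 2)^2 / (2 * 1500^2)),
             exp(-(xo - n * h / 2)^2 / (2 * 1500^2)))
  tr <- list(Sx = 0 * g, Sy = 0 * g, Sz = 150 * g, grid_spacing = h)
  gel <- gel_properties(1e4, 0.4999)
  u <- displacement_from_traction(tr, gel)
  # normal load produces essentially no lateral surface motion
  expect_lt(max(abs(u$ux)) / max(abs(u$uz)), 5e-3)
  # and uz agrees with the decoupled normal-only (Boussinesq) convolution
  K <- atfm:::hs_kernels(192, 192, h * 1e-9, gel$E, gel$nu)
  q <- stats::fft(atfm:::pad_matrix(tr$Sz, 192, 192))
  uz_dec <- Re(stats::fft(K$Gzz * q, inverse = TRUE))[1:n, 1:n] / (192^2)
  expect_equal(u$uz, uz_dec * 1e9, tolerance = 1e-6)
})

test_that("subsurface stress matches the surface at depth 0 and decays below", {
  gel <- gel_properties(1e4)
  T0 <- balanced_spots(96, 200)
  s0 <- subsurface_stress(T0, gel, 0)
  expect_equal(s0$Szz, T0$Sz, tolerance = 1e-10)
  expect_equal(s0$Szx, T0$Sx, tolerance = 1e-10)
  s12 <- subsurface_stress(T0, gel, 12)
  expect_lt(max(abs(s12$Szz)), 0.05 * max(abs(T0$Sz)))
  # axial stress under a normal point load decays monotonically with depth
  n <- 64
  Sz <- matrix(0, n, n); Sz[n / 2, n / 2] <- 1000
  trp <- list(Sx = Sz * 0, Sy = Sz * 0, Sz = Sz, grid_spacing = 200)
  ax <- vapply(c(0.5, 1, 2, 4), function(d)
    subsurface_stress(trp, gel, d, pad_factor = 4)$Szz[n / 2, n / 2], 0)
  expect_true(all(diff(ax) < 0) || all(diff(ax) > 0))
  expect_true(all(abs(ax) == sort(abs(ax), decreasing = TRUE)))
})

test_that("noise propagation is linear and respects its preconditions", {
  gel <- gel_properties(1e4)
  z <- propagate_noise(c(0, 0, 0), gel, n_reps = 50, n_grid = 32)
  expect_equal(z$sigma_shear, 0)
  expect_equal(z$sigma_normal, 0)
  a <- propagate_noise(c(5, 5, 10), gel, n_reps = 50, n_grid = 48, seed = 3)
  b <- propagate_noise(c(10, 10, 20), gel, n_reps = 50, n_grid = 48, seed = 3)
  expect_equal(b$sigma_shear / a$sigma_shear, 2, tolerance = 1e-10)
  expect_equal(b$sigma_normal / a$sigma_normal, 2, tolerance = 1e-10)
  expect_error(propagate_noise(c(1, 1, 1), gel, n_reps = 10), "n_reps")
})

test_that("TIRF geometry reproduces the printed critical angle and NA range", {
  g <- tirf_geometry()
  res <- tirf_maintained(g)
  expect_equal(round(res$critical_angle_deg, 1), 68.5)
  expect_equal(round(res$na_range[1], 3), 1.395)
  expect_equal(round(res$na_range[2], 2), 1.42)
  expect_true(res$maintained)
  # degenerate tilt
  res0 <- tirf_maintained(tirf_geometry(tilt_deg = 0))
  expect_equal(res0$na_range[1], res0$na_range[2])
  expect_equal(res0$na_range[1], 1.41, tolerance = 1e-12)
  expect_true(res0$maintained)
  # tilt derived from the deformation geometry when not given
  resd <- tirf_maintained(tirf_geometry(tilt_deg = NULL))
  expect_equal(resd$tilt_deg, atan(500e-9 / 15e-6) * 180 / pi)
  # invalid aperture
  expect_error(tirf_geometry(NA_max = 1.6), "NA_max")
})

test_that("gel properties enforce the physical Poisson range", {
  expect_error(gel_properties(1e4, 0.6), "Poisson")
  expect_error(gel_properties(1e4, 0), "Poisson")
  expect_error(gel_properties(-5), "E > 0")
})
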