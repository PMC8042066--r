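test_that("static beads link into complete constant trajectories", {
  set.seed(1)
  pos <- cbind(runif(10, 0, 2e4), runif(10, 0, 2e4), runif(10, -500, 500))
  locs <- make_locs(pos, 100)
  tr <- link_trajectories(locs, 500)
  comp <- trajectory_complete(tr)
  expect_length(comp, 10)
  expect_true(all(comp))
  sp <- split(tr$x_nm, tr$bead_id)
  expect_true(all(vapply(sp, function(x) diff(range(x)), 0) == 0))
})

test_that("a known flow is linked with the correct identities", {
  set.seed(2)
  n <- 40
  pos <- cbind(runif(n, 0, 3e4), runif(n, 0, 3e4), runif(n, -300, 300))
  flow <- function(t) cbind(rep(50 * (t - 1), n), rep(-30 * (t - 1), n),
                            rep(20 * (t - 1), n))
  locs <- make_locs(pos, 30, disp = flow, sd = 3)
  tr <- link_trajectories(locs, 300)
  expect_true(all(trajectory_complete(tr)))
  # identity check: each trajectory starts and ends near the same bead
  tr0 <- tr[tr$frame == 0, ]
  trN <- tr[tr$frame == 29, ]
  trN <- trN[match(tr0$bead_id, trN$bead_id), ]
  dx <- trN$x_nm - tr0$x_nm
  expect_true(all(abs(dx - 50 * 29) < 20))
})

test_that("a disappearing bead yields an incomplete trajectory excluded from fields", {
  set.seed(3)
  pos <- cbind(runif(9, 1e3, 1.9e4), runif(9, 1e3, 1.9e4), rep(0, 9))
  locs <- make_locs(pos, 60)
  locs <- locs[!(locs$frame >= 50 &
                   abs(locs$x_nm - pos[1, 1]) < 1e-6), ]
  tr <- link_trajectories(locs, 500)
  comp <- trajectory_complete(tr)
  expect_equal(sum(!comp), 1)
  f <- displacement_field(tr, grid_spacing = 500, spatial_median_width = 2)
  expect_true(all(f$uz[, , 10] == 0 | is.na(f$uz[, , 10])))
})

test_that("drift correction cancels rigid drift exactly and preserves real motion", {
  set.seed(4)
  n <- 8
  pos <- cbind(runif(n, 0, 2e4), runif(n, 0, 2e4), runif(n, -200, 200))
  drift <- function(t) {
    d <- cbind(rep(5 * (t - 1), n), rep(-3 * (t - 1), n), rep(2 * (t - 1), n))
    d[1, ] <- d[1, ] + c(10 * (t - 1), 0, 0)  # bead 1 also really moves
    d
  }
  locs <- make_locs(pos, 50, disp = drift)
  tr <- link_trajectories(locs, 500)
  moving_id <- tr$bead_id[tr$frame == 0][
    which.min(abs(tr$x_nm[tr$frame == 0] - pos[1, 1]))]
  refs <- setdiff(unique(tr$bead_id), moving_id)
  cor <- drift_correct(tr, refs)
  # reference beads static to numerical precision
  ref_rows <- cor[cor$bead_id %in% refs, ]
  sp <- split(ref_rows$x_nm, ref_rows$bead_id)
  expect_lt(max(vapply(sp, function(x) diff(range(x)), 0)), 1e-9)
  # the moving bead's own motion is preserved exactly
  mb <- cor[cor$bead_id == moving_id, ]
  expect_equal(mb$x_nm[50] - mb$x_nm[1], 10 * 49, tolerance = 1e-9)
  # zero drift: identity
  locs0 <- make_locs(pos, 10)
  tr0 <- link_trajectories(locs0, 500)
  cor0 <- drift_correct(tr0, unique(tr0$bead_id))
  expect_equal(cor0$x_nm, tr0$x_nm, tolerance = 1e-12)
  expect_error(drift_correct(tr, refs[1:2]), "at least 3")
})

test_that("temporal median removes spikes and passes constants and ramps", {
  pos <- cbind(c(0, 1e4, 2e4), c(0, 1e4, 2e4), c(0, 0, 0))
  locs <- make_locs(pos, 40)
  tr <- link_trajectories(locs, 500)
  # constant: unchanged
  expect_equal(temporal_median(tr, 10)$x_nm, tr$x_nm)
  # single-frame 200 nm spike in z: removed
  spiked <- tr
  hit <- which(spiked$bead_id == 1 & spiked$frame == 20)
  spiked$z_nm[hit] <- 200
  filt <- temporal_median(spiked, 10)
  expect_lt(max(abs(filt$z_nm)), 1e-9)
  # linear ramp: unchanged in the interior
  ramp <- tr
  ramp$x_nm <- ramp$x_nm + 7 * ramp$frame
  rf <- temporal_median(ramp, 9)
  interior <- ramp$frame >= 5 & ramp$frame <= 34
  expect_equal(rf$x_nm[interior], ramp$x_nm[interior])
})

test_that("ensemble displacement uncertainty matches the injected noise", {
  # noiseless static scene: exactly zero
  pos <- cbind(runif(5, 0, 1e4), runif(5, 0, 1e4), rep(0, 5))
  tr0 <- link_trajectories(make_locs(pos, 20), 500)
  u0 <- estimate_uncertainty(tr0, 20)
  expect_equal(c(u0$sigma_x, u0$sigma_y, u0$sigma_z), c(0, 0, 0))

  # injected per-frame noise (4, 4, 7) nm: displacement relative to frame 0
  # is a difference of two noisy positions, so sqrt(2) * sigma per axis
  set.seed(6)
  n <- 50
  pos <- cbind(runif(n, 0, 5e4), runif(n, 0, 5e4), runif(n, -300, 300))
  locs <- do.call(rbind, lapply(1:100, function(t)
    data.frame(frame = t - 1L, bead = seq_len(n),
               x_nm = pos[, 1] + rnorm(n, 0, 4),
               y_nm = pos[, 2] + rnorm(n, 0, 4),
               z_nm = pos[, 3] + rnorm(n, 0, 7))))
  locs$bead <- NULL
  tr <- link_trajectories(locs, 500)
  u <- estimate_uncertainty(tr, 100)
  expect_equal(u$n_beads, n)
  expect_lt(abs(u$sigma_x - sqrt(2) * 4) / (sqrt(2) * 4), 0.15)
  expect_lt(abs(u$sigma_y - sqrt(2) * 4) / (sqrt(2) * 4), 0.15)
  expect_lt(abs(u$sigma_z - sqrt(2) * 7) / (sqrt(2) * 7), 0.15)

  # a high-noise condition dominates a low-noise one component-wise
  set.seed(7)
  locs_hi <- do.call(rbind, lapply(1:100, function(t)
    data.frame(frame = t - 1L,
               x_nm = pos[, 1] + rnorm(n, 0, 9),
               y_nm = pos[, 2] + rnorm(n, 0, 9),
               z_nm = pos[, 3] + rnorm(n, 0, 22))))
  u_hi <- estimate_uncertainty(link_trajectories(locs_hi, 500), 100)
  expect_gt(u_hi$sigma_x, u$sigma_x)
  expect_gt(u_hi$sigma_y, u$sigma_y)
  expect_gt(u_hi$sigma_z, u$sigma_z)
  expect_gt(u_hi$sigma_z, u_hi$sigma_x)
})

test_that("displacement fields reproduce constant and smooth ground truth", {
  set.seed(8)
  # constant displacement: constant field inside the hull
  n <- 60
  pos <- cbind(runif(n, 0, 2e4), runif(n, 0, 2e4), rep(0, n))
  disp <- function(t) if (t == 1) matrix(0, n, 3) else
    matrix(rep(c(100, -50, 30), each = n), n, 3)
  tr <- link_trajectories(make_locs(pos, 3, disp = disp), 500)
  f <- displacement_field(tr, grid_spacing = 500, spatial_median_width = 4)
  expect_true(all(abs(f$ux[, , 3][f$valid] - 100) < 1e-9))
  expect_true(all(abs(f$uy[, , 3][f$valid] + 50) < 1e-9))
  expect_true(all(abs(f$uz[, , 3][f$valid] - 30) < 1e-9))
  # frame 0: identically zero
  expect_true(all(f$ux[, , 1][f$valid] == 0))

  # smooth Gaussian bump (sigma 2 um, 150 nm) sampled at 0.3 beads/um^2:
  # RMS field error < 10% of the peak
  fov <- 30e3
  nb <- round(0.3 * 30 * 30)
  pos <- cbind(runif(nb, 0, fov), runif(nb, 0, fov), rep(0, nb))
  bump <- function(x, y) 150 * exp(-((x - fov / 2)^2 + (y - fov / 2)^2) /
                                     (2 * 2000^2))
  disp <- function(t) cbind(rep(0, nb), rep(0, nb),
                            if (t == 1) rep(0, nb)
                            else bump(pos[, 1], pos[, 2]))
  tr <- link_trajectories(make_locs(pos, 2, disp = disp), 1e4)
  f <- displacement_field(tr, grid_spacing = 302, spatial_median_width = 2)
  truth <- outer(f$y, f$x, function(y, x) bump(x, y))
  err <- f$uz[, , 2] - truth
  expect_lt(sqrt(mean(err[f$valid]^2)), 15)
})

test_that("default spatial median footprint is 604 nm", {
  cfg <- atfm_config()
  expect_equal(cfg$spatial_median_width * cfg$grid_spacing, 604)
})
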