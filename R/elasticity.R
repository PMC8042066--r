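# Linear-elastic half-space solver. Surface displacements and surface
# tractions are related by convolution with the Boussinesq-Cerruti surface
# Green's tensor; the convolution is evaluated spectrally on a zero-padded
# grid using the FFT of the real-space-sampled tensor (with analytic cell
# integrals at the singular cell), so a point load reproduces the
# closed-form solutions and forward and inverse maps are exactly mutually
# inverse. Fields are matrices [ny, nx] (rows = y); stresses in Pa,
# displacements in nm at the interface, SI internally.

#' Gel material properties
#'
#' @param E elastic modulus (Pa).
#' @param nu Poisson's ratio; the silicone gels are nearly incompressible
#'   (default 0.495). Must satisfy 0 < nu < 0.5.
#' @param thickness gel thickness (um), metadata only (the solver assumes a
#'   semi-infinite substrate).
#' @return Object of class `gel_properties`.
#' @export
gel_properties <- function(E, nu = 0.495, thickness = NULL) {
  stopifnot(E > 0)
  if (nu <= 0 || nu >= 0.5)
    stop("Poisson's ratio must lie strictly between 0 and 0.5")
  structure(list(E = E, nu = nu, thickness = thickness),
            class = "gel_properties")
}

# wrapped lattice coordinates of an FFT grid
fft_coords <- function(n) {
  i <- 0:(n - 1)
  i[i > n / 2] <- i[i > n / 2] - n
  i
}

# FFT of the sampled surface Green's tensor on a (pr x pc) grid with
# spacing h (m); the singular cell uses the analytic cell average
# (integral of 1/r over a centred square of side h is 4 asinh(1) h)
hs_kernels <- function(pr, pc, h, E, nu) {
  X <- outer(rep(1, pr), fft_coords(pc)) * h
  Y <- outer(fft_coords(pr), rep(1, pc)) * h
  R2 <- X^2 + Y^2
  R2[1, 1] <- 1
  R <- sqrt(R2)
  Cs <- 4 * asinh(1)
  pref <- (1 + nu) / (pi * E)
  Gxx <- pref * ((1 - nu) / R + nu * X^2 / (R2 * R))
  Gyy <- pref * ((1 - nu) / R + nu * Y^2 / (R2 * R))
  Gxy <- pref * nu * X * Y / (R2 * R)
  Gzz <- (1 - nu^2) / (pi * E) / R
  czx <- (1 + nu) * (1 - 2 * nu) / (2 * pi * E)
  Gzx <- czx * X / R2
  Gzy <- czx * Y / R2
  Gxx[1, 1] <- pref * (1 - nu / 2) * Cs / h
  Gyy[1, 1] <- pref * (1 - nu / 2) * Cs / h
  Gzz[1, 1] <- (1 - nu^2) / (pi * E) * Cs / h
  Gxy[1, 1] <- 0; Gzx[1, 1] <- 0; Gzy[1, 1] <- 0
  k <- lapply(list(Gxx = Gxx, Gyy = Gyy, Gxy = Gxy, Gzz = Gzz,
                   Gzx = Gzx, Gzy = Gzy),
              function(g) stats::fft(g) * h^2)
  k$pr <- pr; k$pc <- pc; k$h <- h
  k
}

pad_matrix <- function(m, pr, pc) {
  out <- matrix(0, pr, pc)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# u (m) on the padded grid from traction (Pa) on the padded grid
hs_forward <- function(K, Sx, Sy, Sz) {
  qx <- stats::fft(Sx); qy <- stats::fft(Sy); qz <- stats::fft(Sz)
  np <- K$pr * K$pc
  ux <- Re(stats::fft(K$Gxx * qx + K$Gxy * qy - K$Gzx * qz,
                      inverse = TRUE)) / np
  uy <- Re(stats::fft(K$Gxy * qx + K$Gyy * qy - K$Gzy * qz,
                      inverse = TRUE)) / np
  uz <- Re(stats::fft(K$Gzx * qx + K$Gzy * qy + K$Gzz * qz,
                      inverse = TRUE)) / np
  list(ux = ux, uy = uy, uz = uz)
}

# vectorised complex 3x3 Cramer solve of A q = b (elementwise over matrices)
solve3 <- function(A11, A12, A13, A21, A22, A23, A31, A32, A33,
                   b1, b2, b3) {
  m11 <- A22 * A33 - A23 * A32
  m12 <- A21 * A33 - A23 * A31
  m13 <- A21 * A32 - A22 * A31
  det <- A11 * m11 - A12 * m12 + A13 * m13
  det[Mod(det) < 1e-300] <- 1
  q1 <- (b1 * m11 - A12 * (b2 * A33 - A23 * b3) +
           A13 * (b2 * A32 - A22 * b3)) / det
  q2 <- (A11 * (b2 * A33 - A23 * b3) - b1 * m12 +
           A13 * (A21 * b3 - b2 * A31)) / det
  q3 <- (A11 * (A22 * b3 - b2 * A32) - A12 * (A21 * b3 - b2 * A31) +
           b1 * m13) / det
  list(q1, q2, q3)
}

# traction (Pa) on the padded grid from u (m) on the padded grid;
# regularization adds zeroth-order (Tikhonov) damping scaled by the peak
# kernel magnitude
hs_inverse <- function(K, ux, uy, uz, regularization = 0) {
  b1 <- stats::fft(ux); b2 <- stats::fft(uy); b3 <- stats::fft(uz)
  A11 <- K$Gxx; A12 <- K$Gxy; A13 <- -K$Gzx
  A21 <- K$Gxy; A22 <- K$Gyy; A23 <- -K$Gzy
  A31 <- K$Gzx; A32 <- K$Gzy; A33 <- K$Gzz
  if (regularization > 0) {
    al <- (regularization * max(Mod(K$Gzz)))^2
    # normal equations: (A^H A + al I) q = A^H b
    H11 <- Conj(A11) * A11 + Conj(A21) * A21 + Conj(A31) * A31 + al
    H12 <- Conj(A11) * A12 + Conj(A21) * A22 + Conj(A31) * A32
    H13 <- Conj(A11) * A13 + Conj(A21) * A23 + Conj(A31) * A33
    H22 <- Conj(A12) * A12 + Conj(A22) * A22 + Conj(A32) * A32 + al
    H23 <- Conj(A12) * A13 + Conj(A22) * A23 + Conj(A32) * A33
    H33 <- Conj(A13) * A13 + Conj(A23) * A23 + Conj(A33) * A33 + al
    r1 <- Conj(A11) * b1 + Conj(A21) * b2 + Conj(A31) * b3
    r2 <- Conj(A12) * b1 + Conj(A22) * b2 + Conj(A32) * b3
    r3 <- Conj(A13) * b1 + Conj(A23) * b2 + Conj(A33) * b3
    q <- solve3(H11, H12, H13, Conj(H12), H22, H23, Conj(H13), Conj(H23),
                H33, r1, r2, r3)
  } else {
    q <- solve3(A11, A12, A13, A21, A22, A23, A31, A32, A33, b1, b2, b3)
  }
  # the rigid-body (k = 0) mode is unobservable
  q[[1]][1, 1] <- 0; q[[2]][1, 1] <- 0; q[[3]][1, 1] <- 0
  np <- K$pr * K$pc
  list(Sx = Re(stats::fft(q[[1]], inverse = TRUE)) / np,
       Sy = Re(stats::fft(q[[2]], inverse = TRUE)) / np,
       Sz = Re(stats::fft(q[[3]], inverse = TRUE)) / np)
}

# 1D Tukey taper: unity in the interior, cosine ramps over `frac` of the
# length at each border
tukey_taper <- function(n, frac = 0.1) {
  w <- rep(1, n)
  m <- max(1, round(frac * n))
  if (2 * m >= n) return(0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  ramp <- 0.5 - 0.5 * cos(pi * (seq_len(m) - 0.5) / m)
  w[seq_len(m)] <- ramp
  w[n + 1 - seq_len(m)] <- ramp
  w
}

as_field_matrices <- function(field, t = NULL) {
  if (inherits(field, "displacement_field")) {
    if (is.null(t)) t <- dim(field$ux)[3]
    list(ux = field$ux[, , t], uy = field$uy[, , t], uz = field$uz[, , t],
         grid_spacing = field$grid_spacing, x = field$x, y = field$y)
  } else field
}

#' Surface displacement of a half-space under a surface traction
#'
#' Forward elastic problem: spectral convolution of the traction field with
#' the Boussinesq-Cerruti surface Green's tensor of a linear-elastic,
#' nearly incompressible half-space (normal/tangential coupling included
#' for nu < 0.5). The traction must be compactly supported on the grid;
#' zero padding suppresses wrap-around.
#'
#' @param traction list (or `stress_field`) with matrices `Sx`, `Sy`
#'   (shear, Pa) and `Sz` (normal, Pa), plus `grid_spacing` (nm) unless
#'   given separately.
#' @param gel a [gel_properties()] object.
#' @param grid_spacing grid pitch (nm); defaults to `traction$grid_spacing`.
#' @param pad_factor zero-padding factor.
#' @return List with `ux`, `uy`, `uz` displacement matrices (nm) on the
#'   input grid.
#' @export
displacement_from_traction <- function(traction, gel,
                                       grid_spacing = traction$grid_spacing,
                                       pad_factor = 2) {
  stopifnot(inherits(gel, "gel_properties"), !is.null(grid_spacing))
  Sx <- traction$Sx; Sy <- traction$Sy; Sz <- traction$Sz
  if (any(!is.finite(Sx)) || any(!is.finite(Sy)) || any(!is.finite(Sz)))
    stop("traction field contains non-finite values")
  ny <- nrow(Sz); nx <- ncol(Sz)
  pr <- stats::nextn(ceiling(pad_factor * ny), c(2, 3))
  pc <- stats::nextn(ceiling(pad_factor * nx), c(2, 3))
  K <- hs_kernels(pr, pc, grid_spacing * 1e-9, gel$E, gel$nu)
  u <- hs_forward(K, pad_matrix(Sx, pr, pc), pad_matrix(Sy, pr, pc),
                  pad_matrix(Sz, pr, pc))
  lapply(u, function(m) m[seq_len(ny), seq_len(nx)] * 1e9)
}

#' Surface traction from a surface displacement field
#'
#' Inverse elastic problem: the surface Green's tensor is inverted in the
#' spectral domain, with optional zeroth-order Tikhonov damping
#' (`regularization = 0` is pure inversion; the median-filtered input is
#' already smooth). The mean displacement is subtracted per component
#' (rigid translation carries no strain), invalid (NA) grid points are
#' filled with zero displacement and a Tukey taper is applied to the field
#' borders before the transform.
#'
#' Sign convention: `Sz > 0` means the gel surface is pulled upward
#' (tension), matching `uz > 0` for upward displacement.
#'
#' @param field displacement as a list of matrices `ux`, `uy`, `uz` (nm)
#'   with `grid_spacing` (nm), or a [displacement_field()] (time point `t`).
#' @param gel a [gel_properties()] object.
#' @param regularization dimensionless damping; 0 = pure inversion.
#' @param t time index when `field` is a `displacement_field`.
#' @param grid_spacing grid pitch (nm); defaults to `field$grid_spacing`.
#' @param pad_factor zero-padding factor.
#' @param taper Tukey taper width fraction at each border.
#' @return Object of class `stress_field`: matrices `Sx`, `Sy` (shear, Pa)
#'   and `Sz` (normal, Pa) on the input grid, with `grid_spacing` and the
#'   validity mask of the input.
#' @export
traction_from_displacement <- function(field, gel, regularization = 0,
                                       t = NULL,
                                       grid_spacing = NULL,
                                       pad_factor = 2, taper = 0.1) {
  stopifnot(inherits(gel, "gel_properties"))
  f <- as_field_matrices(field, t)
  if (is.null(grid_spacing)) grid_spacing <- f$grid_spacing
  stopifnot(!is.null(grid_spacing))
  ny <- nrow(f$uz); nx <- ncol(f$uz)
  valid <- is.finite(f$ux) & is.finite(f$uy) & is.finite(f$uz)
  if (!any(valid)) stop("displacement field has no valid grid points")
  w2 <- outer(tukey_taper(ny, taper), tukey_taper(nx, taper))
  prep <- function(m) {
    mu <- mean(m[valid])
    m <- m - mu
    m[!valid] <- 0
    m * w2 * 1e-9
  }
  pr <- stats::nextn(ceiling(pad_factor * ny), c(2, 3))
  pc <- stats::nextn(ceiling(pad_factor * nx), c(2, 3))
  K <- hs_kernels(pr, pc, grid_spacing * 1e-9, gel$E, gel$nu)
  S <- hs_inverse(K, pad_matrix(prep(f$ux), pr, pc),
                  pad_matrix(prep(f$uy), pr, pc),
                  pad_matrix(prep(f$uz), pr, pc), regularization)
  out <- lapply(S, function(m) m[seq_len(ny), seq_len(nx)])
  structure(c(out, list(grid_spacing = grid_spacing, valid = valid)),
            class = "stress_field")
}

#' Stress cross-section through the gel bulk
#'
#' Propagates the surface traction to depth: the traction components on
#' horizontal planes (sigma_zx, sigma_zy, sigma_zz) at depth d follow from
#' the surface traction by the analytic half-space propagators (they are
#' independent of Poisson's ratio) and decay with depth (Saint-Venant).
#' At depth 0 the input surface stresses are recovered exactly.
#'
#' @param traction a `stress_field` (or list with `Sx`, `Sy`, `Sz` and
#'   `grid_spacing` in nm).
#' @param gel a [gel_properties()] object (API consistency; the propagated
#'   components do not depend on it).
#' @param depth_um depth below the surface (um, >= 0).
#' @param pad_factor zero-padding factor.
#' @return List with matrices `Szx`, `Szy`, `Szz` (Pa) at the given depth
#'   and `shear_mag` = sqrt(Szx^2 + Szy^2).
#' @export
subsurface_stress <- function(traction, gel, depth_um, pad_factor = 2) {
  stopifnot(depth_um >= 0)
  ny <- nrow(traction$Sz); nx <- ncol(traction$Sz)
  h <- traction$grid_spacing * 1e-9
  d <- depth_um * 1e-6
  pr <- stats::nextn(ceiling(pad_factor * ny), c(2, 3))
  pc <- stats::nextn(ceiling(pad_factor * nx), c(2, 3))
  qx <- stats::fft(pad_matrix(traction$Sx, pr, pc))
  qy <- stats::fft(pad_matrix(traction$Sy, pr, pc))
  qz <- stats::fft(pad_matrix(traction$Sz, pr, pc))
  kx <- outer(rep(1, pr), fft_coords(pc)) * (2 * pi / (pc * h))
  ky <- outer(fft_coords(pr), rep(1, pc)) * (2 * pi / (pr * h))
  k <- sqrt(kx^2 + ky^2)
  ksafe <- k; ksafe[1, 1] <- 1
  ex <- kx / ksafe; ey <- ky / ksafe
  ex[1, 1] <- 0; ey[1, 1] <- 0
  kd <- k * d
  E1 <- exp(-kd)
  szz <- E1 * ((1 + kd) * qz - 1i * kd * (ex * qx + ey * qy))
  szx <- E1 * ((1 - kd * ex^2) * qx - kd * ex * ey * qy + 1i * kd * ex * qz)
  szy <- E1 * (-kd * ex * ey * qx + (1 - kd * ey^2) * qy + 1i * kd * ey * qz)
  np <- pr * pc
  crop <- function(m) Re(stats::fft(m, inverse = TRUE) / np)[seq_len(ny),
                                                             seq_len(nx)]
  out <- list(Szx = crop(szx), Szy = crop(szy), Szz = crop(szz))
  out$shear_mag <- sqrt(out$Szx^2 + out$Szy^2)
  out
}

#' Monte-Carlo propagation of localization noise to stress uncertainty
#'
#' Draws i.i.d. Gaussian displacement noise with the given per-axis
#' standard deviations at every grid point, passes it through the
#' pipeline's full filtering chain (temporal median over `temporal_width`
#' frames, then the spatial median filter of the gridding stage) and the
#' spectral stress inversion, and reports the per-grid-point standard
#' deviation of the resulting stresses over `n_reps` repetitions. Border
#' regions affected by the inversion taper are excluded from the summary.
#'
#' @param sigma an [estimate_uncertainty()] result or numeric
#'   `c(sigma_x, sigma_y, sigma_z)` in nm.
#' @param gel a [gel_properties()] object.
#' @param grid_spacing displacement grid pitch (nm).
#' @param n_reps Monte-Carlo repetitions (>= 50).
#' @param seed RNG seed.
#' @param n_grid grid side length (points).
#' @param temporal_width temporal median window (frames).
#' @param spatial_median_width spatial median window (grid points).
#' @param crop border fraction excluded from the summary.
#' @return List with `sigma_shear` (pooled per-point SD of Sx and Sy, Pa),
#'   `sigma_normal` (per-point SD of Sz, Pa), and the settings used.
#' @export
propagate_noise <- function(sigma, gel, grid_spacing = 60.4, n_reps = 100,
                            seed = 1, n_grid = 128, temporal_width = 10,
                            spatial_median_width = 10, crop = 0.15) {
  stopifnot(n_reps >= 50, inherits(gel, "gel_properties"))
  if (inherits(sigma, "uncertainty_estimate"))
    sigma <- c(sigma$sigma_x, sigma$sigma_y, sigma$sigma_z)
  stopifnot(length(sigma) == 3, all(sigma >= 0))
  ny <- nx <- n_grid
  pr <- pc <- stats::nextn(2 * n_grid, c(2, 3))
  K <- hs_kernels(pr, pc, grid_spacing * 1e-9, gel$E, gel$nu)
  w2 <- outer(tukey_taper(ny, 0.1), tukey_taper(nx, 0.1))
  sel <- seq.int(floor(crop * n_grid) + 1, n_grid - floor(crop * n_grid))
  acc <- lapply(1:3, function(i) list(s = 0, s2 = 0))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      noise <- lapply(sigma, function(s) {
        if (s == 0) return(matrix(0, ny, nx))
        u <- cpp_row_median(matrix(rnorm(ny * nx * temporal_width, sd = s),
                                   nrow = ny * nx))
        cpp_median_filter2(matrix(u, ny, nx), spatial_median_width)
      })
      S <- hs_inverse(K, pad_matrix(noise[[1]] * w2 * 1e-9, pr, pc),
                      pad_matrix(noise[[2]] * w2 * 1e-9, pr, pc),
                      pad_matrix(noise[[3]] * w2 * 1e-9, pr, pc), 0)
      for (i in 1:3) {
        v <- S[[i]][sel, sel]
        acc[[i]]$s <- acc[[i]]$s + v
        acc[[i]]$s2 <- acc[[i]]$s2 + v^2
      }
    }
  })
  sds <- lapply(acc, function(a) {
    v <- a$s2 / n_reps - (a$s / n_reps)^2
    sqrt(pmax(v, 0) * n_reps / (n_reps - 1))
  })
  list(sigma_shear = sqrt(mean(c(sds[[1]]^2, sds[[2]]^2))),
       sigma_normal = sqrt(mean(sds[[3]]^2)),
       n_reps = n_reps, n_grid = n_grid, grid_spacing = grid_spacing,
       temporal_width = temporal_width,
       spatial_median_width = spatial_median_width)
}

#' TIRF illumination geometry
#'
#' @param n_glass refractive index of the coverglass/objective immersion.
#' @param NA_min,NA_max illumination numerical aperture range.
#' @param NA_tirf_threshold NA above which TIRF is achieved for the setup.
#' @param axial_deformation_nm axial dynamic range of the gel surface (nm).
#' @param contact_length_um lateral extent of the cell contact (um).
#' @param tilt_deg surface tilt (degrees); when `NULL` it is derived as
#'   `atan(axial_deformation / contact_length)`.
#' @return Object of class `tirf_geometry`.
#' @export
tirf_geometry <- function(n_glass = 1.515, NA_min = 1.38, NA_max = 1.41,
                          NA_tirf_threshold = 1.38,
                          axial_deformation_nm = 500,
                          contact_length_um = 15, tilt_deg = 1.5) {
  stopifnot(NA_min < NA_max, NA_max < n_glass)
  structure(list(n_glass = n_glass, NA_min = NA_min, NA_max = NA_max,
                 NA_tirf_threshold = NA_tirf_threshold,
                 axial_deformation_nm = axial_deformation_nm,
                 contact_length_um = contact_length_um,
                 tilt_deg = tilt_deg),
            class = "tirf_geometry")
}

#' Is TIRF illumination maintained under gel deformation?
#'
#' The critical incidence angle for the maximal illumination NA is
#' `asin(NA_max / n_glass)`. Normal stresses tilt the gel-sample interface
#' by the geometry's tilt angle (by default the printed 1.5 degrees;
#' derived from `atan(axial_deformation / contact_length)` when `tilt_deg`
#' is `NULL`), perturbing the effective NA to
#' `n_glass * sin(critical +- tilt)`. TIRF is maintained when the lower NA
#' bound still exceeds the TIRF threshold.
#'
#' @param geom a [tirf_geometry()] object.
#' @return List with `critical_angle_deg`, `tilt_deg`, `na_range`
#'   (lower, upper) and logical `maintained`.
#' @export
tirf_maintained <- function(geom) {
  stopifnot(inherits(geom, "tirf_geometry"))
  arg <- geom$NA_max / geom$n_glass
  if (arg >= 1) stop("NA_max must be smaller than n_glass")
  crit <- asin(arg) * 180 / pi
  tilt <- geom$tilt_deg
  if (is.null(tilt))
    tilt <- atan((geom$axial_deformation_nm * 1e-9) /
                   (geom$contact_length_um * 1e-6)) * 180 / pi
  ang <- (crit + c(-tilt, tilt)) * pi / 180
  na_range <- geom$n_glass * sin(ang)
  list(critical_angle_deg = crit, tilt_deg = tilt, na_range = na_range,
       maintained = na_range[1] > geom$NA_tirf_threshold)
}
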