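# Synthetic aTFM data with known ground truth for every pipeline stage:
# seeded fiducial bead layouts, named ground-truth displacement generators,
# and astigmatic image rendering with Poisson shot noise and an optional
# smooth "cell bleed-through" background condition.

#' Define a synthetic aTFM scene
#'
#' The defaults reproduce the reference acquisition conditions: 0.3
#' fiducial beads per um^2, 100 time points at 1 s, and two background
#' conditions (minimal background versus fluorescence bleed-through from
#' the labelled cell). The photon budget per bead and frame is a stand-in
#' chosen so that localization uncertainties fall in the few-nanometre
#' regime typical of astigmatic single-particle imaging.
#'
#' @param fov_um field of view `c(width, height)` (um).
#' @param bead_density beads per um^2.
#' @param photon_budget expected photons per bead per frame.
#' @param background_low,background_high background photons/pixel for the
#'   low- and high-noise conditions.
#' @param n_frames number of time points.
#' @param time_step acquisition interval (s).
#' @param displacement_generator one of `"static"`, `"rigid_drift"`,
#'   `"hertz_indentation"`, `"traction_spots"`.
#' @param seed RNG seed; everything derived from the scene is
#'   deterministic given the seed.
#' @param pixel_size camera pixel (nm).
#' @param min_separation_um minimum bead separation (um) of the thinned
#'   layout.
#' @param params generator-specific parameters, see [generate_scene()].
#' @return Object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(fov_um = c(30, 30), bead_density = 0.3,
                            photon_budget = 5000, background_low = 2,
                            background_high = 20, n_frames = 100,
                            time_step = 1,
                            displacement_generator = c(
                              "static", "rigid_drift", "hertz_indentation",
                              "traction_spots"),
                            seed = 1, pixel_size = 60.4,
                            min_separation_um = 1, params = list()) {
  displacement_generator <- match.arg(displacement_generator)
  stopifnot(all(fov_um > 0), bead_density > 0, photon_budget > 0,
            background_low >= 0, background_high >= 0, n_frames >= 1)
  structure(list(fov_um = fov_um, bead_density = bead_density,
                 photon_budget = photon_budget,
                 background_low = background_low,
                 background_high = background_high,
                 n_frames = n_frames, time_step = time_step,
                 displacement_generator = displacement_generator,
                 seed = seed, pixel_size = pixel_size,
                 min_separation_um = min_separation_um, params = params),
            class = "synthetic_scene")
}

# seeded uniform point process thinned to a minimum separation
sample_bead_layout <- function(fov_nm, n, min_sep_nm) {
  x <- numeric(0); y <- numeric(0)
  attempts <- 0L
  max_attempts <- 200L * n
  while (length(x) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cx <- runif(1, 0, fov_nm[1]); cy <- runif(1, 0, fov_nm[2])
    if (length(x) == 0 ||
        min((x - cx)^2 + (y - cy)^2) >= min_sep_nm^2) {
      x <- c(x, cx); y <- c(y, cy)
    }
  }
  if (length(x) < n)
    stop("bead density too high for the minimum-separation constraint")
  data.frame(x_nm = x, y_nm = y)
}

#' Generate a synthetic scene: bead layout and ground-truth displacements
#'
#' Beads are placed by a seeded uniform point process thinned to the
#' scene's minimum separation; the per-frame ground-truth displacement of
#' every bead comes from the scene's named generator:
#' \describe{
#'   \item{static}{all displacements zero.}
#'   \item{rigid_drift}{rigid 3D drift, `params$rate_nm` per frame
#'     (default `c(5, -3, 2)`).}
#'   \item{hertz_indentation}{static Hertzian bowl ([hertz_uz()]) pressed
#'     into the surface; `params`: `P` (N, default the buoyancy-corrected
#'     70 um silica sphere load), `E` (Pa, default 250), `a` (m, default
#'     3 um), centre at the field centre. Displacement is axial
#'     (downward).}
#'   \item{traction_spots}{adhesion-like Gaussian traction spots on a 10
#'     kPa gel (defaults: one shear spot of 500 Pa peak and one normal
#'     spot of 150 Pa peak, sigma 1 um) whose surface displacement field
#'     (via [displacement_from_traction()]) ramps up linearly over the
#'     movie; `params`: `spots` data frame (x_um, y_um, sigma_um, Sx, Sy,
#'     Sz), `E`, `nu`.}
#' }
#'
#' @param scene a [synthetic_scene()].
#' @return The scene augmented with `beads` (frame-0 positions, nm) and
#'   `truth`, an array of dim (n_beads, n_frames, 3) of ground-truth
#'   displacements (nm).
#' @export
generate_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  fov_nm <- scene$fov_um * 1e3
  n <- round(prod(scene$fov_um) * scene$bead_density)
  beads <- with_seed(scene$seed,
                     sample_bead_layout(fov_nm, n,
                                        scene$min_separation_um * 1e3))
  nb <- nrow(beads)
  nt <- scene$n_frames
  truth <- array(0, c(nb, nt, 3))
  p <- scene$params
  if (scene$displacement_generator == "rigid_drift") {
    rate <- p$rate_nm %||% c(5, -3, 2)
    for (ax in 1:3)
      truth[, , ax] <- outer(rep(1, nb), (seq_len(nt) - 1) * rate[ax])
  } else if (scene$displacement_generator == "hertz_indentation") {
    P <- p$P %||% sphere_load(70e-6)
    E <- p$E %||% 250
    a <- p$a %||% 3e-6
    ctr <- p$center_nm %||% (fov_nm / 2)
    r <- sqrt((beads$x_nm - ctr[1])^2 + (beads$y_nm - ctr[2])^2) * 1e-9
    uz <- hertz_uz(r, P = P, E = E, a = a) * 1e9
    truth[, , 3] <- -uz  # surface pressed down, constant in time
    attrs <- list(P = P, E = E, a = a, center_nm = ctr)
    scene$hertz <- attrs
  } else if (scene$displacement_generator == "traction_spots") {
    E <- p$E %||% 1e4
    nu <- p$nu %||% 0.495
    # force-balanced by default: a contracting shear dipole plus a normal
    # push/pull pair (cell tractions carry no net force; unbalanced spots
    # would give 1/r displacement tails no finite field of view captures)
    spots <- p$spots %||% data.frame(
      x_um = scene$fov_um[1] * c(0.35, 0.65, 0.5, 0.5),
      y_um = scene$fov_um[2] * c(0.5, 0.5, 0.35, 0.65),
      sigma_um = 1, Sx = c(1000, -1000, 0, 0), Sy = 0,
      Sz = c(0, 0, 400, -400))
    grid_nm <- 4 * scene$pixel_size  # traction grid; displacements are smooth
    xo <- seq(0, fov_nm[1], by = grid_nm)
    yo <- seq(0, fov_nm[2], by = grid_nm)
    g <- function(comp) {
      m <- matrix(0, length(yo), length(xo))
      for (i in seq_len(nrow(spots))) {
        gx <- exp(-(xo - spots$x_um[i] * 1e3)^2 /
                    (2 * (spots$sigma_um[i] * 1e3)^2))
        gy <- exp(-(yo - spots$y_um[i] * 1e3)^2 /
                    (2 * (spots$sigma_um[i] * 1e3)^2))
        m <- m + spots[[comp]][i] * outer(gy, gx)
      }
      m
    }
    gel <- gel_properties(E, nu)
    u <- displacement_from_traction(list(Sx = g("Sx"), Sy = g("Sy"),
                                         Sz = g("Sz")), gel,
                                    grid_spacing = grid_nm)
    bi <- function(m, x, y) bilinear_at(m, xo, yo, x, y)
    ramp <- if (nt > 1) (seq_len(nt) - 1) / (nt - 1) else 1
    ub <- cbind(bi(u$ux, beads$x_nm, beads$y_nm),
                bi(u$uy, beads$x_nm, beads$y_nm),
                bi(u$uz, beads$x_nm, beads$y_nm))
    for (ax in 1:3) truth[, , ax] <- outer(ub[, ax], ramp)
    scene$spot_truth <- list(grid_x = xo, grid_y = yo, u = u, spots = spots,
                             gel = gel, ramp = ramp)
  }
  scene$beads <- beads
  scene$truth <- truth
  scene
}

# bilinear sampling of a matrix (rows = y) at scattered points
bilinear_at <- function(m, xg, yg, x, y) {
  dx <- xg[2] - xg[1]; dy <- yg[2] - yg[1]
  fx <- pmin(pmax((x - xg[1]) / dx, 0), length(xg) - 1 - 1e-9)
  fy <- pmin(pmax((y - yg[1]) / dy, 0), length(yg) - 1 - 1e-9)
  ix <- floor(fx); iy <- floor(fy)
  tx <- fx - ix; ty <- fy - iy
  i1 <- cbind(iy + 1, ix + 1)
  m[i1] * (1 - tx) * (1 - ty) +
    m[cbind(iy + 1, ix + 2)] * tx * (1 - ty) +
    m[cbind(iy + 2, ix + 1)] * (1 - tx) * ty +
    m[cbind(iy + 2, ix + 2)] * tx * ty
}

#' Render one astigmatic frame
#'
#' Expected-photon image of beads at the given 3D positions (no noise);
#' building block of the synthetic movies.
#'
#' @param nx,ny image size (pixels).
#' @param x_nm,y_nm,z_nm bead positions (nm; image frame, z relative to
#'   focus).
#' @param photons per-bead photon budgets.
#' @param background background photons/pixel (scalar or matrix).
#' @param curves a [gaussian_defocus_curves()] object.
#' @param pixel_size pixel pitch (nm).
#' @param window_px per-bead rendering window (pixels).
#' @return Photon-count matrix (rows = y).
#' @export
render_frame <- function(nx, ny, x_nm, y_nm, z_nm, photons, background,
                         curves, pixel_size, window_px = 21) {
  img <- if (length(background) == 1) matrix(background, ny, nx)
  else background
  half <- (window_px - 1) / 2
  for (i in seq_along(x_nm)) {
    cx <- floor(x_nm[i] / pixel_size) + 1  # pixel containing the bead
    cy <- floor(y_nm[i] / pixel_size) + 1
    if (cx < 1 - half || cx > nx + half || cy < 1 - half || cy > ny + half)
      next
    dx <- x_nm[i] - (cx - 0.5) * pixel_size
    dy <- y_nm[i] - (cy - 0.5) * pixel_size
    patch <- render_gaussian_psf(curves, dx, dy, z_nm[i],
                                 photons = photons[i], background = 0,
                                 window = window_px,
                                 pixel_size = pixel_size)
    rr <- (cy - half):(cy + half)
    cc <- (cx - half):(cx + half)
    ok_r <- rr >= 1 & rr <= ny
    ok_c <- cc >= 1 & cc <= nx
    img[rr[ok_r], cc[ok_c]] <- img[rr[ok_r], cc[ok_c]] +
      patch[ok_r, ok_c, drop = FALSE]
  }
  img
}

# seeded low-pass-filtered random field emulating cell bleed-through:
# coarse white noise, bicubically upsampled and scaled to the target mean
bleed_background <- function(nx, ny, mean_level, contrast = 0.5) {
  ncell <- 12
  coarse <- matrix(rnorm(ncell^2), ncell, ncell)
  xf <- seq(1, ncell, length.out = nx)
  yf <- seq(1, ncell, length.out = ny)
  m1 <- t(apply(coarse, 1, function(row)
    stats::spline(seq_len(ncell), row, xout = xf, method = "fmm")$y))
  m <- apply(m1, 2, function(col)
    stats::spline(seq_len(ncell), col, xout = yf, method = "fmm")$y)
  m <- m / max(abs(m), 1e-9)
  pmax(mean_level * (1 + contrast * m), 0)
}

#' Render a synthetic time-lapse movie
#'
#' Renders every bead of a generated scene at its displaced 3D position
#' with the scene's photon budget, adds the background (uniform for the
#' low-noise condition, a smooth seeded bleed-through pattern for the
#' high-noise condition) and Poisson shot noise when `noise = TRUE`.
#' Beads displaced outside the PSF z-range are clipped to it, flagged in
#' the returned ground truth, and a warning is raised.
#'
#' @param scene a generated [synthetic_scene()] (see [generate_scene()]).
#' @param curves a [gaussian_defocus_curves()] object used for rendering.
#' @param noise apply Poisson shot noise?
#' @param condition `"low"` or `"high"` background condition.
#' @param z_range rendering z-range (nm).
#' @return List with `frames` (list of photon-count matrices), `scene`,
#'   `clipped` (logical matrix beads x frames), image size, and the
#'   condition used.
#' @export
render_timelapse <- function(scene, curves, noise = TRUE,
                             condition = c("low", "high"),
                             z_range = c(-1000, 1000)) {
  stopifnot(!is.null(scene$beads))
  condition <- match.arg(condition)
  nx <- ceiling(scene$fov_um[1] * 1e3 / scene$pixel_size)
  ny <- ceiling(scene$fov_um[2] * 1e3 / scene$pixel_size)
  nt <- scene$n_frames
  nb <- nrow(scene$beads)
  clipped <- matrix(FALSE, nb, nt)
  frames <- vector("list", nt)
  with_seed(scene$seed + 1L, {
    bg <- if (condition == "low") scene$background_low
    else bleed_background(nx, ny, scene$background_high)
    for (t in seq_len(nt)) {
      z <- scene$truth[, t, 3]
      clip <- z < z_range[1] | z > z_range[2]
      clipped[, t] <- clip
      z <- pmin(pmax(z, z_range[1]), z_range[2])
      img <- render_frame(nx, ny,
                          scene$beads$x_nm + scene$truth[, t, 1],
                          scene$beads$y_nm + scene$truth[, t, 2],
                          z, rep(scene$photon_budget, nb), bg, curves,
                          scene$pixel_size)
      if (noise) img <- matrix(rpois(length(img), img), ny, nx)
      frames[[t]] <- img
    }
  })
  if (any(clipped))
    warning(sum(clipped), " bead-frame(s) clipped to the PSF z-range")
  list(frames = frames, scene = scene, clipped = clipped, nx = nx, ny = ny,
       condition = condition)
}

#' Render a calibration z-stack of sparse beads
#'
#' Noise-free (or Poisson-noisy) astigmatic z-stack of isolated beads at
#' random sub-pixel offsets, for building and validating the spline PSF
#' model.
#'
#' @param curves a [gaussian_defocus_curves()] object.
#' @param n_beads number of beads.
#' @param image_px image side (pixels); beads are placed on a jittered
#'   grid with at least `min_sep_px` separation.
#' @param min_sep_px minimum bead separation (pixels).
#' @param z_step,z_range_nm axial sampling (nm).
#' @param photons,background photon budget and background per slice.
#' @param pixel_size pixel pitch (nm).
#' @param noise apply Poisson noise?
#' @param seed RNG seed.
#' @return List with the [psf_calibration_stack()] and the true bead
#'   positions.
#' @export
render_calibration_stack <- function(curves, n_beads = 5, image_px = 256,
                                     min_sep_px = 75, z_step = 10,
                                     z_range_nm = 2000, photons = 5000,
                                     background = 2, pixel_size = 60.4,
                                     noise = FALSE, seed = 1) {
  z_knots <- seq(-z_range_nm / 2, z_range_nm / 2, by = z_step)
  with_seed(seed, {
    # jittered coarse grid placement guarantees the separation
    ngrid <- floor(image_px / min_sep_px)
    if (ngrid^2 < n_beads)
      stop("image too small for the requested number of isolated beads")
    cells <- sample(ngrid^2, n_beads)
    gx <- ((cells - 1) %% ngrid) * min_sep_px + min_sep_px / 2
    gy <- ((cells - 1) %/% ngrid) * min_sep_px + min_sep_px / 2
    x <- (gx + runif(n_beads, -1, 1)) * pixel_size
    y <- (gy + runif(n_beads, -1, 1)) * pixel_size
    vox <- array(0, c(image_px, image_px, length(z_knots)))
    for (k in seq_along(z_knots)) {
      img <- render_frame(image_px, image_px, x, y,
                          rep(z_knots[k], n_beads),
                          rep(photons, n_beads), background, curves,
                          pixel_size, window_px = 41)
      if (noise) img <- matrix(rpois(length(img), img), image_px, image_px)
      vox[, , k] <- img
    }
    list(stack = psf_calibration_stack(vox, z_step, pixel_size),
         beads = data.frame(x_nm = x, y_nm = y))
  })
}

#' Render a piezo z-scan of a Hertz-indented surface
#'
#' For the static-load calibration the indented surface spans several um,
#' beyond the single-frame astigmatic range, so the sample is stepped
#' through the focal plane with a piezo. A bead with absolute surface
#' height h imaged at piezo height p appears at axial position h - p.
#'
#' @param scene a generated `hertz_indentation` scene.
#' @param curves rendering [gaussian_defocus_curves()].
#' @param piezo_heights_nm piezo positions (nm), e.g. 100 nm spacing
#'   across the indentation depth.
#' @param noise apply Poisson noise?
#' @param condition background condition.
#' @return List with `frames` (one image per piezo slice),
#'   `piezo_heights_nm`, `heights_nm` (true absolute bead heights), and
#'   the scene.
#' @export
render_piezo_stack <- function(scene, curves, piezo_heights_nm,
                               noise = TRUE, condition = "low") {
  stopifnot(scene$displacement_generator == "hertz_indentation",
            !is.null(scene$beads))
  nx <- ceiling(scene$fov_um[1] * 1e3 / scene$pixel_size)
  ny <- ceiling(scene$fov_um[2] * 1e3 / scene$pixel_size)
  nb <- nrow(scene$beads)
  heights <- scene$truth[, 1, 3]  # absolute height = 0 + displacement
  bg <- scene$background_low
  frames <- vector("list", length(piezo_heights_nm))
  with_seed(scene$seed + 2L, {
    if (condition == "high") bg <- bleed_background(nx, ny,
                                                    scene$background_high)
    for (k in seq_along(piezo_heights_nm)) {
      z_app <- heights - piezo_heights_nm[k]
      vis <- abs(z_app) <= 1000
      img <- render_frame(nx, ny, scene$beads$x_nm[vis],
                          scene$beads$y_nm[vis], z_app[vis],
                          rep(scene$photon_budget, sum(vis)), bg, curves,
                          scene$pixel_size)
      if (noise) img <- matrix(rpois(length(img), img), ny, nx)
      frames[[k]] <- img
    }
  })
  list(frames = frames, piezo_heights_nm = piezo_heights_nm,
       heights_nm = heights, scene = scene)
}
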