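# Coordinate convention: images are matrices with rows = y, columns = x,
# 0-based pixel grid; the centre of pixel index i (0-based) lies at
# (i + 0.5) * pixel_size nanometres. z is relative to the focal plane,
# positive above it (PSF elongated along x).

# 3x3 boxcar smoothing (noise suppression for maximum detection only)
box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc)
  n <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    r <- pmin(pmax(1:nr + dr, 1), nr)
    c <- pmin(pmax(1:nc + dc, 1), nc)
    s <- s + m[r, c]
    n <- n + 1
  }
  s / n
}

# Row/column local maxima of an image above a threshold, mutually separated
# by at least min_separation pixels; pairs violating the separation are
# both removed (mirroring the overlap-rejection policy). Maxima are found
# on a 3x3-smoothed copy; duplicate maxima closer than twin_radius pixels
# (Poisson-noise twins riding on one bead, below the bead separation
# scale) are collapsed to the brighter one first.
local_maxima <- function(image, min_intensity, min_separation,
                         twin_radius = 3) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  sm <- box3(image)
  ctr <- sm[2:(nr - 1), 2:(nc - 1)]
  ismax <- image[2:(nr - 1), 2:(nc - 1)] > min_intensity
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & ctr >= sm[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  peaks <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
  peaks$value <- image[cbind(peaks$row, peaks$col)]
  if (nrow(peaks) > 1 && twin_radius > 0) {
    d <- as.matrix(stats::dist(peaks[, c("row", "col")]))
    keep <- rep(TRUE, nrow(peaks))
    ord <- order(-peaks$value)
    for (i in ord) {
      if (!keep[i]) next
      keep[d[i, ] < twin_radius & keep & seq_len(nrow(peaks)) != i] <- FALSE
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  if (nrow(peaks) > 1 && min_separation > 0) {
    d <- as.matrix(stats::dist(peaks[, c("row", "col")]))
    diag(d) <- Inf
    peaks <- peaks[!apply(d < min_separation, 1, any), , drop = FALSE]
  }
  peaks <- peaks[order(peaks$row, peaks$col), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Detect bead candidates in an astigmatic frame
#'
#' Local intensity maxima above a photon threshold, mutually separated by at
#' least `min_separation` pixels; maxima violating the separation are
#' removed symmetrically (both members of a close pair), consistent with
#' the downstream overlap-rejection policy. Output is ordered row-major.
#'
#' @param image photon-count matrix (rows = y).
#' @param min_intensity minimum peak pixel value (photons).
#' @param min_separation minimum mutual distance (pixels).
#' @return A data frame with 1-based `row`, `col` and peak `value`.
#' @export
detect_candidates <- function(image, min_intensity, min_separation = 7) {
  stopifnot(is.matrix(image))
  if (any(image < 0)) stop("image contains negative intensities")
  local_maxima(image, min_intensity, min_separation)
}

# moment-based initial parameters for one fit window
moment_init <- function(win, pixel_size, z_lookup, zlim) {
  n <- nrow(win)
  border <- c(win[1, ], win[n, ], win[, 1], win[, n])
  bg0 <- median(border)
  I <- pmax(win - bg0, 0)
  N0 <- max(sum(I), 10)
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_size
  cx <- sum(outer(rep(1, n), ax) * I) / sum(I)
  cy <- sum(outer(ax, rep(1, n)) * I) / sum(I)
  wx <- marginal_sigma(colSums(I), pixel_size)
  wy <- marginal_sigma(rowSums(I), pixel_size)
  z0 <- z_lookup(wx - wy)
  z0 <- min(max(z0, zlim[1]), zlim[2])
  c(dx = cx, dy = cy, z = z0, N = N0, bg = max(bg0, 0.01))
}

#' Maximum-likelihood localization of bead candidates
#'
#' Fits each candidate window with the spline PSF model under a Poisson
#' pixel-noise model, maximising the log-likelihood of
#' `photons * PSF(dx, dy, z) + background` over the five parameters
#' (x, y, z, photons, background) by damped Newton (Levenberg-type Fisher
#' scoring) iterations. Initial lateral position comes from the window
#' centroid and initial z from the x/y width difference of a moment fit.
#' Only converged fits are returned; candidates on the image border and
#' non-converged fits are dropped and counted in a message.
#'
#' @param image photon-count matrix.
#' @param model an `astig_psf` model.
#' @param candidates data frame from [detect_candidates()].
#' @param window odd fit window side (pixels).
#' @param frame frame index stored in the output.
#' @param camera_gain,camera_offset camera-count to photon conversion
#'   applied as `(image - camera_offset) / camera_gain`.
#' @param maxit,tol iteration cap and position tolerance (nm) of the
#'   optimiser.
#' @return A data frame of localizations: `frame`, `x_nm`, `y_nm`, `z_nm`,
#'   `photons`, `background`, `crlb_x`, `crlb_y`, `crlb_z`, `loglik`.
#'   Positions are in the image frame (pixel centre at
#'   `(index + 0.5) * pixel_size`).
#' @export
fit_mle <- function(image, model, candidates, window = 13, frame = 0L,
                    camera_gain = 1, camera_offset = 0, maxit = 50,
                    tol = 0.01) {
  stopifnot(inherits(model, "astig_psf"), window %% 2 == 1)
  image <- (image - camera_offset) / camera_gain
  half <- (window - 1) / 2
  px <- model$pixel_size
  margin <- 2 * model$z_step
  zlim <- c(model$z_min + margin, model$z_max - margin)
  nzi <- length(model$z_knots) - 1
  cf <- model$coef
  res <- vector("list", nrow(candidates))
  n_border <- 0L; n_fail <- 0L
  for (i in seq_len(nrow(candidates))) {
    r <- candidates$row[i]; c <- candidates$col[i]
    if (r <= half || c <= half || r > nrow(image) - half ||
        c > ncol(image) - half) {
      n_border <- n_border + 1L
      next
    }
    win <- image[(r - half):(r + half), (c - half):(c + half)]
    init <- moment_init(win, px, model$z_lookup, zlim)
    fit <- cpp_fit_mle(win, cf, model$nf, nzi, model$z_min, model$z_step,
                       model$fine_step, px, init, zlim, as.integer(maxit),
                       tol)
    if (!fit$converged) {
      n_fail <- n_fail + 1L
      next
    }
    p <- fit$par
    cr <- crlb_fisher(model, cf, nzi, p[1], p[2], p[3], p[4], p[5], window)
    if (is.null(cr)) {
      n_fail <- n_fail + 1L
      next
    }
    res[[i]] <- data.frame(
      frame = frame,
      x_nm = ((c - 1) + 0.5) * px + p[1],
      y_nm = ((r - 1) + 0.5) * px + p[2],
      z_nm = p[3], photons = p[4], background = p[5],
      crlb_x = cr[1], crlb_y = cr[2], crlb_z = cr[3],
      loglik = fit$loglik)
  }
  if (n_border > 0)
    message(n_border, " candidate(s) dropped at the image border")
  if (n_fail > 0)
    message(n_fail, " fit(s) dropped (no convergence)")
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) out <- empty_localizations()
  rownames(out) <- NULL
  out
}

empty_localizations <- function() {
  data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
             z_nm = numeric(), photons = numeric(), background = numeric(),
             crlb_x = numeric(), crlb_y = numeric(), crlb_z = numeric(),
             loglik = numeric())
}

# Fisher information of the Poisson imaging model; returns the three
# position bounds (nm) or NULL if the information matrix is singular
crlb_fisher <- function(model, cf, nzi, dx, dy, z, photons, background,
                        window) {
  pat <- cpp_psf_patch(cf, model$nf, nzi, model$z_min, model$z_step,
                       model$fine_step, dx, dy, z, as.integer(window),
                       model$pixel_size, TRUE)
  mu <- pmax(photons * pat$P + background, 1e-10)
  D <- cbind(photons * as.vector(pat$Dx), photons * as.vector(pat$Dy),
             photons * as.vector(pat$Dz), as.vector(pat$P), 1)
  FI <- crossprod(D / sqrt(as.vector(mu)))
  V <- tryCatch(solve(FI), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V)[1:3] <= 0))
    return(NULL)
  sqrt(diag(V)[1:3])
}

#' Cramer-Rao lower bounds of the astigmatic localization
#'
#' Theoretical minimum standard deviations of an unbiased estimator of the
#' emitter position, from the Fisher information of the Poisson imaging
#' model at the given operating point (all five parameters free).
#'
#' @param model an `astig_psf` model.
#' @param photons expected photon count (> 0).
#' @param background expected background photons per pixel.
#' @param z axial position (nm).
#' @param window odd fit window side (pixels).
#' @param dx,dy lateral offset of the operating point (nm).
#' @return Named vector `c(sigma_x, sigma_y, sigma_z)` in nm.
#' @export
crlb <- function(model, photons, background = 0, z = 0, window = 13,
                 dx = 0, dy = 0) {
  stopifnot(inherits(model, "astig_psf"), photons > 0, background >= 0)
  if (z < model$z_min || z > model$z_max)
    stop("z outside the calibrated range")
  cr <- crlb_fisher(model, model$coef,
                    length(model$z_knots) - 1, dx, dy, z, photons,
                    background, window)
  if (is.null(cr))
    stop("singular Fisher information (flat PSF at this operating point)")
  setNames(cr, c("sigma_x", "sigma_y", "sigma_z"))
}

#' Remove mutually overlapping localizations
#'
#' Overlapping beads prohibit accurate localization: every localization
#' with a same-frame neighbour closer (laterally) than `exclusion_radius`
#' is removed, symmetrically (both members of a close pair).
#'
#' @param localizations localization data frame (needs `frame`, `x_nm`,
#'   `y_nm`).
#' @param exclusion_radius minimum allowed lateral separation (nm).
#' @return The surviving subset of the input rows.
#' @export
filter_overlaps <- function(localizations, exclusion_radius) {
  stopifnot(exclusion_radius > 0)
  if (nrow(localizations) == 0) return(localizations)
  keep <- rep(TRUE, nrow(localizations))
  for (f in unique(localizations$frame)) {
    idx <- which(localizations$frame == f)
    if (length(idx) < 2) next
    d <- as.matrix(stats::dist(localizations[idx, c("x_nm", "y_nm")]))
    diag(d) <- Inf
    keep[idx[apply(d < exclusion_radius, 1, any)]] <- FALSE
  }
  out <- localizations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default overlap-exclusion radius of a PSF model
#'
#' Twice the largest PSF second-moment width at |z| = 800 nm, the edge of
#' the reliable astigmatic range.
#'
#' @param model an `astig_psf` model.
#' @return Radius in nm.
#' @export
default_exclusion_radius <- function(model) {
  w <- model$widths
  sel <- abs(abs(w$z) - 800) < model$z_step / 2
  if (!any(sel)) sel <- abs(w$z) == max(abs(w$z))
  2 * max(w$wx[sel], w$wy[sel])
}
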