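#' Calibration z-stack of astigmatic bead images
#'
#' Container for the experimental calibration acquisition: a gel decorated
#' with sparse fluorescent beads stepped through the focal plane (2 um range
#' at 10 nm steps in the reference protocol), one astigmatic image per
#' z-position.
#'
#' @param voxels 3D array of photon counts, dim `c(rows, cols, n_slices)`
#'   (rows = y). All intensities must be >= 0.
#' @param z_step piezo step between slices (nm).
#' @param pixel_size lateral pixel pitch (nm).
#' @return An object of class `psf_calibration_stack`; its `z_range` equals
#'   `(n_slices - 1) * z_step` and slices are assigned axial positions
#'   symmetric about the focal plane.
#' @export
psf_calibration_stack <- function(voxels, z_step, pixel_size) {
  stopifnot(length(dim(voxels)) == 3, z_step > 0, pixel_size > 0)
  if (any(voxels < 0)) stop("calibration stack contains negative intensities")
  nz <- dim(voxels)[3]
  z_range <- (nz - 1) * z_step
  structure(list(voxels = voxels, z_step = z_step, z_range = z_range,
                 pixel_size = pixel_size,
                 z_knots = seq(-z_range / 2, z_range / 2, by = z_step)),
            class = "psf_calibration_stack")
}

# separable cubic-spline resampling: g(r, c) = f(r + sy, c + sx) (pixels)
shift_image <- function(mat, sx, sy) {
  nr <- nrow(mat); nc <- ncol(mat)
  if (abs(sx) > 1e-12) {
    xs <- seq_len(nc) + sx
    mat <- t(apply(mat, 1, function(row)
      stats::spline(seq_len(nc), row, xout = xs, method = "fmm")$y))
  }
  if (abs(sy) > 1e-12) {
    ys <- seq_len(nr) + sy
    mat <- apply(mat, 2, function(col)
      stats::spline(seq_len(nr), col, xout = ys, method = "fmm")$y)
  }
  mat
}

# separable cubic-spline lateral upsampling onto an `os`-times finer grid
upsample_image <- function(mat, os) {
  if (os == 1) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  xf <- seq(1, nc, by = 1 / os)
  yf <- seq(1, nr, by = 1 / os)
  m1 <- t(apply(mat, 1, function(row)
    stats::spline(seq_len(nc), row, xout = xf, method = "fmm")$y))
  apply(m1, 2, function(col)
    stats::spline(seq_len(nr), col, xout = yf, method = "fmm")$y)
}

# piecewise-cubic coefficients of the "fmm" interpolating spline through
# (z_knots, y) for many series at once; Y is [n_knots, n_series].
# Returns list of 4 matrices [n_knots - 1, n_series].
zspline_coefficients <- function(z_knots, Y) {
  nz <- length(z_knots)
  h <- diff(z_knots)[1]
  zj <- z_knots[-nz]
  out <- lapply(1:4, function(i) matrix(0, nz - 1, ncol(Y)))
  for (s in seq_len(ncol(Y))) {
    f <- splinefun(z_knots, Y[, s], method = "fmm")
    c0 <- Y[-nz, s]
    c1 <- f(zj, deriv = 1)
    c2 <- f(zj, deriv = 2) / 2
    c3 <- (Y[-1, s] - c0 - c1 * h - c2 * h^2) / h^3
    out[[1]][, s] <- c0; out[[2]][, s] <- c1
    out[[3]][, s] <- c2; out[[4]][, s] <- c3
  }
  out
}

# sub-pixel residual shift of image B relative to reference M, estimated by
# one linearised (Lucas-Kanade) least-squares step on the image gradients
residual_shift <- function(B, M) {
  nr <- nrow(M); nc <- ncol(M)
  gx <- (M[, c(2:nc, nc)] - M[, c(1, 1:(nc - 1))]) / 2
  gy <- (M[c(2:nr, nr), ] - M[c(1, 1:(nr - 1)), ]) / 2
  G <- cbind(as.vector(gx), as.vector(gy))
  d <- as.vector(B - M)
  -solve(crossprod(G), crossprod(G, d))[, 1]
}

#' Build the spline PSF model from a calibration stack
#'
#' Detects isolated beads in the calibration stack, aligns each bead to the
#' ensemble mean with sub-pixel precision (intensity centroid followed by
#' gradient-based refinement), averages them into a single experimental 3D
#' PSF, and interpolates it with cubic splines: an "fmm" (not-a-knot style)
#' cubic spline along z at every lateral sample of a 2x oversampled
#' template, with C1 lateral interpolation between samples. Each z-slice of
#' the stored model is normalised to unit sum, so [evaluate_psf()] returns
#' the expected photons per pixel of a unit-intensity emitter.
#'
#' @param stack a [psf_calibration_stack()].
#' @param detection_threshold minimum bead peak intensity (photons) in the
#'   central slice.
#' @param roi_px odd lateral template size (pixels); beads closer than
#'   `2 * roi_px` pixels to each other are excluded from the average.
#' @param oversample lateral oversampling factor of the stored template.
#' @param align_iter sub-pixel alignment refinement iterations.
#' @return An object of class `astig_psf`.
#' @export
build_psf_model <- function(stack, detection_threshold, roi_px = 35,
                            oversample = 2, align_iter = 3) {
  stopifnot(inherits(stack, "psf_calibration_stack"), roi_px %% 2 == 1)
  vox <- stack$voxels
  nz <- dim(vox)[3]
  mid <- vox[, , (nz + 1) %/% 2]
  peaks <- local_maxima(mid, min_intensity = detection_threshold,
                        min_separation = roi_px)
  if (nrow(peaks) == 0) stop("no beads detected in the calibration stack")
  # exclude beads violating the 2x fit-window separation requirement
  if (nrow(peaks) > 1) {
    d <- as.matrix(stats::dist(peaks[, c("row", "col")]))
    diag(d) <- Inf
    bad <- apply(d < 2 * roi_px, 1, any)
    if (any(bad))
      message(sum(bad), " bead(s) excluded: closer than 2 x roi_px")
    peaks <- peaks[!bad, , drop = FALSE]
  }
  half <- (roi_px - 1) / 2
  inb <- peaks$row > half & peaks$row <= nrow(mid) - half &
    peaks$col > half & peaks$col <= ncol(mid) - half
  if (any(!inb))
    message(sum(!inb), " bead(s) excluded: too close to the image border")
  peaks <- peaks[inb, , drop = FALSE]
  if (nrow(peaks) == 0) stop("no usable beads in the calibration stack")

  # extract per-bead subvolumes and subtract a scalar background estimated
  # from the border pixels of the central slices
  beads <- lapply(seq_len(nrow(peaks)), function(i) {
    r <- peaks$row[i]; c <- peaks$col[i]
    sub <- vox[(r - half):(r + half), (c - half):(c + half), , drop = FALSE]
    csl <- sub[, , max(1, (nz + 1) %/% 2 - 5):min(nz, (nz + 1) %/% 2 + 5)]
    ring <- rbind(csl[1:2, , ], csl[(roi_px - 1):roi_px, , ])
    bg <- median(c(ring, csl[, 1:2, ], csl[, (roi_px - 1):roi_px, ]))
    sub - bg
  })

  # first pass: centroid alignment of the z-summed image
  zsum <- lapply(beads, function(b) apply(b, c(1, 2), sum))
  ax <- seq_len(roi_px) - (half + 1)
  centred <- vector("list", length(beads))
  for (i in seq_along(beads)) {
    w <- pmax(zsum[[i]], 0)
    ox <- sum(outer(rep(1, roi_px), ax) * w) / sum(w)
    oy <- sum(outer(ax, rep(1, roi_px)) * w) / sum(w)
    centred[[i]] <- array(
      apply(beads[[i]], 3, shift_image, sx = ox, sy = oy),
      dim = dim(beads[[i]]))
  }
  # refinement passes against the ensemble mean
  for (iter in seq_len(align_iter)) {
    zs <- lapply(centred, function(b) apply(b, c(1, 2), sum))
    M <- Reduce(`+`, zs) / length(zs)
    for (i in seq_along(centred)) {
      dlt <- residual_shift(zs[[i]], M)
      if (max(abs(dlt)) > 1e-3 && max(abs(dlt)) < 2)
        centred[[i]] <- array(
          apply(centred[[i]], 3, shift_image, sx = dlt[1], sy = dlt[2]),
          dim = dim(centred[[i]]))
    }
  }
  avg <- Reduce(`+`, centred) / length(centred)

  # per-slice unit-sum normalisation, then lateral oversampling and
  # piecewise-cubic z coefficients for the native evaluator
  sums <- apply(avg, 3, sum)
  if (any(sums <= 0)) stop("degenerate calibration slice (non-positive sum)")
  norm <- sweep(avg, 3, sums, "/")
  os <- oversample
  nf <- (roi_px - 1) * os + 1
  fine <- vapply(seq_len(nz), function(k) upsample_image(norm[, , k], os),
                 matrix(0, nf, nf))
  Y <- matrix(aperm(fine, c(3, 1, 2)), nrow = nz)  # [nz, nf*nf]
  cf <- zspline_coefficients(stack$z_knots, Y)
  nzi <- nz - 1
  coef <- array(0, dim = c(nf, nf, nzi, 4))
  for (ci in 1:4)
    coef[, , , ci] <- aperm(array(t(cf[[ci]]), c(nf, nf, nzi)), c(1, 2, 3))

  model <- structure(list(
    coef = coef, nf = nf, oversample = os, roi_px = roi_px,
    pixel_size = stack$pixel_size, fine_step = stack$pixel_size / os,
    z_knots = stack$z_knots, z_step = stack$z_step,
    z_min = stack$z_knots[1], z_max = stack$z_knots[nz],
    normalized = TRUE,
    meta = list(created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                n_beads = length(centred))),
    class = "astig_psf")
  model$widths <- psf_width_table(model)
  model$z_lookup <- width_diff_lookup(model$widths)
  model
}

# coefficient matrix ordering: t(cf) is [n_series, nzi] with series index
# iy + nf*(ix-1); array() refolds it to [nf(iy), nf(ix), nzi]

#' Evaluate the spline PSF model
#'
#' Expected photons per pixel for a unit-intensity emitter at lateral offset
#' (`dx`, `dy`) from the window centre and axial position `z`.
#'
#' @param model an `astig_psf` model from [build_psf_model()].
#' @param dx,dy lateral emitter offset (nm).
#' @param z axial position (nm); must lie inside the calibrated range.
#' @param window odd patch side (pixels).
#' @param deriv if `TRUE` also return the patch derivatives with respect to
#'   `dx`, `dy` and `z`.
#' @return A `window` x `window` matrix (rows = y), or a list
#'   `(P, Dx, Dy, Dz)` when `deriv = TRUE`.
#' @export
evaluate_psf <- function(model, dx = 0, dy = 0, z = 0, window = 13,
                         deriv = FALSE) {
  stopifnot(inherits(model, "astig_psf"), window %% 2 == 1)
  if (z < model$z_min || z > model$z_max)
    stop(sprintf("z = %.1f nm outside the calibrated range [%.0f, %.0f] nm",
                 z, model$z_min, model$z_max))
  res <- cpp_psf_patch(model$coef, model$nf,
                       length(model$z_knots) - 1, model$z_min, model$z_step,
                       model$fine_step, dx, dy, z, as.integer(window),
                       model$pixel_size, deriv)
  if (deriv) res else res$P
}

# Gaussian-equivalent width from the FWHM of a 1D marginal (linear
# interpolation of the half-maximum crossings). Unlike raw second moments
# this is insensitive to window truncation of the defocused tails.
marginal_sigma <- function(v, spacing) {
  # v must be background-free; the window-edge tails of a defocused PSF are
  # not zero, so no baseline is subtracted here
  p <- which.max(v)
  half <- v[p] / 2
  li <- which(v[seq_len(p)] <= half)
  ri <- which(v[p:length(v)] <= half) + p - 1L
  if (length(li) == 0 || length(ri) == 0) {
    # width exceeds the window: fall back to the (truncated) second moment
    ax <- (seq_along(v) - (length(v) + 1) / 2) * spacing
    w <- pmax(v, 0)
    cx <- sum(ax * w) / sum(w)
    return(sqrt(sum((ax - cx)^2 * w) / sum(w)))
  }
  i <- max(li)
  xl <- i + (half - v[i]) / (v[i + 1] - v[i])
  i <- min(ri)
  xr <- i - (half - v[i]) / (v[i - 1] - v[i])
  (xr - xl) * spacing / (2 * sqrt(2 * log(2)))
}

# Gaussian-equivalent widths (nm) of a patch along x and y
patch_widths <- function(P, pixel_size) {
  c(wx = marginal_sigma(colSums(P), pixel_size),
    wy = marginal_sigma(rowSums(P), pixel_size))
}

# width-vs-z table of a model (used to initialise z in the MLE fit and to
# derive the default overlap exclusion radius)
psf_width_table <- function(model, window = 21) {
  z <- model$z_knots
  w <- t(vapply(z, function(zz)
    patch_widths(evaluate_psf(model, 0, 0, zz, window = window),
                 model$pixel_size), c(wx = 0, wy = 0)))
  data.frame(z = z, wx = w[, "wx"], wy = w[, "wy"], dw = w[, "wx"] - w[, "wy"])
}

# invert the monotone branch of the width-difference curve around focus
width_diff_lookup <- function(widths) {
  dw <- widths$dw
  inc <- diff(dw) > 0
  mid <- which.min(abs(widths$z))
  lo <- mid; while (lo > 1 && inc[lo - 1]) lo <- lo - 1
  hi <- mid; while (hi < nrow(widths) && inc[hi]) hi <- hi + 1
  approxfun(dw[lo:hi], widths$z[lo:hi], rule = 2)
}

#' @export
print.astig_psf <- function(x, ...) {
  cat("astigmatic spline PSF model\n")
  cat(sprintf("  z range      : [%.0f, %.0f] nm in %.0f nm steps (%d knots)\n",
              x$z_min, x$z_max, x$z_step, length(x$z_knots)))
  cat(sprintf("  template     : %d px (%.1f nm/px, %dx oversampled)\n",
              x$roi_px, x$pixel_size, x$oversample))
  cat(sprintf("  averaged from: %d bead(s), built %s\n",
              x$meta$n_beads, x$meta$created))
  invisible(x)
}

#' Write / read a PSF model container
#'
#' The model (spline coefficients plus calibration metadata: z-range, pixel
#' size, creation date) is stored in a single serialised container so one
#' calibration can be reused across datasets.
#'
#' @param model an `astig_psf` model.
#' @param path file path (conventionally `.psf`).
#' @return `write_psf_model` returns `path` invisibly; `read_psf_model`
#'   returns the model.
#' @export
write_psf_model <- function(model, path) {
  stopifnot(inherits(model, "astig_psf"))
  obj <- list(format = "atfm-psf", version = "1", model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_psf_model
#' @export
read_psf_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "atfm-psf"))
    stop("not an atfm PSF container: ", path)
  if (!identical(obj$version, "1"))
    stop(sprintf("PSF container version mismatch: expected 1, found %s",
                 obj$version))
  obj$model
}
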