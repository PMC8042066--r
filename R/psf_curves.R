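#' Parametric astigmatic defocus curves
#'
#' Describes how the orthogonal Gaussian widths of an astigmatic PSF vary
#' with axial position. A cylindrical lens in the emission path shifts the
#' focal planes of the x and y image axes in opposite directions, so the
#' elliptical shape of a bead image encodes its axial position. The width
#' model is the standard astigmatism calibration curve
#' \deqn{\sigma(z) = \sigma_0 \sqrt{1 + u^2 + A u^3 + B u^4}, \quad
#'       u = (z - \gamma)/d,}
#' with focal offset \eqn{\gamma} and depth of focus \eqn{d}.
#'
#' Sign convention (shared by the synthetic generator and the fitter):
#' z > 0 means the bead sits above the focal plane and the PSF elongates
#' along x, which requires `focal_offset_x < focal_offset_y`.
#'
#' @param sigma0_x,sigma0_y in-focus Gaussian widths (nm).
#' @param focal_offset_x,focal_offset_y axial positions (nm) at which the x
#'   and y widths are minimal; must differ so that z is decodable.
#' @param depth_of_focus defocus scale d (nm).
#' @param higher_order numeric vector `c(A, B)` of dimensionless
#'   higher-order defocus coefficients.
#' @return An object of class `defocus_curves`.
#' @examples
#' cur <- gaussian_defocus_curves()
#' defocus_sigma(cur, c(-400, 0, 400))
#' @export
gaussian_defocus_curves <- function(sigma0_x = 130, sigma0_y = 130,
                                    focal_offset_x = -250,
                                    focal_offset_y = 250,
                                    depth_of_focus = 400,
                                    higher_order = c(0, 0)) {
  stopifnot(sigma0_x > 0, sigma0_y > 0, depth_of_focus > 0,
            length(higher_order) == 2)
  if (focal_offset_x >= focal_offset_y)
    stop("focal_offset_x must be smaller than focal_offset_y ",
         "(z > 0 elongates the PSF along x)")
  structure(list(sigma0_x = sigma0_x, sigma0_y = sigma0_y,
                 focal_offset_x = focal_offset_x,
                 focal_offset_y = focal_offset_y,
                 depth_of_focus = depth_of_focus,
                 higher_order = as.numeric(higher_order)),
            class = "defocus_curves")
}

#' Evaluate astigmatic width curves
#'
#' @param curves a [gaussian_defocus_curves()] object.
#' @param z axial positions (nm), vectorised.
#' @return A list with components `sx` and `sy` (nm).
#' @export
defocus_sigma <- function(curves, z) {
  stopifnot(inherits(curves, "defocus_curves"))
  A <- curves$higher_order[1]
  B <- curves$higher_order[2]
  w <- function(s0, gamma) {
    u <- (z - gamma) / curves$depth_of_focus
    arg <- 1 + u^2 + A * u^3 + B * u^4
    if (any(arg <= 0)) stop("defocus curve gives a non-positive width")
    s0 * sqrt(arg)
  }
  list(sx = w(curves$sigma0_x, curves$focal_offset_x),
       sy = w(curves$sigma0_y, curves$focal_offset_y))
}

#' Render an astigmatic Gaussian bead image
#'
#' Pixel-integrated elliptical Gaussian for an emitter at lateral offset
#' (`dx`, `dy`) from the window centre and axial position `z`, with widths
#' taken from the defocus curves. The patch integral equals `photons` up to
#' the flux falling outside the window; `background` photons per pixel are
#' added uniformly.
#'
#' @param curves a [gaussian_defocus_curves()] object.
#' @param dx,dy lateral emitter offset from the window centre (nm).
#' @param z axial position (nm).
#' @param photons total expected photon count of the emitter (> 0).
#' @param background expected background photons per pixel (>= 0).
#' @param window odd patch side length (pixels).
#' @param pixel_size pixel pitch (nm).
#' @return A `window` x `window` matrix of expected photons per pixel
#'   (rows = y, columns = x).
#' @export
render_gaussian_psf <- function(curves, dx = 0, dy = 0, z = 0,
                                photons = 1000, background = 0,
                                window = 13, pixel_size = 60.4) {
  stopifnot(photons > 0, background >= 0, window >= 3, pixel_size > 0)
  s <- defocus_sigma(curves, z)
  half <- (window - 1) / 2
  edges <- (seq_len(window + 1) - 1 - window / 2) * pixel_size
  fx <- diff(pnorm(edges, mean = dx, sd = s$sx))
  fy <- diff(pnorm(edges, mean = dy, sd = s$sy))
  photons * outer(fy, fx) + background
}
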