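# Static-load calibration: a sphere of known weight indents a soft gel and
# the bead-decorated surface profile is fitted with the Hertzian
# surface-displacement model, which is linear in the load P and
# parameterised by the contact radius a. All quantities in SI units
# (m, N, Pa) unless suffixed _nm.

#' Hertzian contact model parameters
#'
#' @param P indentation load (N).
#' @param E gel elastic modulus (Pa).
#' @param a contact radius (m).
#' @param R indenter sphere radius (m), optional metadata; must exceed `a`.
#' @return An object of class `hertz_model`.
#' @export
hertz_model <- function(P, E, a, R = NULL) {
  stopifnot(P > 0, E > 0, a > 0)
  if (!is.null(R) && (R <= 0 || a >= R))
    stop("contact radius must be positive and smaller than the sphere radius")
  structure(list(P = P, E = E, a = a, R = R), class = "hertz_model")
}

#' Hertzian surface displacement profile
#'
#' Normal displacement of the gel surface at radial distance r from the
#' contact centre under a rigid spherical indenter:
#' inside the contact (r < a)
#' \deqn{u_z(r) = \frac{3P}{4Ea}\left(1 - \frac{r^2}{2a^2}\right),}
#' outside (r > a)
#' \deqn{u_z(r) = \frac{3P}{4Ea}\frac{1}{\pi}\left\{\left(2 -
#'   \frac{r^2}{a^2}\right)\sin^{-1}\frac{a}{r} +
#'   \frac{r}{a}\sqrt{1 - \frac{a^2}{r^2}}\right\}.}
#' The two branches agree at r = a (value 3P/8Ea).
#'
#' @param r radial distance(s) from the contact centre (m, >= 0).
#' @param model a [hertz_model()]; alternatively give `P`, `E`, `a`.
#' @param P,E,a load (N), modulus (Pa) and contact radius (m) when no
#'   model object is supplied.
#' @return Displacement u_z (m), positive into the gel, vectorised over `r`.
#' @export
hertz_uz <- function(r, model = NULL, P = model$P, E = model$E, a = model$a) {
  if (any(r < 0)) stop("negative radial distance")
  stopifnot(P > 0, E > 0, a > 0)
  u0 <- 3 * P / (4 * E * a)
  uz <- numeric(length(r))
  inside <- r <= a
  uz[inside] <- u0 * (1 - r[inside]^2 / (2 * a^2))
  ro <- r[!inside]
  uz[!inside] <- u0 / pi * ((2 - ro^2 / a^2) * asin(a / ro) +
                              (ro / a) * sqrt(1 - a^2 / ro^2))
  uz
}

#' Gravitational load of a sphere in a medium
#'
#' Buoyancy-corrected weight
#' \eqn{F = (\pi/6) d^3 (\rho_s - \rho_m) g} of a sphere resting on the gel
#' surface. With the reference calibration values (70 um silica sphere,
#' 2.65 g/cm^3, aqueous buffer) this gives 2.91 nN, i.e. the nominal 3 nN
#' static load.
#'
#' @param diameter sphere diameter (m).
#' @param density_sphere,density_medium densities (kg/m^3).
#' @param g gravitational acceleration (m/s^2).
#' @return Load in N. If the sphere is lighter than the medium the negative
#'   (buoyant) force is returned with attribute `buoyant = TRUE`.
#' @export
sphere_load <- function(diameter, density_sphere = 2650,
                        density_medium = 1000, g = 9.81) {
  stopifnot(diameter > 0)
  F <- pi / 6 * diameter^3 * (density_sphere - density_medium) * g
  if (density_sphere < density_medium) attr(F, "buoyant") <- TRUE
  F
}

#' Stitch piezo z-slices into an extended-range surface
#'
#' The astigmatic range of a single frame (about +-0.8 um) is smaller than
#' the indentation depth, so the surface is reconstructed from a piezo
#' z-stack: the absolute height of a bead is its localized axial position
#' plus the piezo height of the slice. Beads recur across slices; their
#' localizations are clustered laterally and averaged with
#' inverse-CRLB-variance weights, using only slices where the bead sits
#' inside the reliable astigmatic range.
#'
#' @param slice_localizations list of localization data frames, one per
#'   piezo position (columns `x_nm`, `y_nm`, `z_nm` and optionally
#'   `crlb_z`).
#' @param piezo_heights_nm piezo height of each slice (nm), same length.
#' @param z_reliable_nm half-width of the reliable astigmatic range (nm).
#' @param gate_nm lateral clustering gate (nm).
#' @param min_slices minimum number of slices a bead must be localized in
#'   (a real bead stepped through the reliable range appears in many
#'   consecutive slices; single-slice clusters are spurious fits). Ignored
#'   when only one slice is supplied.
#' @return An object of class `stitched_surface`: data frame with `x_nm`,
#'   `y_nm`, `height_nm` (absolute surface height) and `n_slices`.
#' @export
stitch_zstack <- function(slice_localizations, piezo_heights_nm,
                          z_reliable_nm = 700, gate_nm = 500,
                          min_slices = 2) {
  stopifnot(length(slice_localizations) == length(piezo_heights_nm))
  all <- do.call(rbind, lapply(seq_along(slice_localizations), function(i) {
    L <- slice_localizations[[i]]
    if (is.null(L) || nrow(L) == 0) return(NULL)
    L$piezo <- piezo_heights_nm[i]
    L
  }))
  if (is.null(all) || nrow(all) == 0) stop("no localizations to stitch")
  n_total_clusters <- NA
  inr <- abs(all$z_nm) <= z_reliable_nm
  cl_all <- cluster_lateral(all$x_nm, all$y_nm, gate_nm)
  n_excluded <- length(setdiff(unique(cl_all), unique(cl_all[inr])))
  if (n_excluded > 0)
    message(n_excluded,
            " bead(s) excluded: never inside the reliable astigmatic range")
  all <- all[inr, , drop = FALSE]
  cl <- cl_all[inr]
  if (!"crlb_z" %in% names(all) || any(!is.finite(all$crlb_z)))
    all$crlb_z <- 1
  h <- all$z_nm + all$piezo
  w <- 1 / pmax(all$crlb_z, 1e-3)^2
  agg <- function(v, f) vapply(split(v, f), sum, 0)
  sw <- agg(w, cl)
  out <- data.frame(
    x_nm = agg(all$x_nm * w, cl) / sw,
    y_nm = agg(all$y_nm * w, cl) / sw,
    height_nm = agg(h * w, cl) / sw,
    n_slices = as.vector(table(cl)))
  rownames(out) <- NULL
  if (length(slice_localizations) > 1 && min_slices > 1) {
    n_spur <- sum(out$n_slices < min_slices)
    if (n_spur > 0)
      message(n_spur, " cluster(s) dropped: fewer than ", min_slices,
              " slices")
    out <- out[out$n_slices >= min_slices, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("stitched_surface", "data.frame")
  out
}

# greedy lateral clustering with a distance gate; beads are well separated
# compared to the gate at the densities used here
cluster_lateral <- function(x, y, gate) {
  n <- length(x)
  id <- integer(n)
  cx <- numeric(0); cy <- numeric(0); cn <- integer(0)
  for (i in seq_len(n)) {
    if (length(cx) > 0) {
      d2 <- (cx - x[i])^2 + (cy - y[i])^2
      j <- which.min(d2)
      if (d2[j] < gate^2) {
        id[i] <- j
        cx[j] <- (cx[j] * cn[j] + x[i]) / (cn[j] + 1)
        cy[j] <- (cy[j] * cn[j] + y[i]) / (cn[j] + 1)
        cn[j] <- cn[j] + 1L
        next
      }
    }
    cx <- c(cx, x[i]); cy <- c(cy, y[i]); cn <- c(cn, 1L)
    id[i] <- length(cx)
  }
  id
}

#' Radial indentation profile of a stitched surface
#'
#' Locates the contact centre (least-squares paraboloid fit to the deepest
#' part of the bowl), estimates the undeformed surface height from the far
#' field, and bins the indentation depth radially.
#'
#' @param surface a `stitched_surface` (or data frame with `x_nm`, `y_nm`,
#'   `height_nm`).
#' @param bin_width_nm radial bin width (nm).
#' @param center optional `c(x, y)` contact centre (nm); estimated when
#'   `NULL`.
#' @param baseline optional undeformed surface height (nm); estimated from
#'   the outermost 15% of radii when `NULL`.
#' @return Data frame `r_nm`, `uz_nm` (mean indentation depth per bin,
#'   positive into the gel), `n`; attributes `center` and `baseline`.
#' @export
indentation_profile <- function(surface, bin_width_nm = 500, center = NULL,
                                baseline = NULL) {
  h <- surface$height_nm
  if (is.null(center)) {
    deep <- h <= stats::quantile(h, 0.35)
    fit <- lm(h ~ x + y + I(x^2) + I(y^2),
              data = data.frame(x = surface$x_nm[deep],
                                y = surface$y_nm[deep], h = h[deep]))
    b <- coef(fit)
    if (!is.finite(b["I(x^2)"]) || b["I(x^2)"] <= 0 ||
        !is.finite(b["I(y^2)"]) || b["I(y^2)"] <= 0) {
      center <- c(stats::weighted.mean(surface$x_nm, max(h) - h + 1e-9),
                  stats::weighted.mean(surface$y_nm, max(h) - h + 1e-9))
    } else {
      center <- c(-b["x"] / (2 * b["I(x^2)"]), -b["y"] / (2 * b["I(y^2)"]))
    }
  }
  r <- sqrt((surface$x_nm - center[1])^2 + (surface$y_nm - center[2])^2)
  if (is.null(baseline))
    baseline <- median(h[r >= stats::quantile(r, 0.85)])
  uz <- baseline - h
  bins <- floor(r / bin_width_nm)
  agg <- function(v) vapply(split(v, bins), mean, 0)
  out <- data.frame(r_nm = agg(r), uz_nm = agg(uz),
                    n = as.vector(table(bins)))
  rownames(out) <- NULL
  attr(out, "center") <- unname(center)
  attr(out, "baseline") <- unname(baseline)
  out
}

#' Fit the Hertzian model to an indentation profile
#'
#' Nonlinear least squares of [hertz_uz()] over load P and contact radius a
#' with the gel modulus E held fixed (P and E are degenerate if both
#' float). 1-sigma parameter uncertainties come from the fit covariance.
#'
#' @param r radial distances (m).
#' @param uz indentation depths (m).
#' @param E gel elastic modulus (Pa).
#' @param start optional list with starting `P` (N) and `a` (m).
#' @return List of class `hertz_fit`: `P`, `a`, `se_P`, `se_a`,
#'   `covariance`, `one_sided` (TRUE when all samples lie on one side of
#'   the fitted contact radius) and the underlying `fit` object.
#' @export
fit_hertz <- function(r, uz, E, start = NULL) {
  stopifnot(E > 0, length(r) == length(uz))
  ok <- is.finite(r) & is.finite(uz)
  r <- r[ok]; uz <- uz[ok]
  if (length(r) < 10)
    stop("need at least 10 profile samples to fit the Hertzian model")
  if (is.null(start)) {
    u0 <- max(uz)
    a0 <- r[which.min(abs(uz - u0 / 2))]
    if (a0 <= 0) a0 <- max(r) / 4
    start <- list(P = 4 * E * a0 * max(u0, 1e-12) / 3, a = a0)
  }
  dat <- data.frame(r = r, uz = uz)
  fit <- tryCatch(
    minpack.lm::nlsLM(uz ~ hertz_uz(r, P = P, E = E, a = a),
                      data = dat, start = start,
                      lower = c(P = 1e-15, a = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Hertz fit did not converge: ", conditionMessage(e)))
  cf <- coef(fit)
  V <- tryCatch(vcov(fit), error = function(e) matrix(NA, 2, 2))
  one_sided <- all(r < cf["a"]) || all(r > cf["a"])
  if (one_sided)
    warning("all profile samples lie on one side of the contact radius")
  structure(list(P = unname(cf["P"]), a = unname(cf["a"]),
                 se_P = sqrt(V[1, 1]), se_a = sqrt(V[2, 2]),
                 covariance = V, one_sided = one_sided, fit = fit),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertzian fit: P = %.3f nN (se %.3f), a = %.2f um (se %.2f)\n",
              x$P * 1e9, x$se_P * 1e9, x$a * 1e6, x$se_a * 1e6))
  invisible(x)
}

#' Fit an indentation force from a stitched surface
#'
#' Convenience wrapper: radial profile extraction, far-field baseline
#' estimation iteratively refined against the fitted model's own far-field
#' decay, and the (P, a) least-squares fit with E fixed.
#'
#' @param surface a `stitched_surface`.
#' @param E gel elastic modulus (Pa).
#' @param bin_width_nm radial bin width (nm).
#' @param baseline_iter baseline refinement iterations.
#' @return A `hertz_fit` (see [fit_hertz()]) with the final `profile`
#'   attached.
#' @export
fit_indentation <- function(surface, E, bin_width_nm = 500,
                            baseline_iter = 3) {
  prof <- indentation_profile(surface, bin_width_nm)
  base <- attr(prof, "baseline")
  ctr <- attr(prof, "center")
  fit <- fit_hertz(prof$r_nm * 1e-9, prof$uz_nm * 1e-9, E)
  for (i in seq_len(baseline_iter)) {
    # far-field samples should sit on the model tail, not at zero depth
    r <- sqrt((surface$x_nm - ctr[1])^2 + (surface$y_nm - ctr[2])^2)
    far <- r >= stats::quantile(r, 0.85)
    resid <- surface$height_nm[far] +
      1e9 * hertz_uz(r[far] * 1e-9, P = fit$P, E = E, a = fit$a)
    base <- median(resid)
    prof <- indentation_profile(surface, bin_width_nm, center = ctr,
                                baseline = base)
    fit <- fit_hertz(prof$r_nm * 1e-9, prof$uz_nm * 1e-9, E,
                     start = list(P = fit$P, a = fit$a))
  }
  fit$profile <- prof
  fit
}
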