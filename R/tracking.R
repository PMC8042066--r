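# Trajectories are long-format data frames (bead_id, frame, x_nm, y_nm,
# z_nm) of class "atfm_trajectories", with attributes n_frames (frames the
# acquisition spans) and frames (the frame indices). Only trajectories
# present in every frame ("complete") enter displacement fields.

as_trajectories <- function(df, frames) {
  df <- df[order(df$bead_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, frames = frames, n_frames = length(frames),
            class = c("atfm_trajectories", "data.frame"))
}

#' Which trajectories span the full acquisition?
#'
#' @param trajectories an `atfm_trajectories` object.
#' @return Named logical vector over bead ids.
#' @export
trajectory_complete <- function(trajectories) {
  nf <- attr(trajectories, "n_frames") %||%
    length(unique(trajectories$frame))
  tab <- table(trajectories$bead_id)
  setNames(as.vector(tab) == nf, names(tab))
}

#' Link per-frame localizations into bead trajectories
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate matches
#' between the previous and current frame are processed in order of
#' increasing 3D distance (ties resolved towards the lower bead id) and
#' accepted while both partners are unmatched and the distance is below the
#' gate. Unmatched localizations start new trajectories.
#'
#' @param localizations localization data frame with `frame`, `x_nm`,
#'   `y_nm`, `z_nm`.
#' @param max_displacement_per_frame linking gate (nm).
#' @return An `atfm_trajectories` object.
#' @export
link_trajectories <- function(localizations, max_displacement_per_frame = 500) {
  stopifnot(nrow(localizations) > 0)
  frames <- sort(unique(localizations$frame))
  loc_split <- split(localizations, localizations$frame)
  first <- loc_split[[as.character(frames[1])]]
  n <- nrow(first)
  rows <- vector("list", length(frames))
  first$bead_id <- seq_len(n)
  rows[[1]] <- first
  last_pos <- first  # one row per active trajectory, most recent position
  next_id <- n + 1L
  for (fi in seq_along(frames)[-1]) {
    cur <- loc_split[[as.character(frames[fi])]]
    if (is.null(cur) || nrow(cur) == 0) {
      last_pos <- last_pos[0, ]
      next
    }
    cur$bead_id <- NA_integer_
    if (nrow(last_pos) > 0) {
      d2 <- outer(last_pos$x_nm, cur$x_nm, "-")^2 +
        outer(last_pos$y_nm, cur$y_nm, "-")^2 +
        outer(last_pos$z_nm, cur$z_nm, "-")^2
      cand <- which(d2 < max_displacement_per_frame^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(d2[cand], last_pos$bead_id[cand[, 1]], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        used_prev <- rep(FALSE, nrow(last_pos))
        used_cur <- rep(FALSE, nrow(cur))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_prev[i] && !used_cur[j]) {
            cur$bead_id[j] <- last_pos$bead_id[i]
            used_prev[i] <- TRUE
            used_cur[j] <- TRUE
          }
        }
      }
    }
    new <- which(is.na(cur$bead_id))
    if (length(new) > 0) {
      cur$bead_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    rows[[fi]] <- cur
    last_pos <- cur
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  as_trajectories(out, frames)
}

#' Correct trajectories for rigid 3D sample drift
#'
#' Per-frame drift is the mean displacement (relative to the first frame)
#' of a set of reference beads far from the cell contact; it is subtracted
#' from every trajectory, so the reference beads' mean residual
#' displacement is zero in every frame.
#'
#' @param trajectories an `atfm_trajectories` object.
#' @param reference_ids bead ids of at least 3 complete reference
#'   trajectories.
#' @return Drift-corrected trajectories; the per-frame drift table is
#'   attached as attribute `drift`.
#' @export
drift_correct <- function(trajectories, reference_ids) {
  comp <- trajectory_complete(trajectories)
  refs <- unique(reference_ids)
  refs <- refs[as.character(refs) %in% names(comp)[comp]]
  if (length(refs) < 3)
    stop("drift correction needs at least 3 complete reference trajectories")
  frames <- attr(trajectories, "frames")
  ref <- trajectories[trajectories$bead_id %in% refs, ]
  ref <- ref[order(ref$bead_id, ref$frame), ]
  nfr <- length(frames)
  pos <- lapply(c("x_nm", "y_nm", "z_nm"), function(cn)
    matrix(ref[[cn]], nrow = nfr))
  drift <- vapply(pos, function(m) rowMeans(m - rep(m[1, ],
                                                    each = nfr)),
                  numeric(nfr))
  colnames(drift) <- c("x_nm", "y_nm", "z_nm")
  idx <- match(trajectories$frame, frames)
  out <- trajectories
  out$x_nm <- out$x_nm - drift[idx, "x_nm"]
  out$y_nm <- out$y_nm - drift[idx, "y_nm"]
  out$z_nm <- out$z_nm - drift[idx, "z_nm"]
  attr(out, "drift") <- data.frame(frame = frames, drift)
  out
}

# running median with truncated windows; an even width w covers offsets
# -w/2 ... w/2 - 1 around each sample
running_median <- function(x, width) {
  n <- length(x)
  lo <- -(width %/% 2); hi <- width - 1 - width %/% 2
  vapply(seq_len(n), function(i)
    median(x[max(1, i + lo):min(n, i + hi)]), 0)
}

#' Temporal median filter of trajectories
#'
#' Running median (default width 10 frames) applied per coordinate to each
#' trajectory to remove spurious localizations; windows are centred and
#' truncated at the trajectory ends. For trajectories shorter than the
#' width the window is clamped to the trajectory length.
#'
#' @param trajectories an `atfm_trajectories` object (or any data frame
#'   with `bead_id`, `frame` and coordinate columns).
#' @param width filter width (frames).
#' @return Trajectories with filtered coordinates.
#' @export
temporal_median <- function(trajectories, width = 10) {
  stopifnot(width >= 1)
  ord <- order(trajectories$bead_id, trajectories$frame)
  out <- trajectories
  ids <- trajectories$bead_id[ord]
  for (cn in c("x_nm", "y_nm", "z_nm")) {
    filt <- lapply(split(trajectories[[cn]][ord], ids), function(x)
      running_median(x, min(width, length(x))))
    v <- numeric(nrow(trajectories))
    v[ord] <- unlist(filt, use.names = FALSE)
    out[[cn]] <- v
  }
  out
}

#' Ensemble displacement uncertainty of static beads
#'
#' Per-axis ensemble standard deviation of the displacement of a subset of
#' beads (unperturbed by cellular forces and drift-corrected) relative to
#' their initial position, pooled over beads and the first `n_frames` time
#' points.
#'
#' @param trajectories drift-corrected `atfm_trajectories`, complete over
#'   the analysed window.
#' @param n_frames number of time points analysed.
#' @return An object of class `uncertainty_estimate`: list with `sigma_x`,
#'   `sigma_y`, `sigma_z` (nm), `n_beads`, `n_frames`.
#' @export
estimate_uncertainty <- function(trajectories, n_frames = 100) {
  frames <- attr(trajectories, "frames") %||%
    sort(unique(trajectories$frame))
  frames <- frames[seq_len(min(n_frames, length(frames)))]
  tr <- trajectories[trajectories$frame %in% frames, ]
  comp <- table(tr$bead_id)
  ids <- names(comp)[comp == length(frames)]
  if (length(ids) == 0) stop("no complete trajectories in the window")
  tr <- tr[tr$bead_id %in% ids, ]
  tr <- tr[order(tr$bead_id, tr$frame), ]
  sig <- vapply(c("x_nm", "y_nm", "z_nm"), function(cn) {
    m <- matrix(tr[[cn]], nrow = length(frames))
    d <- m[-1, , drop = FALSE] - rep(m[1, ], each = length(frames) - 1)
    sqrt(mean(d^2))
  }, 0)
  structure(list(sigma_x = sig[[1]], sigma_y = sig[[2]], sigma_z = sig[[3]],
                 n_beads = length(ids), n_frames = length(frames)),
            class = "uncertainty_estimate")
}

#' @export
print.uncertainty_estimate <- function(x, ...) {
  cat(sprintf(
    "displacement uncertainty (%d beads, %d frames):\n  sigma_x = %.2f nm, sigma_y = %.2f nm, sigma_z = %.2f nm\n",
    x$n_beads, x$n_frames, x$sigma_x, x$sigma_y, x$sigma_z))
  invisible(x)
}

#' Automatic reference-bead selection
#'
#' Complete trajectories whose total displacement magnitude lies in the
#' lowest decile (at least `min_n` beads) are proposed as drift references,
#' standing in for "beads far from the cell contact" when no region mask is
#' given.
#'
#' @param trajectories an `atfm_trajectories` object.
#' @param fraction fraction of complete beads to select.
#' @param min_n minimum number of references.
#' @return Vector of bead ids.
#' @export
select_reference_beads <- function(trajectories, fraction = 0.1, min_n = 3) {
  comp <- trajectory_complete(trajectories)
  ids <- as.integer(names(comp)[comp])
  if (length(ids) < min_n) stop("not enough complete trajectories")
  tr <- trajectories[trajectories$bead_id %in% ids, ]
  tr <- tr[order(tr$bead_id, tr$frame), ]
  nfr <- attr(trajectories, "n_frames")
  tot <- vapply(split(seq_len(nrow(tr)), tr$bead_id), function(ii) {
    p <- as.matrix(tr[ii, c("x_nm", "y_nm", "z_nm")])
    sum(sqrt(rowSums(sweep(p, 2, p[1, ])^2)))
  }, 0)
  k <- max(min_n, ceiling(fraction * length(ids)))
  as.integer(names(sort(tot)[seq_len(k)]))
}

#' Grid bead displacements into a displacement field
#'
#' Displacements of complete trajectories relative to the first frame are
#' interpolated onto a regular grid (piecewise-linear interpolation on the
#' Delaunay triangulation of the frame-0 bead positions; grid points
#' outside the convex hull are marked invalid) and then smoothed with a 2D
#' spatial median filter per component.
#'
#' @param trajectories filtered, drift-corrected `atfm_trajectories`.
#' @param grid_spacing grid pitch (nm); default one camera pixel.
#' @param spatial_median_width median filter width (grid points), giving a
#'   604 nm footprint at the default 60.4 nm spacing.
#' @param xlim,ylim optional grid extents (nm); default the bead bounding
#'   box.
#' @param time_step acquisition time step (s), stored as metadata.
#' @return An object of class `displacement_field`: arrays `ux`, `uy`, `uz`
#'   of dim (ny, nx, n_frames) in nm (frame 1 identically zero), grid
#'   vectors `x`, `y` (nm), `valid` mask, `grid_spacing`, `frames`.
#' @export
displacement_field <- function(trajectories, grid_spacing = 60.4,
                               spatial_median_width = 10, xlim = NULL,
                               ylim = NULL, time_step = 1) {
  comp <- trajectory_complete(trajectories)
  ids <- names(comp)[comp]
  if (length(ids) < 4)
    stop("displacement field needs at least 4 complete trajectories")
  tr <- trajectories[trajectories$bead_id %in% ids, ]
  tr <- tr[order(tr$bead_id, tr$frame), ]
  frames <- attr(trajectories, "frames")
  nfr <- length(frames)
  nb <- length(ids)
  X <- matrix(tr$x_nm, nrow = nfr)
  Y <- matrix(tr$y_nm, nrow = nfr)
  Z <- matrix(tr$z_nm, nrow = nfr)
  x0 <- X[1, ]; y0 <- Y[1, ]
  if (is.null(xlim)) xlim <- range(x0)
  if (is.null(ylim)) ylim <- range(y0)
  xo <- seq(xlim[1], xlim[2], by = grid_spacing)
  yo <- seq(ylim[1], ylim[2], by = grid_spacing)
  nx <- length(xo); ny <- length(yo)
  ux <- array(0, c(ny, nx, nfr))
  uy <- array(0, c(ny, nx, nfr))
  uz <- array(0, c(ny, nx, nfr))
  interp_one <- function(v) {
    g <- interp::interp(x = x0, y = y0, z = v, xo = xo, yo = yo,
                        method = "linear", output = "grid")
    t(g$z)  # to rows = y
  }
  valid <- !is.na(interp_one(rep(0, nb)))
  for (ti in seq_len(nfr)[-1]) {
    gx <- cpp_median_filter2(interp_one(X[ti, ] - x0), spatial_median_width)
    gy <- cpp_median_filter2(interp_one(Y[ti, ] - y0), spatial_median_width)
    gz <- cpp_median_filter2(interp_one(Z[ti, ] - Z[1, ]),
                             spatial_median_width)
    gx[!valid] <- NA; gy[!valid] <- NA; gz[!valid] <- NA
    ux[, , ti] <- gx; uy[, , ti] <- gy; uz[, , ti] <- gz
  }
  ux[, , 1][!valid] <- NA
  uy[, , 1][!valid] <- NA
  uz[, , 1][!valid] <- NA
  structure(list(ux = ux, uy = uy, uz = uz, x = xo, y = yo,
                 grid_spacing = grid_spacing, valid = valid,
                 frames = frames, time_step = time_step),
            class = "displacement_field")
}
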