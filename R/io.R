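# File formats. Images travel as multi-page TIFF (16-bit counts in, 32-bit
# float fields out; the float pages are stored min/max-scaled with the
# scaling recorded in a JSON sidecar, NA encoded as a sentinel). Tables
# travel as CSV with a schema line; every output carries a version string.

SCHEMA <- list(localizations = "atfm-localizations v1",
               trajectories = "atfm-trajectories v1",
               field = "atfm-field v1",
               config = "atfm-config v1")

#' Read / write photon-count image stacks
#'
#' 16-bit grayscale multi-page TIFF; values are integer photon counts
#' (clamped to the 16-bit range on write).
#'
#' @param frames list of numeric matrices.
#' @param path TIFF file path.
#' @return `read_image_stack` returns a list of matrices.
#' @export
write_image_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  enc <- lapply(frames, function(f) {
    f <- round(pmin(pmax(f, 0), 65535))
    f / 65535
  })
  tiff::writeTIFF(enc, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) round(p * 65535))
}

# float field stack: each page scaled to [0, 0.9], NA as sentinel 1.0
write_float_stack <- function(pages, path, meta = list()) {
  ranges <- lapply(pages, function(p) {
    fin <- is.finite(p)
    if (!any(fin)) c(0, 0) else range(p[fin])
  })
  enc <- mapply(function(p, rg) {
    s <- if (rg[2] > rg[1]) 0.9 * (p - rg[1]) / (rg[2] - rg[1])
    else p * 0 + 0.45
    s[!is.finite(p)] <- 1
    s
  }, pages, ranges, SIMPLIFY = FALSE)
  tiff::writeTIFF(enc, path, bits.per.sample = 32L)
  meta$schema <- SCHEMA$field
  meta$page_min <- vapply(ranges, `[`, 0, 1)
  meta$page_max <- vapply(ranges, `[`, 0, 2)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_float_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, SCHEMA$field))
    stop(sprintf("field schema mismatch: expected '%s', found '%s'",
                 SCHEMA$field, meta$schema %||% "<none>"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  dec <- mapply(function(p, mn, mx) {
    out <- if (mx > mn) p / 0.9 * (mx - mn) + mn else p * 0 + mn
    out[p >= 0.999999] <- NA
    out
  }, pages, meta$page_min, meta$page_max, SIMPLIFY = FALSE)
  list(pages = dec, meta = meta)
}

write_table_schema <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", schema), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_table_schema <- function(path, schema) {
  first <- readLines(path, n = 1)
  found <- sub("^# ", "", first)
  if (!identical(found, schema))
    stop(sprintf("schema mismatch in %s: expected '%s', found '%s'",
                 path, schema, found))
  read.csv(path, skip = 1)
}

#' Read / write localization tables
#'
#' CSV with columns `frame`, `x_nm`, `y_nm`, `z_nm`, `photons`,
#' `background`, `crlb_x`, `crlb_y`, `crlb_z`, `loglik` and a schema
#' version line.
#'
#' @param localizations localization data frame.
#' @param path CSV path.
#' @export
write_localizations <- function(localizations, path)
  write_table_schema(localizations, path, SCHEMA$localizations)

#' @rdname write_localizations
#' @export
read_localizations <- function(path)
  read_table_schema(path, SCHEMA$localizations)

#' Read / write trajectory tables
#'
#' @param trajectories an `atfm_trajectories` object.
#' @param path CSV path.
#' @export
write_trajectories <- function(trajectories, path)
  write_table_schema(as.data.frame(trajectories), path, SCHEMA$trajectories)

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- read_table_schema(path, SCHEMA$trajectories)
  as_trajectories(df, sort(unique(df$frame)))
}

#' Write / read a displacement field container
#'
#' Multi-page 32-bit TIFF (pages ordered component-major: all ux frames,
#' then uy, then uz) plus a JSON sidecar with grid metadata.
#'
#' @param field a [displacement_field()].
#' @param path TIFF path (sidecar at `<path>.json`).
#' @export
write_displacement_field <- function(field, path) {
  nt <- dim(field$ux)[3]
  pages <- c(lapply(seq_len(nt), function(t) field$ux[, , t]),
             lapply(seq_len(nt), function(t) field$uy[, , t]),
             lapply(seq_len(nt), function(t) field$uz[, , t]))
  write_float_stack(pages, path, meta = list(
    kind = "displacement_field", n_frames = nt,
    grid_spacing = field$grid_spacing, x0 = field$x[1], y0 = field$y[1],
    nx = length(field$x), ny = length(field$y),
    time_step = field$time_step, units = "nm",
    frames = field$frames))
  invisible(path)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  fs <- read_float_stack(path)
  m <- fs$meta
  nt <- m$n_frames
  arr <- function(off) {
    a <- array(NA_real_, c(m$ny, m$nx, nt))
    for (t in seq_len(nt)) a[, , t] <- fs$pages[[off + t]]
    a
  }
  x <- m$x0 + (seq_len(m$nx) - 1) * m$grid_spacing
  y <- m$y0 + (seq_len(m$ny) - 1) * m$grid_spacing
  ux <- arr(0)
  structure(list(ux = ux, uy = arr(nt), uz = arr(2 * nt), x = x, y = y,
                 grid_spacing = m$grid_spacing,
                 valid = is.finite(ux[, , 1]), frames = m$frames,
                 time_step = m$time_step),
            class = "displacement_field")
}

#' Write / read a stress field container
#'
#' @param stress a `stress_field` (or list of them, one per time point).
#' @param path TIFF path.
#' @export
write_stress_field <- function(stress, path) {
  if (inherits(stress, "stress_field")) stress <- list(stress)
  nt <- length(stress)
  pages <- c(lapply(stress, `[[`, "Sx"), lapply(stress, `[[`, "Sy"),
             lapply(stress, `[[`, "Sz"))
  write_float_stack(pages, path, meta = list(
    kind = "stress_field", n_frames = nt,
    grid_spacing = stress[[1]]$grid_spacing, units = "Pa"))
  invisible(path)
}

#' @rdname write_stress_field
#' @export
read_stress_field <- function(path) {
  fs <- read_float_stack(path)
  nt <- fs$meta$n_frames
  lapply(seq_len(nt), function(t) {
    structure(list(Sx = fs$pages[[t]], Sy = fs$pages[[nt + t]],
                   Sz = fs$pages[[2 * nt + t]],
                   grid_spacing = fs$meta$grid_spacing),
              class = "stress_field")
  })
}
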