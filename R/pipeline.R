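# Pipeline driver: localize -> filter overlaps -> link -> drift-correct ->
# temporal median -> displacement field -> stress inversion, with a QC
# report of bead counts per stage.

#' Pipeline configuration
#'
#' Validated parameter set for [run_pipeline()]; the defaults are the
#' reference acquisition settings (60.4 nm pixel, temporal median width 10
#' frames, spatial median width 10 pixels = 604 nm, Poisson's ratio
#' 0.495).
#'
#' @param pixel_size camera pixel (nm).
#' @param gel_E gel elastic modulus (Pa); `NULL` skips the stress stage.
#' @param gel_nu Poisson's ratio.
#' @param temporal_median_width trajectory median filter width (frames).
#' @param spatial_median_width field median filter width (grid points).
#' @param linking_gate maximum displacement per frame when linking (nm).
#' @param fit_window MLE fit window (pixels, odd).
#' @param min_intensity candidate detection threshold above the frame
#'   median (photons).
#' @param min_separation candidate separation (pixels).
#' @param exclusion_radius overlap-rejection radius (nm); `NULL` derives
#'   it from the PSF model ([default_exclusion_radius()]).
#' @param grid_spacing displacement grid pitch (nm); defaults to one pixel.
#' @param reference_ids drift-reference bead ids; `NULL` selects the
#'   lowest-motion decile automatically.
#' @param camera_gain,camera_offset camera-count to photon conversion.
#' @param regularization stress-inversion damping.
#' @param seed seed for any stochastic step.
#' @return Object of class `atfm_config`.
#' @export
atfm_config <- function(pixel_size = 60.4, gel_E = NULL, gel_nu = 0.495,
                        temporal_median_width = 10,
                        spatial_median_width = 10, linking_gate = 500,
                        fit_window = 13, min_intensity = 50,
                        min_separation = 7, exclusion_radius = NULL,
                        grid_spacing = NULL, reference_ids = NULL,
                        camera_gain = 1, camera_offset = 0,
                        regularization = 0, seed = 1) {
  cfg <- structure(list(pixel_size = pixel_size, gel_E = gel_E,
                        gel_nu = gel_nu,
                        temporal_median_width = temporal_median_width,
                        spatial_median_width = spatial_median_width,
                        linking_gate = linking_gate,
                        fit_window = fit_window,
                        min_intensity = min_intensity,
                        min_separation = min_separation,
                        exclusion_radius = exclusion_radius,
                        grid_spacing = grid_spacing %||% pixel_size,
                        reference_ids = reference_ids,
                        camera_gain = camera_gain,
                        camera_offset = camera_offset,
                        regularization = regularization, seed = seed),
                   class = "atfm_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- c("pixel_size", "temporal_median_width", "spatial_median_width",
           "linking_gate", "fit_window", "grid_spacing", "camera_gain")
  for (p in pos)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop("config: '", p, "' must be positive")
  if (!is.null(cfg$gel_E) && cfg$gel_E <= 0)
    stop("config: 'gel_E' must be positive")
  if (cfg$gel_nu <= 0 || cfg$gel_nu >= 0.5)
    stop("config: 'gel_nu' must lie strictly between 0 and 0.5")
  if (cfg$fit_window %% 2 != 1) stop("config: 'fit_window' must be odd")
  if (cfg$regularization < 0) stop("config: negative regularization")
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config an [atfm_config()] object.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$schema <- SCHEMA$config
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, SCHEMA$config))
    stop(sprintf("config schema mismatch: expected '%s', found '%s'",
                 SCHEMA$config, obj$schema %||% "<none>"))
  obj$schema <- NULL
  do.call(atfm_config, obj)
}

#' Localize beads in every frame of a movie
#'
#' Candidate detection (threshold = frame median + `min_intensity`) and
#' MLE fitting, per frame.
#'
#' @param frames list of photon-count matrices.
#' @param model an `astig_psf` model.
#' @param config an [atfm_config()].
#' @return Localization data frame over all frames (0-based frame index).
#' @export
localize_movie <- function(frames, model, config = atfm_config()) {
  res <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    img <- frames[[t]]
    cand <- detect_candidates(img, median(img) + config$min_intensity,
                              config$min_separation)
    res[[t]] <- suppressMessages(
      fit_mle(img, model, cand, window = config$fit_window,
              frame = t - 1L, camera_gain = config$camera_gain,
              camera_offset = config$camera_offset))
  }
  do.call(rbind, res)
}

#' Run the full aTFM pipeline on a movie
#'
#' Executes localize -> overlap filter -> link -> drift-correct ->
#' temporal median -> displacement field -> stress inversion, logging
#' per-stage bead counts and timings to stderr, and returns all
#' intermediate products plus a QC report. Stage failures are reported
#' with the stage name; products of completed stages are preserved in the
#' error's `partial` attribute.
#'
#' @param config an [atfm_config()].
#' @param movie list of photon-count matrices (or a TIFF path).
#' @param psf_model an `astig_psf` model (or a PSF container path).
#' @return List with `localizations`, `trajectories` (drift-corrected,
#'   filtered), `field` ([displacement_field()]), `stress` (list of
#'   `stress_field` per frame, when `gel_E` is set) and `qc`.
#' @export
run_pipeline <- function(config, movie, psf_model) {
  stopifnot(inherits(config, "atfm_config"))
  if (is.character(movie)) movie <- read_image_stack(movie)
  if (is.character(psf_model)) psf_model <- read_psf_model(psf_model)
  qc <- list()
  done <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                 conditionMessage(e)))
      attr(err, "partial") <- done
      stop(err)
    })
    message(sprintf("[%s] %.2f s", name, proc.time()[["elapsed"]] - t0))
    out
  }

  locs <- stage("localize", localize_movie(movie, psf_model, config))
  qc$n_localizations <- nrow(locs)
  done$localizations <- locs

  radius <- config$exclusion_radius %||% default_exclusion_radius(psf_model)
  locs_f <- stage("filter_overlaps", filter_overlaps(locs, radius))
  qc$exclusion_radius <- radius
  qc$n_after_overlap_filter <- nrow(locs_f)

  traj <- stage("link", link_trajectories(locs_f, config$linking_gate))
  comp <- trajectory_complete(traj)
  qc$n_trajectories <- length(comp)
  qc$n_complete <- sum(comp)
  area_um2 <- prod(dim(movie[[1]])) * (config$pixel_size * 1e-3)^2
  qc$final_density_per_um2 <- sum(comp) / area_um2

  refs <- config$reference_ids %||%
    stage("select_references", select_reference_beads(traj))
  traj <- stage("drift_correct", drift_correct(traj, refs))
  qc$n_reference_beads <- length(refs)
  qc$uncertainty <- stage(
    "estimate_uncertainty",
    estimate_uncertainty(traj[traj$bead_id %in% refs, , drop = FALSE],
                         n_frames = attr(traj, "n_frames")))
  done$trajectories <- traj

  tm_width <- min(config$temporal_median_width, attr(traj, "n_frames"))
  traj_f <- stage("temporal_median", temporal_median(traj, tm_width))
  field <- stage("displacement_field",
                 displacement_field(traj_f, config$grid_spacing,
                                    config$spatial_median_width))
  done$field <- field

  stress <- NULL
  if (!is.null(config$gel_E)) {
    gel <- gel_properties(config$gel_E, config$gel_nu)
    stress <- stage("stress", lapply(seq_along(field$frames), function(t)
      traction_from_displacement(field, gel, config$regularization, t = t)))
  }
  list(localizations = locs, trajectories = traj_f, field = field,
       stress = stress, qc = qc)
}
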