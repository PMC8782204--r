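#' Pipeline configuration with documented defaults
#'
#' Collects every tunable of the localization and index pipelines in one flat
#' list. Defaults follow the hardware and algorithm settings the method was
#' built around: 3.5 mm contact pitch and 2 mm contact diameter (the implanted
#' electrodes' geometry), a 2 mm center-of-mass cube, 500 ms energy smoothing,
#' a 250 ms energy-coefficient window, 60-140 Hz high-gamma and 80-250 Hz
#' ripple bands with a 50 Hz Q=30 notch, a 10-sigma onset threshold, and the
#' 20 ms merge gap / 50 ms minimum duration of the interictal event detector.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `seeg_config`.
#' @examples
#' cfg <- seeg_config(pitch_mm = 3)
#' cfg$pitch_mm
#' @export
seeg_config <- function(...) {
  cfg <- list(
    # electrode localization
    threshold_rule   = "relative:0.5",  # or "percentile:<p>", "otsu", "absolute:<v>"
    presmooth_sigma_mm = 0.5,    # Gaussian presmoothing; 0 disables
    pitch_mm         = 3.5,      # contact center-to-center spacing
    cube_mm          = 2.0,      # center-of-mass cube edge (contact size)
    max_contacts     = 16L,
    direction_granularity = 3L,  # icosphere subdivision level
    distance_bin     = 1.0,      # Hough anchor bin, voxels
    inlier_radius_mm = 2.0,      # Hough inlier distance (mm; resolution-free)
    min_votes        = NA_real_, # NA: max(10, 25% of first peak)
    n_electrodes     = NA_integer_, # NA: vote-based stopping
    com_max_iter     = 30L,
    com_tol_voxel    = 0.01,     # displacement stop for center-of-mass steps
    gmm_seed         = 1L,
    # ictal index
    highgamma_band   = c(60, 140),
    notch_hz         = 50,
    notch_q          = 30,
    filter_order     = 5L,
    smooth_window_ms = 500,
    k_sigma          = 10,
    ec_window_ms     = 250,
    # interictal index
    ripple_band      = c(80, 250),
    merge_gap_ms     = 20,
    min_duration_ms  = 50
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop_seeg("bad_config", "config overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop_seeg("bad_config", "unknown config keys: ",
                paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "seeg_config")
}

#' @export
print.seeg_config <- function(x, ...) {
  cat("<seeg_config>\n")
  for (k in names(x))
    cat("  ", k, " = ", paste(format(x[[k]]), collapse = " "), "\n", sep = "")
  invisible(x)
}

# One-line flat-JSON echo used in TSV output headers and CLI logs.
config_echo <- function(cfg) {
  as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                                na = "null"))
}

seeg_log <- function(...) {
  if (isTRUE(getOption("seegquake.quiet", TRUE))) return(invisible(NULL))
  message("[seegquake] ", ...)
}
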