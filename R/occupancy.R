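#' Deployable sensor configuration
#'
#' Bundles every parameter the per-frame sensor needs.  The defaults are the
#' deployed field values: a 5 degC shift of the mean floor temperature, a
#' Multiple Nest Occupation Threshold (MNOT) of 796 colored pixels and a
#' triangular head template of 43 x 33 pixels (height x base).
#'
#' @param shift Celsius shift added to the floor temperature to build the
#'   Background Color Threshold (calibration settings: 1, 3 or 5 degC).
#' @param mnot Multiple Nest Occupation Threshold, pixels: CP strictly above
#'   it flags a multiple occupation.
#' @param min_particle_area area-opening threshold, pixels (components
#'   smaller than this are treated as noise).
#' @param template the hen template used for pattern recognition.
#' @param match_threshold minimum NCC score accepted as a hen detection.
#' @param rotation_step template rotation increment, degrees.
#' @param max_hens cap on the reported hen count.
#' @param calibration the frame's [temperature_calibration()].
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(shift = 5, mnot = 796L, min_particle_area = 50L,
                          template = render_template("triangle", 43, 33),
                          match_threshold = 0.5, rotation_step = 30,
                          max_hens = 5L,
                          calibration = temperature_calibration()) {
  if (shift < 0) stop_config("shift must be non-negative")
  if (mnot < 0) stop_config("mnot must be non-negative")
  if (min_particle_area < 0) stop_config("min_particle_area must be non-negative")
  if (match_threshold <= 0 || match_threshold > 1) {
    stop_config("match_threshold must be in (0, 1]")
  }
  if (rotation_step <= 0 || rotation_step > 360) {
    stop_config("rotation_step must be in (0, 360]")
  }
  if (max_hens < 1) stop_config("max_hens must be >= 1")
  stopifnot(inherits(template, "hen_template"),
            inherits(calibration, "temperature_calibration"))
  structure(list(shift = shift, mnot = as.integer(mnot),
                 min_particle_area = as.integer(min_particle_area),
                 template = template, match_threshold = match_threshold,
                 rotation_step = rotation_step, max_hens = as.integer(max_hens),
                 calibration = calibration),
            class = "sensor_config")
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf(paste0("<sensor_config> shift %g degC, MNOT %d px, template %s %dx%d,\n",
                     "  match threshold %g, rotation step %g deg, min particle %d px, max hens %d\n"),
              x$shift, x$mnot, x$template$shape_kind, x$template$height,
              x$template$base, x$match_threshold, x$rotation_step,
              x$min_particle_area, x$max_hens))
  invisible(x)
}

#' Multiple Nest Occupation flag
#'
#' MNO is 1 when the colored-pixel count strictly exceeds the MNOT ("CP
#' overcame the MNOT"), 0 otherwise.
#'
#' @param cp colored-pixel count.
#' @param mnot Multiple Nest Occupation Threshold, pixels.
#' @return 0 or 1 (integer).
#' @export
classify_mno <- function(cp, mnot) {
  if (any(cp < 0) || any(mnot < 0)) stop_input("cp and mnot must be non-negative")
  as.integer(cp > mnot)
}

#' Run the per-frame nest-usage sensor
#'
#' Executes the full per-frame pipeline: intensity histogram, floor
#' temperature (histogram mode), BCT = floor + shift, binarization, small-
#' particle filtering, colored-pixel count, MNO flag, and - only when a
#' multiple occupation is flagged - rotated-template pattern recognition to
#' count the hens.  When MNO is 0 the hen count is 1 if CP exceeds the
#' minimum particle area (one hen present) and 0 otherwise (empty nest).
#'
#' @param frame a [thermal_frame()].
#' @param config a [sensor_config()].
#' @return An `occupancy_result`: list with `cp`, `mno`, `hen_count`,
#'   `detections` (data.frame, see [match_template_rotations()]),
#'   `background_temp`, `bct` and `timestamp`.
#' @export
process_frame <- function(frame, config = sensor_config()) {
  stopifnot(inherits(frame, "thermal_frame"), inherits(config, "sensor_config"))
  background_temp <- estimate_background_temperature(frame)
  bct <- compute_bct(background_temp, config$shift, frame$calibration)
  bin <- binarize(frame, bct)
  filt <- filter_small_particles(bin, config$min_particle_area)
  cp <- count_colored_pixels(filt)
  mno <- classify_mno(cp, config$mnot)
  if (mno == 1L) {
    detections <- match_template_rotations(filt, config$template,
                                           rotation_step = config$rotation_step,
                                           threshold = config$match_threshold)
    hen_count <- min(nrow(detections), config$max_hens)
  } else {
    detections <- data.frame(row_offset = integer(0), col_offset = integer(0),
                             center_row = numeric(0), center_col = numeric(0),
                             score = numeric(0), rotation = numeric(0))
    hen_count <- if (cp > config$min_particle_area) 1L else 0L
  }
  structure(list(cp = cp, mno = mno, hen_count = as.integer(hen_count),
                 detections = detections, background_temp = background_temp,
                 bct = bct, timestamp = frame$timestamp),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("<occupancy_result> CP %d, MNO %d, hens %d, floor %.1f degC (BCT %d)\n",
              x$cp, x$mno, x$hen_count, x$background_temp, x$bct))
  invisible(x)
}

#' Process a sequence of frames
#'
#' Applies [process_frame()] to each frame in order (one evaluation per
#' frame).  Frames that fail to process are skipped with a warning and
#' reported in the `skipped` attribute.
#'
#' @param frames list of [thermal_frame()] objects sharing a calibration.
#' @param config a [sensor_config()].
#' @return List of `occupancy_result`, one per processed frame, with
#'   attribute `skipped` (integer indices of failed frames).
#' @export
process_sequence <- function(frames, config = sensor_config()) {
  results <- vector("list", length(frames))
  skipped <- integer(0)
  for (k in seq_along(frames)) {
    res <- tryCatch(process_frame(frames[[k]], config), error = function(e) e)
    if (inherits(res, "error")) {
      warning("frame ", k, " skipped: ", conditionMessage(res))
      skipped <- c(skipped, k)
    } else {
      results[[k]] <- res
    }
  }
  results <- results[!vapply(results, is.null, logical(1))]
  attr(results, "skipped") <- skipped
  results
}

#' Tabulate occupancy results
#'
#' @param results list of `occupancy_result` from [process_sequence()].
#' @return data.frame with one row per frame: `timestamp`, `cp`, `mno`,
#'   `hen_count`, `background_temp`.
#' @export
occupancy_table <- function(results) {
  data.frame(
    timestamp = vapply(results, function(r) r$timestamp, numeric(1)),
    cp = vapply(results, function(r) r$cp, numeric(1)),
    mno = vapply(results, function(r) r$mno, integer(1)),
    hen_count = vapply(results, function(r) r$hen_count, integer(1)),
    background_temp = vapply(results, function(r) r$background_temp, numeric(1))
  )
}
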