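#' Linear temperature calibration of a thermographic frame
#'
#' Thermographic frames are 8-bit grayscale images in which each pixel
#' intensity corresponds to a measured surface temperature.  The mapping is
#' modelled as affine over the full intensity range: intensity 0 maps to
#' `temp_at_0` degrees Celsius and intensity 255 to `temp_at_255`.
#'
#' The default calibration spans 0-51 degrees C, i.e. 0.2 degrees C per
#' intensity step, comfortably finer than the +/- 2 degrees C accuracy of
#' typical uncooled microbolometer cameras.
#'
#' @param temp_at_0 temperature (degrees C) mapped to intensity 0.
#' @param temp_at_255 temperature (degrees C) mapped to intensity 255; must
#'   exceed `temp_at_0`.
#' @return An object of class `temperature_calibration`.
#' @examples
#' calib <- temperature_calibration(0, 51)
#' temperature_to_intensity(25.5, calib)  # 128
#' intensity_to_temperature(128, calib)   # 25.6
#' @export
temperature_calibration <- function(temp_at_0 = 0, temp_at_255 = 51) {
  if (!is.numeric(temp_at_0) || !is.numeric(temp_at_255) ||
      length(temp_at_0) != 1L || length(temp_at_255) != 1L ||
      !is.finite(temp_at_0) || !is.finite(temp_at_255)) {
    stop_config("calibration temperatures must be finite scalars")
  }
  if (temp_at_255 <= temp_at_0) {
    stop_config("invalid calibration: temp_at_255 (", temp_at_255,
                ") must exceed temp_at_0 (", temp_at_0, ")")
  }
  structure(list(temp_at_0 = as.numeric(temp_at_0),
                 temp_at_255 = as.numeric(temp_at_255)),
            class = "temperature_calibration")
}

#' @export
print.temperature_calibration <- function(x, ...) {
  cat(sprintf("<temperature_calibration> intensity 0 = %g degC, 255 = %g degC (%.4g degC/step)\n",
              x$temp_at_0, x$temp_at_255, (x$temp_at_255 - x$temp_at_0) / 255))
  invisible(x)
}

#' Convert temperatures to 8-bit intensities and back
#'
#' `temperature_to_intensity()` applies the affine calibration map, rounds
#' half-up to the nearest integer and clips to \[0, 255\].
#' `intensity_to_temperature()` is the exact affine inverse (no rounding).
#'
#' @param temp temperature(s) in degrees Celsius.
#' @param intensity intensity value(s) in \[0, 255\].
#' @param calib a [temperature_calibration()].
#' @return Integer intensities, or numeric temperatures.
#' @export
temperature_to_intensity <- function(temp, calib = temperature_calibration()) {
  stopifnot(inherits(calib, "temperature_calibration"))
  x <- (temp - calib$temp_at_0) / (calib$temp_at_255 - calib$temp_at_0) * 255
  as.integer(pmin(255, pmax(0, round_half_up(x))))
}

#' @rdname temperature_to_intensity
#' @export
intensity_to_temperature <- function(intensity, calib = temperature_calibration()) {
  stopifnot(inherits(calib, "temperature_calibration"))
  if (any(intensity < 0 | intensity > 255)) {
    stop_input("intensity out of [0, 255]")
  }
  calib$temp_at_0 + intensity / 255 * (calib$temp_at_255 - calib$temp_at_0)
}

#' Thermographic frame
#'
#' A thermal frame is a matrix of 8-bit intensities (rows = image rows,
#' origin top-left) together with its temperature calibration and an
#' optional timestamp in seconds.  The reference camera resolution is
#' 320 x 240 pixels but any size is accepted.
#'
#' @param pixels integer/numeric matrix with values in \[0, 255\].
#' @param calibration a [temperature_calibration()].
#' @param timestamp optional acquisition time in seconds.
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(pixels, calibration = temperature_calibration(),
                          timestamp = NA_real_) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop_input("pixels must be a non-empty matrix")
  }
  if (anyNA(pixels) || any(pixels < 0 | pixels > 255)) {
    stop_input("pixel intensities must lie in [0, 255]")
  }
  stopifnot(inherits(calibration, "temperature_calibration"))
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, calibration = calibration,
                 timestamp = as.numeric(timestamp)),
            class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("<thermal_frame> %d x %d px, intensities [%d, %d]%s\n",
              ncol(x$pixels), nrow(x$pixels), min(x$pixels), max(x$pixels),
              if (is.na(x$timestamp)) "" else sprintf(", t = %gs", x$timestamp)))
  invisible(x)
}

#' Intensity histogram of a frame
#'
#' Counts pixels at each of the 256 intensity levels.  The counts always sum
#' to the number of pixels in the frame.
#'
#' @param frame a [thermal_frame()] or an intensity matrix.
#' @return Integer vector of length 256; element `i` counts pixels with
#'   intensity `i - 1`.
#' @export
compute_histogram <- function(frame) {
  px <- as_pixel_matrix(frame)
  tabulate(as.integer(px) + 1L, nbins = 256L)
}

#' Estimate the floor (background) temperature of a frame
#'
#' The intensity histogram of a nest-interior frame is dominated by a
#' near-normal background component (the floor), possibly with a smaller
#' warm-body component at higher intensities.  The global mean would be
#' biased upward by the warm pixels, so the estimator takes the mode of the
#' histogram after smoothing with a centred moving average: the arg-max bin
#' (lowest intensity on ties), converted to degrees Celsius.  This estimates
#' the mean of the dominant normal component.
#'
#' @param frame a [thermal_frame()].
#' @param smooth_window width, in bins, of the moving-average smoother
#'   (default 5); truncated at the histogram edges.
#' @return Background temperature in degrees Celsius.
#' @export
estimate_background_temperature <- function(frame, smooth_window = 5L) {
  stopifnot(inherits(frame, "thermal_frame"))
  h <- compute_histogram(frame)
  half <- (as.integer(smooth_window) - 1L) %/% 2L
  # centred moving average with truncated (partial) windows at the edges
  cs <- c(0, cumsum(h))
  lo <- pmax(seq_len(256L) - half, 1L)
  hi <- pmin(seq_len(256L) + half, 256L)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  # smoothing can flatten a sharp peak into a plateau of tied bins; break
  # ties by the raw count, then toward the lower intensity
  cand <- which(sm == max(sm))
  mode_intensity <- cand[which.max(h[cand])] - 1L
  intensity_to_temperature(mode_intensity, frame$calibration)
}

#' Background Color Threshold (BCT)
#'
#' The BCT is the binarization threshold: the estimated floor temperature
#' plus a configured Celsius shift, converted to a grayscale intensity.
#' Pixels strictly above the BCT are treated as warm-body foreground.
#'
#' @param background_temp floor temperature in degrees Celsius.
#' @param shift non-negative Celsius shift added to the floor temperature
#'   (deployed value 5 degrees C; 1 and 3 are the other calibration settings).
#' @param calib a [temperature_calibration()].
#' @return Intensity threshold in \[0, 255\].
#' @export
compute_bct <- function(background_temp, shift, calib = temperature_calibration()) {
  if (shift < 0) stop_config("shift must be non-negative")
  temp <- background_temp + shift
  if (temp > calib$temp_at_255) {
    warning("BCT temperature ", temp, " degC above calibration range; clipped to 255")
  }
  temperature_to_intensity(temp, calib)
}

#' Binarize a frame at the BCT
#'
#' Pixels strictly greater than the threshold become 1 (foreground), all
#' others 0.  A threshold named after the background must not itself be
#' foreground, hence the strict comparison.
#'
#' @param frame a [thermal_frame()] or intensity matrix.
#' @param bct intensity threshold in \[0, 255\].
#' @return 0/1 integer matrix of the same shape, with attribute `bct`.
#' @export
binarize <- function(frame, bct) {
  if (bct < 0 || bct > 255) stop_input("bct out of [0, 255]")
  px <- as_pixel_matrix(frame)
  out <- matrix(as.integer(px > bct), nrow = nrow(px))
  attr(out, "bct") <- bct
  out
}
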