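#' Valid-mode cross-correlation of an image with a template
#'
#' Computes `C(i, j) = sum_{x, y} t(x, y) * p(x + i, y + j)` over all offsets
#' where the template lies fully inside the image (no padding).  Offsets are
#' 0-based: entry `[a, b]` of the returned matrix (1-based R indexing) is the
#' score at offset `(a - 1, b - 1)` from the top-left corner.  The offset
#' maximizing the map is the most likely template location.
#'
#' @param image numeric matrix (W x Z in rows x cols).
#' @param template numeric matrix (U x V) with U <= W, V <= Z, or a
#'   `hen_template`.
#' @return A `(W-U+1) x (Z-V+1)` numeric matrix of raw correlation scores.
#' @seealso [normalized_cross_correlate()] for the intensity-invariant score.
#' @export
cross_correlate <- function(image, template) {
  p <- as_pixel_matrix(image)
  t <- template_mask(template)
  if (nrow(t) > nrow(p) || ncol(t) > ncol(p)) {
    stop_input("template (", nrow(t), "x", ncol(t), ") larger than image (",
               nrow(p), "x", ncol(p), ")")
  }
  storage.mode(p) <- "double"; storage.mode(t) <- "double"
  cpp_cross_correlate(p, t)
}

#' Normalized cross-correlation (NCC)
#'
#' The raw correlation of [cross_correlate()] grows with overall image
#' brightness, so a bright empty frame can outscore a true match.  NCC
#' removes that dependence: at each offset the template and the image window
#' are mean-centred and the product is divided by the two root-sum-square
#' deviations, giving a score in \[-1, 1\] that is invariant under any
#' positive affine transform `p -> a * p + b` of the image intensities.
#' A score of 1 marks an exact (up to affine intensity change) copy of the
#' template.  Windows with zero intensity variance carry no evidence and
#' score 0 by convention; a constant template is an error since its own
#' variance term would vanish.
#'
#' @inheritParams cross_correlate
#' @return A `(W-U+1) x (Z-V+1)` numeric matrix of scores in \[-1, 1\];
#'   entry `[a, b]` is the score at 0-based offset `(a - 1, b - 1)`.
#' @export
normalized_cross_correlate <- function(image, template) {
  p <- as_pixel_matrix(image)
  t <- template_mask(template)
  if (nrow(t) > nrow(p) || ncol(t) > ncol(p)) {
    stop_input("template (", nrow(t), "x", ncol(t), ") larger than image (",
               nrow(p), "x", ncol(p), ")")
  }
  if (length(unique(as.vector(t))) == 1L) {
    stop_input("constant template: normalized cross-correlation undefined")
  }
  storage.mode(p) <- "double"; storage.mode(t) <- "double"
  cpp_ncc(p, t)
}

#' Match a template over a set of rotations
#'
#' Hens sit at arbitrary orientations, so the template is matched at every
#' rotation in `{0, step, 2 step, ...} < 360` degrees (nearest-neighbour
#' re-rasterized, re-binarized).  Scores are pooled by window centre, the
#' per-centre maximum over rotations is kept, and candidates at or above
#' `threshold` go through greedy non-maximum suppression: highest score
#' first, suppressing any candidate whose centre lies within
#' `suppression_radius` of an accepted detection.  The default radius is the
#' longest side of the template: self-match artifacts (e.g. a triangle
#' re-matching its own 180-degree flip at a small offset) are bounded by the
#' template extent, so one hen cannot yield two counts, while genuinely
#' distinct hens sit farther apart than one template length.
#'
#' @param image numeric or 0/1 matrix (the sensor matches on the binarized,
#'   particle-filtered frame).
#' @param template a `hen_template` or 0/1 matrix.
#' @param rotation_step rotation increment in degrees, in (0, 360].
#' @param threshold minimum NCC score for a detection, in (0, 1].
#' @param suppression_radius minimum centre-to-centre distance, pixels.
#' @return data.frame of detections sorted by descending score: 0-based
#'   `row_offset`/`col_offset` of the rotated template's top-left corner,
#'   `center_row`/`center_col`, `score`, `rotation` (degrees).
#' @export
match_template_rotations <- function(image, template, rotation_step = 30,
                                     threshold = 0.5,
                                     suppression_radius = NULL) {
  if (rotation_step <= 0 || rotation_step > 360) {
    stop_input("rotation_step must be in (0, 360]")
  }
  if (threshold <= 0 || threshold > 1) stop_input("threshold must be in (0, 1]")
  p <- as_pixel_matrix(image)
  mask0 <- template_mask(template)
  if (is.null(suppression_radius)) {
    suppression_radius <- max(nrow(mask0), ncol(mask0))
  }
  angles <- seq(0, 360 - rotation_step, by = rotation_step)
  cand <- vector("list", length(angles))
  for (k in seq_along(angles)) {
    mk <- rotate_mask(mask0, angles[k])
    if (nrow(mk) > nrow(p) || ncol(mk) > ncol(p)) {
      warning("rotated template (", angles[k], " deg) exceeds image; rotation skipped")
      next
    }
    if (sum(mk) == 0L) next
    r <- normalized_cross_correlate(p, mk)
    hits <- which(r >= threshold)
    if (length(hits) == 0L) next
    i0 <- (hits - 1L) %% nrow(r)   # 0-based row offset
    j0 <- (hits - 1L) %/% nrow(r)  # 0-based col offset
    cand[[k]] <- data.frame(row_offset = i0, col_offset = j0,
                            center_row = i0 + (nrow(mk) - 1) / 2,
                            center_col = j0 + (ncol(mk) - 1) / 2,
                            score = r[hits], rotation = angles[k])
  }
  cand <- do.call(rbind, cand)
  empty <- data.frame(row_offset = integer(0), col_offset = integer(0),
                      center_row = numeric(0), center_col = numeric(0),
                      score = numeric(0), rotation = numeric(0))
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  # keep the best rotation per window centre, then greedy NMS
  cand <- cand[order(-cand$score, cand$center_row, cand$center_col, cand$rotation), ]
  acc <- empty
  for (idx in seq_len(nrow(cand))) {
    if (nrow(acc) > 0L) {
      d2 <- (acc$center_row - cand$center_row[idx])^2 +
            (acc$center_col - cand$center_col[idx])^2
      if (min(d2) <= suppression_radius^2) next
    }
    acc <- rbind(acc, cand[idx, ])
  }
  rownames(acc) <- NULL
  acc
}

#' Count hens in a binary frame by rotated template matching
#'
#' The number of accepted template detections, capped at `config$max_hens`
#' to guard against noise-driven runaway counts.
#'
#' @param binary_image 0/1 matrix (binarized, particle-filtered frame).
#' @param template a `hen_template`; defaults to `config$template`.
#' @param config a [sensor_config()].
#' @return Integer hen count.
#' @export
count_hens <- function(binary_image, template = config$template,
                       config = sensor_config()) {
  det <- match_template_rotations(binary_image, template,
                                  rotation_step = config$rotation_step,
                                  threshold = config$match_threshold)
  min(nrow(det), config$max_hens)
}
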