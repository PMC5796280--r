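#' Label 8-connected particles in a binary image
#'
#' Partitions the foreground (1) pixels into 8-connected components
#' ("particles") and computes, per particle: area, centroid and central
#' second moments.  Diagonal neighbours belong to the same particle.
#'
#' Coordinates are 0-based with the origin at the top-left pixel, row-major;
#' centroids are means of pixel-centre coordinates.
#'
#' @param binary 0/1 integer matrix (e.g. from [binarize()]).
#' @return A `particle_set`: a data.frame with one row per particle
#'   (`label`, `area`, `centroid_row`, `centroid_col`, `mu_rr`, `mu_cc`,
#'   `mu_rc`) and an attribute `labels` holding the label matrix.
#' @export
label_particles <- function(binary) {
  binary <- as_pixel_matrix(binary)
  storage.mode(binary) <- "integer"
  labels <- cpp_label8(binary)
  k <- max(labels)
  if (k == 0L) {
    out <- data.frame(label = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      mu_rr = numeric(0), mu_cc = numeric(0), mu_rc = numeric(0))
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    r <- (idx - 1L) %% nrow(labels)   # 0-based row
    c <- (idx - 1L) %/% nrow(labels)  # 0-based col
    area <- tabulate(lab, nbins = k)
    cr <- rowsum(r, lab)[, 1] / area
    cc <- rowsum(c, lab)[, 1] / area
    dr <- r - cr[lab]
    dc <- c - cc[lab]
    out <- data.frame(label = seq_len(k), area = area,
                      centroid_row = cr, centroid_col = cc,
                      mu_rr = rowsum(dr * dr, lab)[, 1] / area,
                      mu_cc = rowsum(dc * dc, lab)[, 1] / area,
                      mu_rc = rowsum(dr * dc, lab)[, 1] / area)
  }
  attr(out, "labels") <- labels
  class(out) <- c("particle_set", "data.frame")
  out
}

#' Extract the pixel coordinates of one particle
#'
#' @param particles a `particle_set` from [label_particles()].
#' @param label particle label.
#' @return Two-column matrix of 0-based (row, col) pixel coordinates.
#' @export
particle_coords <- function(particles, label) {
  labels <- attr(particles, "labels")
  idx <- which(labels == label)
  if (length(idx) == 0L) stop_input("no particle with label ", label)
  cbind(row = (idx - 1L) %% nrow(labels),
        col = (idx - 1L) %/% nrow(labels))
}

#' Remove small particles from a binary image
#'
#' Area opening: every 8-connected component with fewer than `min_area`
#' pixels is erased; larger components pass through unchanged.  Applying the
#' filter twice is the same as applying it once.
#'
#' @param binary 0/1 integer matrix.
#' @param min_area minimum component area, in pixels, to keep.
#' @return Filtered 0/1 integer matrix.
#' @export
filter_small_particles <- function(binary, min_area = 50L) {
  if (min_area < 0) stop_input("min_area must be non-negative")
  binary <- as_pixel_matrix(binary)
  if (min_area <= 1L) return(binary)
  storage.mode(binary) <- "integer"
  labels <- cpp_label8(binary)
  k <- max(labels)
  if (k == 0L) return(binary)
  keep <- tabulate(labels[labels > 0L], nbins = k) >= min_area
  out <- matrix(as.integer(labels > 0L & keep[pmax(labels, 1L)]), nrow = nrow(binary))
  attributes(out) <- attributes(binary)
  out
}

#' Count colored pixels (CP)
#'
#' CP is the number of foreground pixels of the binarized, particle-filtered
#' frame; it is proportional to the visible warm-body area in the nest.
#'
#' @param binary 0/1 integer matrix.
#' @return Integer count.
#' @export
count_colored_pixels <- function(binary) {
  sum(as_pixel_matrix(binary) != 0L)
}
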