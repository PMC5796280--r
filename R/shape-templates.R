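# Shape descriptors and hen templates.
#
# A hen's thermal imprint is summarized by one of two shape descriptors,
# depending on the temperature shift used for binarization:
#   * shift 1 degC (whole body visible)  -> equivalent ellipse (second moments)
#   * shift 3/5 degC (head/comb visible) -> minimum-area rotated bounding
#     rectangle, whose long/short sides proportion an isosceles triangle.

# Coerce a particle argument to a 0-based (row, col) coordinate matrix.
# Coordinate matrices are recognized by their "row"/"col" column names (as
# produced by particle_coords()); anything else is treated as a binary mask.
coords_of <- function(particle) {
  if (!is.matrix(particle)) {
    stop_input("particle must be a coordinate matrix or a binary mask")
  }
  if (ncol(particle) == 2L && identical(colnames(particle), c("row", "col"))) {
    return(particle)
  }
  idx <- which(particle != 0)
  if (length(idx) == 0L) stop_input("empty particle mask")
  cbind(row = (idx - 1L) %% nrow(particle),
        col = (idx - 1L) %/% nrow(particle))
}

#' Equivalent ellipse of a particle
#'
#' The ellipse with the same normalized central second moments as the
#' particle's pixel set, the standard particle-analysis definition.  Pixels
#' are treated as unit squares (a 1/12 variance term is added per axis), so
#' a rasterized filled ellipse recovers its own axes.  The descriptor is
#' invariant under particle rotation and translation.
#'
#' @param particle a two-column 0-based (row, col) coordinate matrix or a
#'   binary mask.
#' @return List with class `ellipse_descriptor`: `major_axis`, `minor_axis`
#'   (full axis lengths, pixels; major >= minor) and `orientation` (radians,
#'   angle of the major axis from the column axis, in (-pi/2, pi/2\]).
#' @export
equivalent_ellipse <- function(particle) {
  xy <- coords_of(particle)
  if (nrow(xy) < 5L) stop_input("particle too small for an equivalent ellipse (area >= 5 required)")
  r <- xy[, 1]; c <- xy[, 2]
  mu_rr <- mean((r - mean(r))^2) + 1 / 12
  mu_cc <- mean((c - mean(c))^2) + 1 / 12
  mu_rc <- mean((r - mean(r)) * (c - mean(c)))
  m <- matrix(c(mu_rr, mu_rc, mu_rc, mu_cc), 2)
  e <- eigen(m, symmetric = TRUE)
  major <- 4 * sqrt(max(e$values[1], 0))
  minor <- 4 * sqrt(max(e$values[2], 0))
  if (minor < 1) minor <- 1  # degenerate (collinear) particle
  v <- e$vectors[, 1]  # (row, col) direction of the major axis
  orientation <- atan2(v[1], v[2])
  if (orientation <= -pi / 2) orientation <- orientation + pi
  if (orientation > pi / 2) orientation <- orientation - pi
  structure(list(major_axis = major, minor_axis = minor, orientation = orientation),
            class = "ellipse_descriptor")
}

#' Minimum-area rotated bounding rectangle of a particle
#'
#' Computed by rotating calipers over the convex hull of the pixel centres,
#' adding one pixel per side for the unit pixel extent (an axis-aligned
#' w x h block thus measures exactly w x h, and oblique particles are not
#' inflated by corner staircases).  The minimum-area enclosing rectangle
#' always has a side collinear with a hull edge, so only hull-edge
#' orientations are examined.
#'
#' @inheritParams equivalent_ellipse
#' @return List with class `rectangle_descriptor`: `long_side`, `short_side`
#'   (pixels, long >= short) and `angle` (radians of the long side from the
#'   column axis).
#' @export
min_area_bounding_rectangle <- function(particle) {
  xy <- coords_of(particle)
  if (nrow(xy) < 2L) stop_input("particle area >= 2 required for a bounding rectangle")
  r <- xy[, 1]
  c_ <- xy[, 2]
  hull <- grDevices::chull(c_, r)
  hx <- c_[hull]; hy <- r[hull]
  n <- length(hull)
  best <- NULL
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    ex <- hx[k2] - hx[k]; ey <- hy[k2] - hy[k]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    ux <- ex / len; uy <- ey / len        # edge direction
    p1 <- hx * ux + hy * uy               # projection on edge
    p2 <- -hx * uy + hy * ux              # projection on normal
    s1 <- max(p1) - min(p1) + 1           # + unit pixel extent
    s2 <- max(p2) - min(p2) + 1
    area <- s1 * s2
    if (is.null(best) || area < best$area - 1e-12) {
      ang <- if (s1 >= s2) atan2(uy, ux) else atan2(ux, -uy)
      best <- list(area = area, long = max(s1, s2), short = min(s1, s2), angle = ang)
    }
  }
  ang <- best$angle
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  structure(list(long_side = best$long, short_side = best$short, angle = ang),
            class = "rectangle_descriptor")
}

#' Derive a hen template from labelled single-occupation binary images
#'
#' For each image the largest particle is taken as the hen's imprint.  With
#' a 1 degC shift the imprint is the whole body and the template is the mean
#' equivalent ellipse (major x minor axes).  With a 3 or 5 degC shift only
#' the head region is visible and the template is an isosceles triangle with
#' height = mean long side and base = mean short side of the minimum-area
#' bounding rectangles.  Dimensions are rounded half-up to whole pixels.
#'
#' @param single_hen_binaries non-empty list of 0/1 matrices, one hen each.
#' @param shift the Celsius shift the binaries were thresholded at (1, 3 or 5).
#' @return A rendered template, see [render_template()].
#' @export
derive_template <- function(single_hen_binaries, shift) {
  if (length(single_hen_binaries) == 0L) stop_input("empty list of binary images")
  kind <- if (shift == 1) "ellipse" else "triangle"
  dims <- vapply(single_hen_binaries, function(b) {
    ps <- label_particles(b)
    if (nrow(ps) == 0L) stop_input("binary image contains no particle")
    xy <- particle_coords(ps, ps$label[which.max(ps$area)])
    if (kind == "ellipse") {
      d <- equivalent_ellipse(xy)
      c(d$major_axis, d$minor_axis)
    } else {
      d <- min_area_bounding_rectangle(xy)
      c(d$long_side, d$short_side)
    }
  }, numeric(2))
  render_template(kind,
                  height = round_half_up(mean(dims[1, ])),
                  base = round_half_up(mean(dims[2, ])))
}

#' Rasterize a hen template
#'
#' Renders a filled binary mask in a tight `height` x `base` bounding box.
#' The triangle is isosceles with the apex centred on the top row and the
#' base along the bottom row; the ellipse is axis-aligned with vertical
#' major axis `height` and horizontal minor axis `base`.  A pixel is set if
#' its centre lies inside the continuous shape; every triangle row keeps at
#' least one pixel so the apex survives rasterization.
#'
#' @param shape_kind `"ellipse"` or `"triangle"`.
#' @param height template height (ellipse major axis), pixels, >= 3.
#' @param base template base (ellipse minor axis), pixels, >= 3.
#' @return An object of class `hen_template`: list with `mask` (0/1 integer
#'   matrix), `shape_kind`, `height`, `base`.
#' @export
render_template <- function(shape_kind = c("triangle", "ellipse"), height, base) {
  shape_kind <- match.arg(shape_kind)
  height <- as.integer(height); base <- as.integer(base)
  if (is.na(height) || is.na(base) || height < 3L || base < 3L) {
    stop_input("template height and base must be >= 3 pixels")
  }
  rc <- matrix(rep(seq_len(height) - 0.5, base), nrow = height)          # row centres
  cc <- matrix(rep(seq_len(base) - 0.5, each = height), nrow = height)   # col centres
  if (shape_kind == "ellipse") {
    a <- height / 2; b <- base / 2
    mask <- ((rc - a) / a)^2 + ((cc - b) / b)^2 <= 1
  } else {
    halfwidth <- rc / height * (base / 2)
    mask <- abs(cc - base / 2) <= halfwidth
    empty <- rowSums(mask) == 0L
    if (any(empty)) mask[cbind(which(empty), rep(ceiling(base / 2), sum(empty)))] <- TRUE
  }
  mask <- matrix(as.integer(mask), nrow = height)
  structure(list(mask = mask, shape_kind = shape_kind,
                 height = height, base = base),
            class = "hen_template")
}

#' @export
print.hen_template <- function(x, ...) {
  cat(sprintf("<hen_template> %s %d x %d px (height x base), area %d px\n",
              x$shape_kind, x$height, x$base, sum(x$mask)))
  invisible(x)
}

# Coerce a template argument to its 0/1 mask matrix.
template_mask <- function(template) {
  if (inherits(template, "hen_template")) return(template$mask)
  if (is.matrix(template)) return(template)
  stop_input("template must be a hen_template or a matrix")
}

#' Rotate a binary mask
#'
#' Nearest-neighbour rotation about the mask centre, counter-clockwise in
#' standard image coordinates, followed by re-binarization and trimming to
#' the tight bounding box.  Used to generate the rotated template stack for
#' matching.
#'
#' @param mask 0/1 matrix.
#' @param angle_deg rotation angle in degrees.
#' @return Rotated, trimmed 0/1 integer matrix.
#' @export
rotate_mask <- function(mask, angle_deg) {
  mask <- template_mask(mask)
  a <- (angle_deg %% 360) * pi / 180
  if (a == 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  ca <- cos(a); sa <- sin(a)
  H <- ceiling(h * abs(ca) + w * abs(sa))
  W <- ceiling(h * abs(sa) + w * abs(ca))
  rc <- rep(seq_len(H) - 0.5 - H / 2, W)
  cc <- rep(seq_len(W) - 0.5 - W / 2, each = H)
  # inverse map: rotate output centres by -a back into source coordinates
  sr <- ca * rc + sa * cc + h / 2
  sc <- -sa * rc + ca * cc + w / 2
  ri <- ceiling(sr); ci <- ceiling(sc)
  ok <- ri >= 1L & ri <= h & ci >= 1L & ci <= w
  out <- matrix(0L, H, W)
  out[ok] <- mask[cbind(ri[ok], ci[ok])]
  keep_r <- which(rowSums(out) > 0L)
  keep_c <- which(colSums(out) > 0L)
  if (length(keep_r) == 0L) return(matrix(0L, 0, 0))
  out[keep_r[1]:keep_r[length(keep_r)], keep_c[1]:keep_c[length(keep_c)], drop = FALSE]
}
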