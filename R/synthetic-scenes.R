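# Seeded synthetic thermal nest scenes with ground truth.
#
# A scene emulates the statistical structure the sensor assumes: a
# near-constant floor at 13-21 degC with Gaussian intensity noise, and hens
# rendered as a feathered body ellipse (surface only a few degC above the
# floor) carrying a much warmer bare head/comb triangle placed inside the
# body outline near one end, the top view of a sitting hen.  With a 1 degC
# shift the whole body imprint is visible (ellipse); with a 5 degC shift
# only the head triangle exceeds the threshold, so a single hen yields a
# colored-pixel count in the single-occupation regime.

#' Specification of a synthetic nest scene
#'
#' Defaults reproduce the deployed field conditions: 320 x 240 frames, floor
#' temperature drawn uniformly from 13-21 degC, 0.3 degC Gaussian pixel
#' noise, body ellipse axes around 158 x 83 px, head triangle around
#' 43 x 33 px (height x base), head/comb temperature 37-40 degC and body
#' surface 3.5 degC above the floor.
#'
#' @param width,height frame size in pixels.
#' @param floor_temp floor temperature in degC, or `NULL` to draw uniformly
#'   from `floor_range` per scene.
#' @param floor_range range of floor temperatures, degC.
#' @param noise_sd per-pixel Gaussian temperature noise, degC.
#' @param n_hens number of hens to render.
#' @param body_temp_range head/comb temperature range, degC; must stay above
#'   the floor by more than 5 degC.
#' @param body_surface_offset feathered-body surface excess over the floor,
#'   degC (visible at 1 and 3 degC shifts, invisible at 5).
#' @param body_major_range,body_minor_range body ellipse axis ranges, px.
#' @param head_height_range,head_base_range head triangle dimension ranges, px.
#' @param hard_case_fraction share of scenes rendered as hard cases (hens
#'   overlapping, or a hen clipped at the frame border).
#' @param min_head_separation minimum head-centre distance enforced between
#'   hens in regular (non-hard) scenes, px.
#' @param calibration the frame's [temperature_calibration()].
#' @param seed optional integer seed making [generate_scene()] reproducible.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(width = 320L, height = 240L,
                       floor_temp = NULL, floor_range = c(13, 21),
                       noise_sd = 0.3, n_hens = 1L,
                       body_temp_range = c(37, 40),
                       body_surface_offset = 3.5,
                       body_major_range = c(151, 165),
                       body_minor_range = c(77, 89),
                       head_height_range = c(42, 44),
                       head_base_range = c(32, 34),
                       hard_case_fraction = 0.1,
                       min_head_separation = 60,
                       calibration = temperature_calibration(),
                       seed = NULL) {
  if (!is.null(floor_temp) && min(body_temp_range) <= floor_temp + 5) {
    stop_config("head/comb temperature must exceed the floor by more than 5 degC")
  }
  if (min(body_temp_range) <= max(if (is.null(floor_temp)) floor_range else floor_temp) + 5) {
    stop_config("head/comb temperature must exceed the floor by more than 5 degC")
  }
  if (noise_sd < 0) stop_config("noise_sd must be non-negative")
  structure(list(width = as.integer(width), height = as.integer(height),
                 floor_temp = floor_temp, floor_range = floor_range,
                 noise_sd = noise_sd, n_hens = as.integer(n_hens),
                 body_temp_range = body_temp_range,
                 body_surface_offset = body_surface_offset,
                 body_major_range = body_major_range,
                 body_minor_range = body_minor_range,
                 head_height_range = head_height_range,
                 head_base_range = head_base_range,
                 hard_case_fraction = hard_case_fraction,
                 min_head_separation = min_head_separation,
                 calibration = calibration, seed = seed),
            class = "scene_spec")
}

# Rigid-body hen geometry: local x runs along the body major axis, the head
# triangle sits inside the ellipse with its apex 7 px short of the body end.
hen_masks <- function(spec, hen, rows, cols) {
  th <- hen$orientation
  dx <- (cols - hen$center_col) * cos(th) + (rows - hen$center_row) * sin(th)
  dy <- -(cols - hen$center_col) * sin(th) + (rows - hen$center_row) * cos(th)
  a <- hen$body_major / 2; b <- hen$body_minor / 2
  body <- (dx / a)^2 + (dy / b)^2 <= 1
  xa <- a - 7                      # head apex position along the major axis
  hh <- hen$head_height; hb <- hen$head_base
  depth <- xa - dx                 # distance back from the apex
  head <- depth >= 0 & depth <= hh & abs(dy) <= depth / hh * (hb / 2)
  list(body = body, head = head)
}

draw_hen <- function(spec, hard = FALSE, towards = NULL) {
  a <- runif(1, spec$body_major_range[1], spec$body_major_range[2])
  margin <- a / 2 + 1
  if (hard && is.null(towards)) {
    # clipped at the border: centre close to a frame edge
    center_row <- sample(c(runif(1, 10, margin), runif(1, spec$height - margin, spec$height - 10)), 1)
    center_col <- runif(1, 10, spec$width - 10)
  } else {
    center_row <- runif(1, margin, spec$height - margin)
    center_col <- runif(1, margin, spec$width - margin)
  }
  list(center_row = center_row, center_col = center_col,
       orientation = runif(1, 0, 2 * pi),
       body_temp = runif(1, spec$body_temp_range[1], spec$body_temp_range[2]),
       body_major = a,
       body_minor = runif(1, spec$body_minor_range[1], spec$body_minor_range[2]),
       head_height = runif(1, spec$head_height_range[1], spec$head_height_range[2]),
       head_base = runif(1, spec$head_base_range[1], spec$head_base_range[2]))
}

head_center <- function(hen) {
  a <- hen$body_major / 2
  xc <- a - 7 - hen$head_height * 2 / 3   # triangle centroid-ish along major
  c(row = unname(hen$center_row + xc * sin(hen$orientation)),
    col = unname(hen$center_col + xc * cos(hen$orientation)))
}

#' Generate one synthetic thermal scene
#'
#' Renders the scene described by a [scene_spec()]: floor plus Gaussian
#' noise, one body ellipse and head triangle per hen (with per-pixel jitter),
#' converted to 8-bit intensities through the calibration.  Regular
#' multi-hen scenes are laid out by rejection sampling so head centres stay
#' at least `min_head_separation` px apart; hard-case scenes deliberately
#' violate that (close pair) or clip a hen at the border.  Identical seeds
#' give bit-identical frames.
#'
#' @param spec a [scene_spec()].
#' @param hard render a hard case (`NA` = draw with probability
#'   `spec$hard_case_fraction`).
#' @return List: `frame` (a [thermal_frame()]) and `truth` (list with
#'   `n_hens`, `floor_temp`, `hard`, `overlap`, and per-hen data.frame
#'   `hens`).
#' @export
generate_scene <- function(spec = scene_spec(), hard = NA) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.na(hard)) hard <- runif(1) < spec$hard_case_fraction
  floor_temp <- if (is.null(spec$floor_temp)) {
    runif(1, spec$floor_range[1], spec$floor_range[2])
  } else {
    spec$floor_temp
  }
  n <- spec$n_hens
  hens <- list()
  for (k in seq_len(n)) {
    if (hard && n >= 2L && k == 2L) {
      # close pair: drop the second hen's head near the first hen's head
      hc <- head_center(hens[[1]])
      for (try in 1:200) {
        cand <- draw_hen(spec)
        ang <- runif(1, 0, 2 * pi)
        sep <- runif(1, 20, 40)
        tgt <- c(hc["row"] + sep * sin(ang), hc["col"] + sep * cos(ang))
        off <- head_center(cand) - c(cand$center_row, cand$center_col)
        cand$center_row <- unname(tgt[1] - off["row"])
        cand$center_col <- unname(tgt[2] - off["col"])
        m <- cand$body_major / 2 + 1
        if (cand$center_row > m && cand$center_row < spec$height - m &&
            cand$center_col > m && cand$center_col < spec$width - m) break
      }
      hens[[k]] <- cand
    } else if (hard && n == 1L && k == 1L) {
      hens[[k]] <- draw_hen(spec, hard = TRUE)
    } else {
      for (try in 1:200) {
        cand <- draw_hen(spec)
        if (k == 1L) break
        seps <- vapply(hens[seq_len(k - 1L)], function(h) {
          sqrt(sum((head_center(h) - head_center(cand))^2))
        }, numeric(1))
        if (all(seps >= spec$min_head_separation)) break
      }
      hens[[k]] <- cand
    }
  }

  rows <- matrix(rep(seq_len(spec$height) - 0.5, spec$width), nrow = spec$height)
  cols <- matrix(rep(seq_len(spec$width) - 0.5, each = spec$height), nrow = spec$height)
  temp <- matrix(floor_temp, spec$height, spec$width) +
    rnorm(spec$height * spec$width, 0, spec$noise_sd)
  # bodies first, then heads: a head always sits above the bodies, so an
  # overlapping neighbour's (cooler) body never occludes it
  body_cover <- matrix(0L, spec$height, spec$width)
  masks <- lapply(hens, hen_masks, spec = spec, rows = rows, cols = cols)
  for (mk in masks) {
    nb <- sum(mk$body)
    if (nb > 0) temp[mk$body] <- floor_temp + spec$body_surface_offset +
        rnorm(nb, 0, spec$noise_sd)
    body_cover <- body_cover + mk$body
  }
  for (k in seq_along(masks)) {
    nh <- sum(masks[[k]]$head)
    if (nh > 0) temp[masks[[k]]$head] <- hens[[k]]$body_temp +
        rnorm(nh, 0, spec$noise_sd)
  }
  overlap <- any(body_cover > 1L)
  px <- matrix(temperature_to_intensity(temp, spec$calibration),
               nrow = spec$height)
  hen_df <- do.call(rbind, lapply(hens, function(h) {
    hc <- head_center(h)
    data.frame(center_row = h$center_row, center_col = h$center_col,
               orientation = h$orientation, body_temp = h$body_temp,
               body_major = h$body_major, body_minor = h$body_minor,
               head_height = h$head_height, head_base = h$head_base,
               head_row = unname(hc["row"]), head_col = unname(hc["col"]))
  }))
  if (!is.null(hen_df)) rownames(hen_df) <- NULL
  list(frame = thermal_frame(px, spec$calibration),
       truth = list(n_hens = n, floor_temp = floor_temp, hard = hard,
                    overlap = overlap, hens = hen_df))
}

#' Generate a labelled set of single/multiple occupation scenes
#'
#' Desk-scale stand-in for a labelled calibration corpus: `n_single` scenes
#' with one hen and `n_multiple` scenes with two or three hens (3 with
#' probability `p_triple`), randomized positions, orientations, sizes and
#' temperatures within the spec ranges.  The fraction
#' `spec$hard_case_fraction` of scenes are hard cases.
#'
#' @param n_single,n_multiple number of scenes per label (>= 1).
#' @param spec a [scene_spec()]; its `n_hens` and `seed` fields are ignored.
#' @param p_triple probability that a multiple scene holds three hens.
#' @param seed integer seed for the whole set.
#' @return A `labelled_frame_set`: list with `frames` (list of
#'   [thermal_frame()]), `labels` (factor single/multiple), `counts` (true
#'   hen counts) and `truth` (list of per-scene truth).
#' @export
generate_labelled_set <- function(n_single, n_multiple, spec = scene_spec(),
                                  p_triple = 0.3, seed = 1L) {
  if (n_single < 1L || n_multiple < 1L) stop_input("need at least one scene per label")
  set.seed(seed)
  spec$seed <- NULL
  n <- n_single + n_multiple
  counts <- c(rep(1L, n_single),
              1L + 1L + (runif(n_multiple) < p_triple))
  frames <- vector("list", n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    spec$n_hens <- counts[k]
    sc <- generate_scene(spec)
    frames[[k]] <- sc$frame
    truth[[k]] <- sc$truth
  }
  structure(list(frames = frames,
                 labels = factor(ifelse(counts >= 2L, "multiple", "single"),
                                 levels = c("single", "multiple")),
                 counts = as.integer(counts), truth = truth),
            class = "labelled_frame_set")
}
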