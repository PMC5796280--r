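# Setup procedure for the nest-usage sensor: CP distributions on labelled
# single/multiple frame sets (step A), sensitivity-constrained MNOT cutoff
# selection, and evaluation of the full pattern-recognition sensor (step B).

#' Colored-pixel distributions of a labelled frame set
#'
#' Runs the imaging pipeline (background estimate, BCT at the given shift,
#' binarization, small-particle filter, CP count) on every frame of a
#' labelled set and compares the single- against the multiple-occupation CP
#' means with a two-group one-way ANOVA.  The F statistic is computed from
#' the between/within sums of squares (for two groups it equals the squared
#' two-sample equal-variance t statistic).
#'
#' @param set a `labelled_frame_set` (see [generate_labelled_set()]): list
#'   with `frames` and a `labels` factor with levels `single`/`multiple`.
#' @param shift Celsius shift used to build the BCT.
#' @param min_particle_area area-opening threshold, pixels.
#' @return List with `cp` (data.frame: `label`, `cp`), `means` (named
#'   numeric), and `anova` (list: `f`, `p`, `df1`, `df2`).
#' @export
compute_cp_distributions <- function(set, shift, min_particle_area = 50L) {
  stopifnot(is.list(set), !is.null(set$frames), !is.null(set$labels))
  if (length(set$frames) == 0L) stop_input("empty frame set")
  labels <- factor(set$labels, levels = c("single", "multiple"))
  if (any(table(labels) == 0L)) stop_input("both labels must be present")
  cp <- vapply(set$frames, function(f) {
    bct <- compute_bct(estimate_background_temperature(f), shift, f$calibration)
    count_colored_pixels(filter_small_particles(binarize(f, bct), min_particle_area))
  }, numeric(1))
  means <- tapply(cp, labels, mean)
  an <- anova_two_group(cp, labels)
  list(cp = data.frame(label = labels, cp = cp), means = means, anova = an)
}

# Two-group one-way ANOVA from sums of squares.
anova_two_group <- function(x, g) {
  g <- droplevels(factor(g))
  if (nlevels(g) != 2L) stop_input("exactly two groups required")
  n <- length(x)
  grand <- mean(x)
  ni <- tabulate(g)
  mi <- tapply(x, g, mean)
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum((x - mi[g])^2)
  df1 <- 1L
  df2 <- n - 2L
  f <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else {
    (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  list(f = f, p = p, df1 = df1, df2 = df2)
}

#' Scan candidate MNOT cutoffs
#'
#' For every candidate cutoff, computes the sensitivity (fraction of
#' multiple-occupation frames with CP strictly above the cutoff) and
#' specificity (fraction of single-occupation frames at or below it).
#' Sensitivity is non-increasing and specificity non-decreasing in the
#' cutoff.
#'
#' @param single_cp,multiple_cp CP samples of the two labelled classes.
#' @param cutoffs integer candidate cutoffs; defaults to
#'   `0:max(multiple_cp)`.
#' @return data.frame: `cutoff`, `sensitivity`, `specificity` (percent).
#' @export
cutoff_scan <- function(single_cp, multiple_cp, cutoffs = NULL) {
  if (length(single_cp) == 0L || length(multiple_cp) == 0L) {
    stop_input("both CP samples must be non-empty")
  }
  if (is.null(cutoffs)) cutoffs <- 0:max(multiple_cp)
  s_mult <- sort(multiple_cp)
  s_sing <- sort(single_cp)
  # counts strictly above each cutoff via binary search on the sorted samples
  n_above <- length(s_mult) - findInterval(cutoffs, s_mult)
  n_at_or_below <- findInterval(cutoffs, s_sing)
  data.frame(cutoff = cutoffs,
             sensitivity = 100 * n_above / length(s_mult),
             specificity = 100 * n_at_or_below / length(s_sing))
}

#' Select the MNOT at a target sensitivity
#'
#' Returns the largest integer cutoff whose sensitivity (share of multiple-
#' occupation frames with CP strictly above it) still reaches the target -
#' i.e. the cutoff maximizing specificity subject to the sensitivity floor.
#' If even cutoff 0 misses the target the function warns and returns 0.
#'
#' @param single_cp,multiple_cp CP samples of the two labelled classes.
#' @param target_sensitivity sensitivity floor in percent (default 80, a
#'   reasonable level of the human ability to spot a hen in a thermographic
#'   image).
#' @return Integer cutoff (the MNOT), with attributes
#'   `achieved_sensitivity` and `achieved_specificity` (percent).
#' @export
select_mnot <- function(single_cp, multiple_cp, target_sensitivity = 80) {
  if (length(single_cp) == 0L || length(multiple_cp) == 0L) {
    stop_input("both CP samples must be non-empty")
  }
  n <- length(multiple_cp)
  k <- ceiling(target_sensitivity / 100 * n)  # need >= k multiples above cutoff
  if (k < 1L) {
    cutoff <- as.integer(max(multiple_cp))  # any cutoff satisfies a 0% floor
  } else if (k > n || 100 * sum(multiple_cp > 0) / n < target_sensitivity) {
    warning("no cutoff reaches the target sensitivity; returning 0")
    cutoff <- 0L
  } else {
    # the k-th largest multiple CP is the smallest value that must stay above
    kth <- sort(multiple_cp, decreasing = TRUE)[k]
    cutoff <- as.integer(kth) - 1L
    if (cutoff < 0L) cutoff <- 0L
  }
  structure(cutoff,
            achieved_sensitivity = 100 * sum(multiple_cp > cutoff) / n,
            achieved_specificity = 100 * sum(single_cp <= cutoff) / length(single_cp))
}

#' Evaluate the full sensor on a labelled frame set (step B)
#'
#' Runs [process_frame()] on every frame and scores the MNO flag against the
#' labels, positive = multiple occupation: TP = multiple correctly flagged,
#' FP = single flagged multiple, TN = single correctly passed, FN = multiple
#' missed.  The per-frame hen counts (pattern recognition) are returned so
#' the counting accuracy on multiple-occupation frames can be assessed.
#'
#' @param set a `labelled_frame_set` with `frames`, `labels` and true
#'   `counts`.
#' @param config a [sensor_config()].
#' @return List with `confusion` (a [confusion_counts()]) and `results`
#'   (data.frame: `label`, `true_count`, `cp`, `mno`, `hen_count`).
#' @export
evaluate_step_b <- function(set, config = sensor_config()) {
  stopifnot(is.list(set), !is.null(set$frames), !is.null(set$labels))
  labels <- factor(set$labels, levels = c("single", "multiple"))
  counts <- if (is.null(set$counts)) rep(NA_integer_, length(labels)) else set$counts
  res <- lapply(set$frames, process_frame, config = config)
  df <- data.frame(label = labels,
                   true_count = counts,
                   cp = vapply(res, function(r) r$cp, numeric(1)),
                   mno = vapply(res, function(r) r$mno, integer(1)),
                   hen_count = vapply(res, function(r) r$hen_count, integer(1)))
  confusion <- confusion_from_pairs(df$mno, as.integer(labels == "multiple"))
  list(confusion = confusion, results = df)
}
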