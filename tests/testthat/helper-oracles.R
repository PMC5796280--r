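# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Exhaustive double-summation cross-correlation (valid mode).
oracle_cross_correlate <- function(p, t) {
  U <- nrow(t); V <- ncol(t)
  out <- matrix(0, nrow(p) - U + 1, ncol(p) - V + 1)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      s <- 0
      for (x in seq_len(U)) {
        for (y in seq_len(V)) {
          s <- s + t[x, y] * p[i + x - 1, j + y - 1]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# Exhaustive normalized cross-correlation straight from the defining formula.
oracle_ncc <- function(p, t) {
  U <- nrow(t); V <- ncol(t)
  tbar <- mean(t)
  tden <- sqrt(sum((t - tbar)^2))
  out <- matrix(0, nrow(p) - U + 1, ncol(p) - V + 1)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      w <- p[i:(i + U - 1), j:(j + V - 1)]
      wden <- sqrt(sum((w - mean(w))^2))
      out[i, j] <- if (wden == 0) 0 else
        sum((t - tbar) * (w - mean(w))) / (tden * wden)
    }
  }
  out
}

# Minimum-area rectangle by dense scan over orientations (same side
# convention as the implementation: centre extent + 1 px).
oracle_min_rect <- function(xy, n_angles = 3601) {
  best <- Inf; long <- NA; short <- NA
  for (th in seq(0, pi / 2, length.out = n_angles)) {
    p1 <- xy[, 2] * cos(th) + xy[, 1] * sin(th)
    p2 <- -xy[, 2] * sin(th) + xy[, 1] * cos(th)
    s1 <- diff(range(p1)) + 1
    s2 <- diff(range(p2)) + 1
    if (s1 * s2 < best) {
      best <- s1 * s2
      long <- max(s1, s2); short <- min(s1, s2)
    }
  }
  list(long = long, short = short, area = best)
}

# Exhaustive MNOT selection: scan every integer cutoff, keep the largest
# whose sensitivity meets the target.
oracle_select_mnot <- function(single_cp, multiple_cp, target = 80) {
  best <- NA_integer_
  for (cut in 0:max(multiple_cp)) {
    sens <- 100 * sum(multiple_cp > cut) / length(multiple_cp)
    if (sens >= target) best <- cut
  }
  if (is.na(best)) 0L else best
}

# Recursive-free 8-connected labeling oracle on small images.
oracle_label8_areas <- function(bin) {
  visited <- matrix(FALSE, nrow(bin), ncol(bin))
  areas <- integer(0)
  for (start in which(bin != 0)) {
    r0 <- (start - 1) %% nrow(bin) + 1
    c0 <- (start - 1) %/% nrow(bin) + 1
    if (visited[r0, c0]) next
    queue <- list(c(r0, c0)); visited[r0, c0] <- TRUE; area <- 0L
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]; area <- area + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cur[1] + dr; cc <- cur[2] + dc
        if (rr >= 1 && rr <= nrow(bin) && cc >= 1 && cc <= ncol(bin) &&
            bin[rr, cc] != 0 && !visited[rr, cc]) {
          visited[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    areas <- c(areas, area)
  }
  sort(areas)
}

# Frame with a constant background intensity and optional rectangular blobs.
make_frame <- function(background = 90L, blobs = list(), nrow = 60L, ncol = 80L,
                       calib = temperature_calibration()) {
  px <- matrix(as.integer(background), nrow, ncol)
  for (b in blobs) {
    px[b$rows, b$cols] <- as.integer(b$intensity)
  }
  thermal_frame(px, calib)
}
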