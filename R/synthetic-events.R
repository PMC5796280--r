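# Seeded synthetic nest event streams with ground-truth records.

#' Specification of a synthetic event stream
#'
#' Emulates a field day at the nest: hens visit one at a time (1 Hz RFID
#' reads while seated), some visits end in an oviposition, and a share of
#' visits are joined by a second hen, raising the sensor's multiple-
#' occupation flag mid-visit.
#'
#' @param n_hens number of distinct hens in the flock.
#' @param n_visits number of visits to script.
#' @param mean_duration mean visit duration, seconds (exponential with a
#'   10 s floor).
#' @param egg_prob probability that a visit includes an oviposition.
#' @param mno_prob probability that a visit is flagged as multiple
#'   occupation.
#' @param gap_range inter-visit gap range, seconds.
#' @param seed integer seed.
#' @return List of class `stream_spec`.
#' @export
stream_spec <- function(n_hens = 10L, n_visits = 50L, mean_duration = 120,
                        egg_prob = 0.4, mno_prob = 0.2,
                        gap_range = c(30, 300), seed = 1L) {
  for (p in c(egg_prob, mno_prob)) {
    if (p < 0 || p > 1) stop_config("probabilities must be in [0, 1]")
  }
  if (n_hens < 1L || n_visits < 0L) stop_config("n_hens >= 1 and n_visits >= 0 required")
  structure(list(n_hens = as.integer(n_hens), n_visits = as.integer(n_visits),
                 mean_duration = mean_duration, egg_prob = egg_prob,
                 mno_prob = mno_prob, gap_range = gap_range,
                 seed = as.integer(seed)),
            class = "stream_spec")
}

#' Generate a synthetic nest event stream with ground truth
#'
#' Scripts `n_visits` visits: each contributes 1 Hz `rfid_read` events for
#' its duration, possibly an `mno_flag` (at a random moment of the visit),
#' possibly an `egg_detected`, and a closing `nest_empty`.  Consecutive
#' visits are guaranteed to alternate hen ids so the number of records
#' equals the number of visits.  The ground truth contains the records
#' [process_event_stream()] must reconstruct and the outcome
#' ([assign_eggs()]) of every egg.
#'
#' @param spec a [stream_spec()].
#' @return List: `events` (a [nest_events()] data.frame), `truth` (list with
#'   `records` and `egg_outcomes` data.frames).
#' @export
generate_event_stream <- function(spec = stream_spec()) {
  set.seed(spec$seed)
  t <- 0
  ev_time <- numeric(0); ev_kind <- character(0); ev_payload <- character(0)
  rec <- vector("list", spec$n_visits)
  eggs <- list()
  prev_hen <- ""
  for (v in seq_len(spec$n_visits)) {
    repeat {
      hen <- sprintf("hen%02d", sample.int(spec$n_hens, 1))
      if (hen != prev_hen || spec$n_hens == 1L) break
    }
    prev_hen <- hen
    dur <- 10 + round(stats::rexp(1, 1 / spec$mean_duration))
    reads <- t + 0:dur
    has_mno <- runif(1) < spec$mno_prob
    has_egg <- runif(1) < spec$egg_prob
    times <- reads; kinds <- rep("rfid_read", length(reads))
    payloads <- rep(hen, length(reads))
    if (has_mno) {
      mno_t <- t + runif(1, 1, dur - 1)
      times <- c(times, mno_t); kinds <- c(kinds, "mno_flag")
      payloads <- c(payloads, NA_character_)
    }
    egg_t <- NA_real_
    if (has_egg) {
      egg_t <- t + runif(1, 2, dur - 2)
      times <- c(times, egg_t); kinds <- c(kinds, "egg_detected")
      payloads <- c(payloads, NA_character_)
    }
    o <- order(times)
    ev_time <- c(ev_time, times[o], t + dur + 1)
    ev_kind <- c(ev_kind, kinds[o], "nest_empty")
    ev_payload <- c(ev_payload, payloads[o], NA_character_)
    rec[[v]] <- data.frame(hen_id = hen, visit_start = t,
                           nest_visit_duration = dur,
                           multiple_nest_occupation = as.integer(has_mno),
                           egg_deposited = as.integer(has_egg),
                           deposition_time = egg_t, stringsAsFactors = FALSE)
    if (has_egg) {
      eggs[[length(eggs) + 1L]] <- data.frame(
        time = egg_t,
        outcome = if (has_mno) "uncertain_mno" else "assigned",
        hen_id = if (has_mno) NA_character_ else hen,
        stringsAsFactors = FALSE)
    }
    t <- t + dur + 1 + round(runif(1, spec$gap_range[1], spec$gap_range[2]))
  }
  records <- if (spec$n_visits == 0L) empty_records() else do.call(rbind, rec)
  rownames(records) <- NULL
  egg_truth <- if (length(eggs) == 0L) {
    data.frame(egg = integer(0), time = numeric(0), outcome = character(0),
               hen_id = character(0), stringsAsFactors = FALSE)
  } else {
    cbind(egg = seq_along(eggs), do.call(rbind, eggs))
  }
  list(events = nest_events(ev_time, ev_kind, ev_payload),
       truth = list(records = records, egg_outcomes = egg_truth))
}
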