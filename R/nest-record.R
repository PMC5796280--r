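# Laying-hen records from nest event streams.
#
# The experimental nesting system emits a time-ordered stream of decoded
# events: RFID transponder reads (one per second while a hen sits on the
# nest antenna), egg detections from the photocell pair, multiple-occupation
# flags from the thermographic sensor, and nest-empty notifications.  A
# "laying hen record" summarizes one maximal run of reads of the same hen.

#' Build an event data.frame
#'
#' @param time event times in seconds, non-decreasing.
#' @param kind one of `rfid_read`, `egg_detected`, `mno_flag`, `nest_empty`.
#' @param payload hen id for `rfid_read`; optional annotation for
#'   `egg_detected` (`blocked_in_nest`, `broken_in_tube`, `undetected`);
#'   `NA` otherwise.
#' @return data.frame of class `nest_events`.
#' @export
nest_events <- function(time, kind, payload = NA_character_) {
  kinds <- c("rfid_read", "egg_detected", "mno_flag", "nest_empty")
  if (!all(kind %in% kinds)) {
    stop_input("unknown event kind: ", paste(setdiff(kind, kinds), collapse = ", "))
  }
  if (is.unsorted(time)) stop_input("event times must be non-decreasing")
  ev <- data.frame(time = as.numeric(time), kind = as.character(kind),
                   payload = rep_len(as.character(payload), length(time)),
                   stringsAsFactors = FALSE)
  if (any(ev$kind == "rfid_read" & (is.na(ev$payload) | ev$payload == ""))) {
    stop_input("rfid_read events need a hen id payload")
  }
  class(ev) <- c("nest_events", "data.frame")
  ev
}

empty_records <- function() {
  data.frame(hen_id = character(0), visit_start = numeric(0),
             nest_visit_duration = numeric(0),
             multiple_nest_occupation = integer(0),
             egg_deposited = integer(0), deposition_time = numeric(0),
             stringsAsFactors = FALSE)
}

#' Reconstruct laying-hen records from an event stream
#'
#' One record per maximal run of consecutive reads of the same hen id.
#' Repeated reads extend the visit duration (last read minus first read, so
#' a single read yields duration 0).  An `mno_flag` event sets the record's
#' multiple-occupation field, which stays set for the rest of the visit.
#' An `egg_detected` event sets the egg fields; the deposition time of the
#' first egg is kept.  A read of a different hen stores the open record and
#' starts a new one; `nest_empty` stores the open record; the final open
#' record is flushed at stream end.  Eggs arriving with no open record are
#' collected as orphans (attribute `orphan_eggs`), not errors.
#'
#' @param events a [nest_events()] data.frame (time-ordered).
#' @return data.frame with one row per record: `hen_id`, `visit_start`,
#'   `nest_visit_duration`, `multiple_nest_occupation`, `egg_deposited`,
#'   `deposition_time` (`NA` when no egg); attribute `orphan_eggs` holds the
#'   times of unowned egg events.
#' @export
process_event_stream <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(empty_records())
  if (is.unsorted(events$time)) stop_input("event stream must be time-ordered")
  records <- vector("list", nrow(events))
  nrec <- 0L
  open <- NULL
  orphans <- numeric(0)
  flush <- function(open) {
    if (is.null(open)) return(invisible(NULL))
    nrec <<- nrec + 1L
    records[[nrec]] <<- data.frame(
      hen_id = open$hen_id, visit_start = open$start,
      nest_visit_duration = open$last - open$start,
      multiple_nest_occupation = open$mno,
      egg_deposited = open$egg, deposition_time = open$egg_time,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(events))) {
    t <- events$time[k]
    switch(events$kind[k],
      rfid_read = {
        id <- events$payload[k]
        if (is.null(open) || open$hen_id != id) {
          flush(open)
          open <- list(hen_id = id, start = t, last = t, mno = 0L,
                       egg = 0L, egg_time = NA_real_)
        } else {
          open$last <- t
        }
      },
      mno_flag = {
        if (!is.null(open)) open$mno <- 1L
      },
      egg_detected = {
        if (is.null(open)) {
          orphans <- c(orphans, t)
        } else if (open$egg == 0L) {
          open$egg <- 1L
          open$egg_time <- t
        }
      },
      nest_empty = {
        flush(open)
        open <- NULL
      })
  }
  flush(open)
  out <- if (nrec == 0L) empty_records() else do.call(rbind, records[seq_len(nrec)])
  rownames(out) <- NULL
  attr(out, "orphan_eggs") <- orphans
  out
}

#' Assign eggs to hens
#'
#' An egg detected during a single-occupation visit is assigned to the
#' visiting hen; during a multiple occupation the layer is uncertain and the
#' egg cannot be attributed.  Egg events carrying a failure annotation
#' (`blocked_in_nest`, `broken_in_tube`, `undetected`, `laid_outside`) pass
#' it through; eggs falling outside any visit are `undetected`.
#'
#' @param records laying-hen records from [process_event_stream()].
#' @param egg_events data.frame with `time` and optional `annotation`.
#' @return data.frame of class `egg_outcomes`: `egg` (index), `time`,
#'   `outcome`, `hen_id` (`NA` unless assigned).
#' @export
assign_eggs <- function(records, egg_events) {
  n <- nrow(egg_events)
  outcome <- character(n)
  hen <- rep(NA_character_, n)
  ann <- if ("annotation" %in% names(egg_events)) egg_events$annotation else rep(NA_character_, n)
  for (k in seq_len(n)) {
    if (!is.na(ann[k]) && nzchar(ann[k])) {
      outcome[k] <- ann[k]
      next
    }
    t <- egg_events$time[k]
    hit <- which(records$visit_start <= t &
                 t <= records$visit_start + records$nest_visit_duration)
    if (length(hit) == 0L) {
      outcome[k] <- "undetected"
    } else {
      hit <- hit[1]
      if (records$multiple_nest_occupation[hit] == 1L) {
        outcome[k] <- "uncertain_mno"
      } else {
        outcome[k] <- "assigned"
        hen[k] <- records$hen_id[hit]
      }
    }
  }
  out <- data.frame(egg = seq_len(n), time = as.numeric(egg_events$time),
                    outcome = outcome, hen_id = hen, stringsAsFactors = FALSE)
  class(out) <- c("egg_outcomes", "data.frame")
  out
}

#' Egg-accounting summary percentages
#'
#' Bookkeeping of the egg-to-hen assignment: the share of eggs laid inside
#' the nest, and of those, the shares that could and could not be attributed
#' to a hen.  All percentages are exact ratios rounded half-up to one
#' decimal.
#'
#' @param outcomes an `egg_outcomes` data.frame for the in-nest eggs.
#' @param total_laid total number of eggs laid.
#' @param laid_outside eggs laid outside the nest.
#' @return List: `inside`, `assigned`, `percent_in_nest`, `percent_assigned`,
#'   `percent_unassigned` (the latter two relative to the in-nest eggs).
#' @examples
#' # 184 eggs laid, 6 outside: 96.7% in nest; 122 of 178 assigned: 68.5%
#' @export
assignment_stats <- function(outcomes, total_laid, laid_outside = 0L) {
  inside <- total_laid - laid_outside
  if (inside != nrow(outcomes)) {
    stop_input("inconsistent totals: total_laid - laid_outside = ", inside,
               " but ", nrow(outcomes), " in-nest outcomes supplied")
  }
  assigned <- sum(outcomes$outcome == "assigned")
  list(inside = inside, assigned = assigned,
       percent_in_nest = round_half_up(100 * inside / total_laid, 1),
       percent_assigned = round_half_up(100 * assigned / inside, 1),
       percent_unassigned = round_half_up(100 * (inside - assigned) / inside, 1))
}

#' Read and write event streams and record logs
#'
#' Tab-separated text round trips for the two stream formats: events as
#' `time <TAB> kind <TAB> payload` and laying-hen records as one line per
#' stored record (`hen_id`, `visit_start`, `nest_visit_duration`,
#' `multiple_nest_occupation`, `egg_deposited`, `deposition_time`).
#'
#' @param events,records data.frames as produced by [nest_events()] /
#'   [process_event_stream()].
#' @param path file path.
#' @return The read functions return the reconstructed data.frame; the write
#'   functions return `path` invisibly.
#' @name nest_io
NULL

#' @rdname nest_io
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname nest_io
#' @export
read_events <- function(path) {
  ev <- read.delim(path, colClasses = c("numeric", "character", "character"))
  nest_events(ev$time, ev$kind, ev$payload)
}

#' @rdname nest_io
#' @export
write_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname nest_io
#' @export
read_records <- function(path) {
  rec <- read.delim(path, colClasses = c("character", "numeric", "numeric",
                                         "integer", "integer", "numeric"))
  rownames(rec) <- NULL
  rec
}
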