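# Laying-hen record state machine, egg assignment, accounting stats, log IO.

test_that("records are one per maximal same-hen run of reads", {
  expect_identical(nrow(process_event_stream(nest_events(numeric(0), character(0)))), 0L)

  # hen A reads 0..10 s at 1 Hz, egg at 6, then hen B at 20
  ev <- nest_events(c(0:6, 6.5, 7:10, 20),
                    c(rep("rfid_read", 7), "egg_detected", rep("rfid_read", 4), "rfid_read"),
                    c(rep("A", 7), NA, rep("A", 4), "B"))
  rec <- process_event_stream(ev)
  expect_identical(nrow(rec), 2L)
  expect_identical(rec$hen_id, c("A", "B"))
  expect_identical(rec$nest_visit_duration, c(10, 0))
  expect_identical(rec$egg_deposited, c(1L, 0L))
  expect_identical(rec$deposition_time, c(6.5, NA_real_))
  expect_identical(rec$multiple_nest_occupation, c(0L, 0L))

  # MNO flag is sticky on the open record
  ev2 <- nest_events(c(0, 1, 2, 2.5, 3, 4),
                     c("rfid_read", "rfid_read", "mno_flag", "egg_detected",
                       "rfid_read", "rfid_read"),
                     c("A", "A", NA, NA, "A", "A"))
  rec2 <- process_event_stream(ev2)
  expect_identical(nrow(rec2), 1L)
  expect_identical(rec2$multiple_nest_occupation, 1L)
  expect_identical(rec2$egg_deposited, 1L)

  # nest_empty closes the open record; orphan eggs are collected, not errors
  ev3 <- nest_events(c(0, 1, 2, 5, 9),
                     c("rfid_read", "rfid_read", "nest_empty", "egg_detected", "rfid_read"),
                     c("A", "A", NA, NA, "A"))
  rec3 <- process_event_stream(ev3)
  expect_identical(nrow(rec3), 2L)
  expect_identical(rec3$egg_deposited, c(0L, 0L))
  expect_identical(attr(rec3, "orphan_eggs"), 5)
})

test_that("record count equals the number of same-id runs", {
  set.seed(91)
  for (k in 1:10) {
    ids <- sample(LETTERS[1:3], 30, replace = TRUE)
    ev <- nest_events(seq_along(ids), rep("rfid_read", 30), ids)
    runs <- sum(ids != c("", ids[-30]))
    expect_identical(nrow(process_event_stream(ev)), runs)
  }
})

test_that("egg assignment follows the MNO rule", {
  rec <- data.frame(hen_id = c("A", "B"), visit_start = c(0, 100),
                    nest_visit_duration = c(50, 50),
                    multiple_nest_occupation = c(0L, 1L),
                    egg_deposited = c(1L, 1L), deposition_time = c(10, 120))
  eggs <- data.frame(time = c(10, 120, 500))
  out <- assign_eggs(rec, eggs)
  expect_identical(out$outcome, c("assigned", "uncertain_mno", "undetected"))
  expect_identical(out$hen_id, c("A", NA, NA))
  # annotations pass through
  eggs2 <- data.frame(time = c(10, 20), annotation = c("blocked_in_nest", NA))
  out2 <- assign_eggs(rec, eggs2)
  expect_identical(out2$outcome, c("blocked_in_nest", "assigned"))
})

test_that("assignment statistics reproduce the accounting arithmetic", {
  outcomes <- data.frame(outcome = c(rep("assigned", 122),
                                     rep("uncertain_mno", 51),
                                     rep("blocked_in_nest", 2),
                                     rep("broken_in_tube", 2),
                                     "undetected"))
  st <- assignment_stats(outcomes, total_laid = 184, laid_outside = 6)
  expect_identical(st$inside, 178)
  expect_identical(st$percent_in_nest, 96.7)
  expect_identical(st$percent_assigned, 68.5)
  expect_identical(st$percent_unassigned, 31.5)
  expect_error(assignment_stats(outcomes, 100, 6), class = "thermonest_input_error")
  all_in <- data.frame(outcome = rep("assigned", 10))
  expect_identical(assignment_stats(all_in, 10)$percent_assigned, 100.0)
})

test_that("generated event streams are recovered exactly", {
  spec <- stream_spec(n_hens = 10, n_visits = 50, egg_prob = 0.4,
                      mno_prob = 0.2, seed = 97)
  gen <- generate_event_stream(spec)
  rec <- process_event_stream(gen$events)
  expect_identical(nrow(rec), 50L)
  truth <- gen$truth$records
  expect_equal(rec$hen_id, truth$hen_id)
  expect_equal(rec$visit_start, truth$visit_start)
  expect_equal(rec$nest_visit_duration, truth$nest_visit_duration)
  expect_identical(rec$multiple_nest_occupation, truth$multiple_nest_occupation)
  expect_identical(rec$egg_deposited, truth$egg_deposited)
  expect_equal(rec$deposition_time, truth$deposition_time)

  eggs <- gen$events[gen$events$kind == "egg_detected", "time", drop = FALSE]
  out <- assign_eggs(rec, eggs)
  expect_identical(out$outcome, gen$truth$egg_outcomes$outcome)
  expect_identical(out$hen_id, gen$truth$egg_outcomes$hen_id)
  # conservation: every egg event gets exactly one outcome
  expect_identical(nrow(out), sum(gen$events$kind == "egg_detected"))

  # degenerate probabilities
  none <- generate_event_stream(stream_spec(n_visits = 20, egg_prob = 0,
                                            mno_prob = 0, seed = 5))
  expect_identical(sum(none$events$kind == "egg_detected"), 0L)
  rec0 <- process_event_stream(none$events)
  expect_identical(sum(rec0$multiple_nest_occupation), 0L)
})

test_that("event and record logs round-trip losslessly", {
  gen <- generate_event_stream(stream_spec(n_visits = 12, seed = 19))
  evp <- tempfile(fileext = ".tsv")
  write_events(gen$events, evp)
  ev2 <- read_events(evp)
  expect_equal(ev2$time, gen$events$time)
  expect_identical(ev2$kind, gen$events$kind)
  expect_identical(is.na(ev2$payload), is.na(gen$events$payload))

  rec <- process_event_stream(gen$events)
  rp <- tempfile(fileext = ".tsv")
  write_records(rec, rp)
  rec2 <- read_records(rp)
  expect_equal(rec2, as.data.frame(rec), ignore_attr = TRUE)
  unlink(c(evp, rp))
})
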