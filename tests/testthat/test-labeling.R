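test_that("event detection thresholds at twice the run median", {
  # constant statistic: nothing exceeds 2x median
  expect_equal(nrow(detect_acc_events(fake_acc_summary(rep(1, 100)))), 0)
  expect_length(detect_movement_onsets(fake_acc_summary(rep(0, 100))), 0)

  # one isolated spike at three times the median; its difference interval
  # is (t - dt, t], so the event starts one grid step before its timestamp
  stat <- rep(1, 200)
  stat[120] <- 3
  ev <- detect_acc_events(fake_acc_summary(stat))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 120 * 0.05 - 0.05)
  expect_equal(ev$end, 120 * 0.05)

  # nearby above-threshold steps merge into one event, distant ones do not
  stat2 <- rep(1, 200)
  stat2[c(50, 52, 120)] <- 5
  ev2 <- detect_acc_events(fake_acc_summary(stat2), gap = 0.15)
  expect_equal(nrow(ev2), 2)
})

test_that("ACC instants map to their closest MAV instants", {
  mav <- structure(list(time = (1:100) * 0.05,
                        values = matrix(0, 100, 8), step = 0.05),
                   class = "mav_stream")
  same <- fake_acc_summary(rep(0, 99), dt = 0.05)
  idx <- align_acc_to_emg(same, mav)
  expect_equal(as.integer(idx), 1:99)
  expect_equal(attr(idx, "max_diff"), 0)

  # the two stated grids stay within 30 ms over a whole run
  acc_grid <- fake_acc_summary(rep(0, 2500), dt = 7 / 148.1)
  mav_big <- structure(list(time = (1:2400) * 0.05,
                            values = matrix(0, 2400, 8), step = 0.05),
                       class = "mav_stream")
  idx2 <- align_acc_to_emg(acc_grid, mav_big)
  expect_lte(attr(idx2, "max_diff"), 0.03)

  # an instant exactly between two MAV times goes to the earlier one
  tie <- structure(list(time = 0.075, stat = 0, median = 0, dt = 0.05),
                   class = "acc_summary")
  expect_equal(as.integer(align_acc_to_emg(tie, mav)), 1L)
})

test_that("noiseless labeling reproduces the ground truth track", {
  sched <- make_schedule("hammer")
  run <- generate_run(sched, noiseless_profile(), seed = 21)
  mav <- compute_mav(run)
  lab <- label_run(mav, summarize_acc(run), sched)
  expect_equal(attr(lab, "fallbacks"), 0)

  # truth labels, instance by instance
  truth_lab <- rep("NR", length(mav$time))
  for (i in seq_len(nrow(run$truth))) {
    sel <- mav$time >= run$truth$onset[i] & mav$time < run$truth$offset[i]
    truth_lab[sel] <- run$truth$code[i]
  }
  # agreement except within one 50 ms step of each boundary
  boundaries <- run$truth$onset[-1]
  near <- vapply(mav$time, function(t) any(abs(t - boundaries) <= 0.051),
                 logical(1))
  expect_true(all(lab$label[!near] == truth_lab[!near]))
  expect_gt(mean(lab$label == truth_lab), 0.98)
  # the run start is rest
  expect_true(all(lab$label[mav$time < 4.5] == "NR"))
})

test_that("every movement onset is recovered within one step when clean", {
  for (g in c(1, 5, 8)) {
    sched <- make_schedule(g)
    run <- generate_run(sched, noiseless_profile(), seed = 30 + g)
    onsets <- detect_movement_onsets(summarize_acc(run))
    grips <- activity_table()$code[activity_table()$is_grip]
    mov <- run$truth[!(run$truth$code %in% c("NR", grips)), ]
    miss <- vapply(mov$onset, function(o) min(abs(onsets - o)), numeric(1))
    expect_true(all(miss <= 0.05))
  }
})

test_that("grip starts never move more than 500 ms from schedule", {
  sched <- make_schedule("door knob")
  run <- generate_run(sched, default_profile(1), seed = 40)
  lab <- label_run(compute_mav(run), summarize_acc(run), sched)
  starts <- vapply(1:12, function(r) {
    sel <- lab$label == "DKG" &
      lab$time >= (5 + 10 * (r - 1)) - 1 & lab$time < (5 + 10 * (r - 1)) + 5
    min(lab$time[sel])
  }, numeric(1))
  sched_starts <- seq(5, 115, by = 10)
  expect_true(all(abs(starts - sched_starts) <= 0.5 + 0.051))
})

test_that("NR subsampling keeps exactly the run-start window", {
  sched <- make_schedule("key")
  run <- generate_run(sched, default_profile(1), seed = 50)
  lab <- label_run(compute_mav(run), summarize_acc(run), sched)
  sub <- subsample_nr(lab)
  expect_equal(sum(sub$label == "NR"), 60)
  # non-NR instances are untouched
  expect_equal(sum(sub$label != "NR"), sum(lab$label != "NR"))
  expect_equal(sub$values[sub$label != "NR", ],
               lab$values[lab$label != "NR", ])
  # a stream with no NR at all passes through unchanged
  no_nr <- lab
  keep <- lab$label != "NR"
  no_nr$time <- lab$time[keep]
  no_nr$values <- lab$values[keep, ]
  no_nr$label <- lab$label[keep]
  expect_equal(subsample_nr(no_nr), no_nr)
})

test_that("segmentation is an exact run-length partition, then truncation", {
  labels <- c(rep("HG", 60), rep("HR", 20), rep("HG", 5), rep("NR", 15))
  stream <- structure(list(time = seq_along(labels) * 0.05,
                           values = matrix(0, length(labels), 8),
                           step = 0.05, label = labels),
                      class = "mav_stream")
  segs <- segment_activities(stream)
  expect_length(segs, 4)
  expect_equal(vapply(segs, `[[`, character(1), "code"),
               c("HG", "HR", "HG", "NR"))
  # concatenating (before truncation) reproduces the label track
  rebuilt <- unlist(lapply(segs, function(s)
    rep(s$code, s$full_length)))
  expect_equal(rebuilt, labels)
  # 60-instance grip truncated to 40; 20-instance movement untouched
  expect_length(segs[[1]]$idx, 40)
  expect_length(segs[[2]]$idx, 20)
  # alternating labels become three segments
  alt <- structure(list(time = (1:3) * 0.05, values = matrix(0, 3, 8),
                        step = 0.05, label = c("HG", "HR", "HG")),
                   class = "mav_stream")
  expect_length(segment_activities(alt), 3)
})

test_that("repetition indices follow the protocol grid", {
  sched <- make_schedule("hammer")
  run <- generate_run(sched, noiseless_profile(), seed = 60)
  lab <- label_run(compute_mav(run), summarize_acc(run), sched)
  segs <- Filter(function(s) s$code != "NR", segment_activities(lab))
  for (s in segs) {
    expect_true(s$rep >= 1 && s$rep <= 12)
    expect_true(s$start >= 5 + 10 * (s$rep - 1) - 0.5)
    expect_true(s$start < 5 + 10 * s$rep)
  }
})
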