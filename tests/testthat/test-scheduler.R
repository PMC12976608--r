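test_that("schedule expansion follows the stagger recurrence", {
  sched <- expand_schedule(fixation_protocol(), 26)
  expect_identical(nrow(sched), 36L)
  s0 <- sched[sched$sample_index == 0, ]
  expect_equal(s0$start, c(0, 60.5, 80.5))
  # sample j is offset by j * interval in every operation
  for (j in 1:11) {
    sj <- sched[sched$sample_index == j, ]
    expect_equal(sj$start, s0$start + j * 26)
  }

  # zero interval: all samples coincide
  sched0 <- expand_schedule(fixation_protocol(n = 2), 0)
  expect_equal(sched0$start[sched0$sample_index == 0],
               sched0$start[sched0$sample_index == 1])

  # buffered busy windows
  p <- two_step_protocol()
  s <- expand_schedule(p, 2)
  expect_equal(s$start, c(0, 11, 2, 13))
  expect_equal(s$busy_end, c(2, 13, 4, 15))
})

test_that("buffer shifts later operations only under the shift policy", {
  p <- two_step_protocol(n = 1)
  w <- expand_schedule(p, 0)
  s <- expand_schedule(p, 0, buffer_policy = "shift")
  expect_equal(w$start[w$op_index == 1], 11)
  expect_equal(s$start[s$op_index == 1], 12)  # wait runs from the buffered end
})

test_that("positive-length busy-window overlaps are conflicts; touches are not", {
  conf <- detect_conflicts(expand_schedule(one_op_protocol(), 2))
  expect_identical(nrow(conf), 1L)
  expect_equal(conf$overlap_start, 2)
  expect_equal(conf$overlap_end, 3)
  expect_false(conf$same_sample)

  expect_identical(nrow(detect_conflicts(expand_schedule(one_op_protocol(), 3))),
                   0L)

  conf6 <- detect_conflicts(expand_schedule(fixation_protocol(), 6))
  expect_gt(nrow(conf6[!conf6$same_sample, ]), 0L)
})

test_that("occupancy track partitions the horizon by multiplicity", {
  occ <- occupancy_track(expand_schedule(one_op_protocol(), 2))
  expect_equal(occ$start, c(0, 2, 3))
  expect_equal(occ$end, c(2, 3, 5))
  expect_identical(occ$multiplicity, c(1L, 2L, 1L))
  expect_identical(occ$state, c("busy", "conflict", "busy"))

  # adjacency: segments tile [0, horizon] and neighbors differ
  sched <- expand_schedule(fixation_protocol(), 6)
  occ <- occupancy_track(sched)
  expect_equal(occ$start_mm[-1], occ$end_mm[-nrow(occ)])
  expect_equal(occ$start_mm[1], 0)
  expect_equal(occ$end_mm[nrow(occ)], max(sched$busy_end_mm))
  expect_true(all(diff(occ$multiplicity) != 0L))
})

test_that("busy time is conserved with multiplicity on random schedules", {
  set.seed(303)
  for (i in 1:60) {
    p <- random_protocol()
    delta <- sample(0:60, 1) * 0.25
    sched <- expand_schedule(p, delta)
    occ <- occupancy_track(sched)
    total <- sum(occ$multiplicity * (occ$end_mm - occ$start_mm))
    d <- labsched:::op_durations_mm(p)
    expect_equal(total, labsched:::n_samples(p) * sum(d + p$buffer_mm))
  }
})

test_that("conflict windows are translation invariant", {
  set.seed(304)
  for (i in 1:25) {
    p <- random_protocol()
    delta <- sample(0:40, 1) * 0.25
    lead <- labsched:::as_mmin(sample(1:50, 1) * 0.5)
    base <- detect_conflicts(expand_schedule(p, delta))
    shifted_sched <- expand_schedule(p, delta)
    for (col in c("start_mm", "hands_on_end_mm", "busy_end_mm")) {
      shifted_sched[[col]] <- shifted_sched[[col]] + lead
    }
    shifted <- detect_conflicts(shifted_sched)
    expect_identical(shifted$overlap_start_mm, base$overlap_start_mm + lead)
    expect_identical(shifted$overlap_end_mm, base$overlap_end_mm + lead)
    expect_identical(shifted[, c("first_sample", "first_op", "second_sample",
                                 "second_op")],
                     base[, c("first_sample", "first_op", "second_sample",
                              "second_op")])
  }
})

test_that("intervals of at least span + buffer never conflict", {
  set.seed(305)
  for (i in 1:40) {
    p <- random_protocol()
    limit_mm <- labsched:::protocol_span_mm(p) + p$buffer_mm
    extra <- sample(0:10, 1) * 250
    conf <- detect_conflicts(
      expand_schedule(p, labsched:::mmin_to_min(limit_mm + extra)))
    expect_identical(nrow(conf[!conf$same_sample, ]), 0L)
  }
})

test_that("sweep detection equals the all-pairs oracle on random instances", {
  set.seed(306)
  for (i in 1:200) {
    p <- random_protocol()
    delta <- sample(0:48, 1) * 0.25
    sched <- expand_schedule(p, delta)
    got <- detect_conflicts(sched)[, conflict_cols]
    want <- oracle_conflict_pairs(sched)
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})
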