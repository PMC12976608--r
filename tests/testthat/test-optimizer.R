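test_that("first-hit lattice scan finds the documented intervals", {
  r <- find_optimal_interval(two_step_protocol(), verify = TRUE)
  expect_identical(r$status, "found")
  expect_equal(r$interval, 2)
  # every candidate below the result conflicted
  expect_true(all(r$tested$conflicts[-nrow(r$tested)] >= 1L))
  expect_identical(r$tested$conflicts[nrow(r$tested)], 0L)

  r1 <- find_optimal_interval(fixation_protocol(), verify = TRUE)
  expect_identical(r1$status, "found")
  expect_equal(r1$interval, 26)
  expect_identical(nrow(r1$schedule), 36L)
})

test_that("search fails once candidates would exceed the protocol span", {
  r <- find_optimal_interval(one_op_protocol(d = 2, buffer = 1,
                                             granularity = 0.25))
  expect_identical(r$status, "failed")
  expect_true(is.na(r$interval))
  # candidates stop at P = 2: 0.25 .. 2.0
  expect_equal(max(r$tested$candidate), 2)
  expect_identical(nrow(r$tested), 8L)
  expect_true(all(r$tested$conflicts >= 1L))
  # the analytic limit P + b is nevertheless valid
  expect_true(brute_force_valid(one_op_protocol(), 3))
})

test_that("a single sample is trivially schedulable at interval zero", {
  r <- find_optimal_interval(fixation_protocol(n = 1))
  expect_identical(r$status, "trivial")
  expect_equal(r$interval, 0)
  expect_identical(nrow(r$schedule), 3L)
})

test_that("found intervals are lattice-minimal against the brute-force oracle", {
  set.seed(404)
  n_found <- 0
  for (i in 1:100) {
    p <- random_protocol(max_ops = 4, max_samples = 4, max_duration = 3,
                         max_wait = 6)
    r <- find_optimal_interval(p)
    g <- p$granularity_mm
    if (r$status == "found") {
      n_found <- n_found + 1
      expect_true(brute_force_valid(p, r$interval))
      if (r$interval_mm > g) {
        below <- seq(g, r$interval_mm - g, by = g)
        ok <- vapply(below, function(mm) {
          brute_force_valid(p, labsched:::mmin_to_min(mm))
        }, logical(1))
        expect_false(any(ok))
      }
    } else if (r$status == "failed") {
      P <- labsched:::protocol_span_mm(p)
      if (P >= g) {
        ok <- vapply(seq(as.numeric(g), P, by = as.numeric(g)), function(mm) {
          brute_force_valid(p, labsched:::mmin_to_min(mm))
        }, logical(1))
        expect_false(any(ok))
      }
      expect_true(brute_force_valid(p, labsched:::mmin_to_min(P + p$buffer_mm)))
    }
  }
  expect_gt(n_found, 10)
})

test_that("coarser granularity cannot find a smaller interval", {
  set.seed(405)
  checked <- 0
  for (i in 1:80) {
    p <- random_protocol(max_ops = 4, max_samples = 4, granularity = 0.25)
    r_fine <- find_optimal_interval(p)
    p5 <- p
    p5$granularity_mm <- 5L * p$granularity_mm
    r_coarse <- find_optimal_interval(p5)
    if (r_fine$status == "found" && r_coarse$status == "found") {
      checked <- checked + 1
      expect_gte(r_coarse$interval_mm, r_fine$interval_mm)
      expect_identical(r_coarse$interval_mm %% as.numeric(p5$granularity_mm), 0)
    }
  }
  expect_gt(checked, 5)
})

test_that("optimization is deterministic", {
  r1 <- find_optimal_interval(fixation_protocol())
  r2 <- find_optimal_interval(fixation_protocol())
  expect_equal(r1$tested, r2$tested)
  expect_equal(r1$interval, r2$interval)
})

test_that("manual evaluation annotates conflicts and validity", {
  bad <- fixation_protocol(mode = "manual", manual_interval = 6)
  ev <- evaluate_manual_interval(bad)
  expect_false(ev$valid)
  expect_gt(nrow(ev$conflicts), 0)

  ok <- protocol(list(operation("x", 2)), c("a", "b"),
                 mode = "manual", manual_interval = 5)
  expect_true(evaluate_manual_interval(ok)$valid)

  zero <- protocol(list(operation("x", 2)), c("a", "b"),
                   mode = "manual", manual_interval = 0)
  expect_false(evaluate_manual_interval(zero)$valid)

  expect_error(evaluate_manual_interval(fixation_protocol()),
               "manual_interval")
})

test_that("manual validity agrees with the brute-force oracle on random instances", {
  set.seed(406)
  for (i in 1:150) {
    p <- random_protocol()
    delta <- sample(0:60, 1) * 0.25
    p$mode <- "manual"
    p$manual_mm <- labsched:::as_mmin(delta)
    expect_identical(evaluate_manual_interval(p)$valid,
                     brute_force_valid(p, delta))
  }
})

test_that("half-open window boundaries decide validity exactly", {
  expect_true(brute_force_valid(one_op_protocol(), 3))     # touch at 3
  expect_false(brute_force_valid(one_op_protocol(), 2.75)) # 0.25 overlap
})
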