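test_that("the chronological view is a sorted permutation of all instances", {
  sched <- expand_schedule(fixation_protocol(), 26)
  bt <- schedule_by_time(sched)
  expect_identical(nrow(bt), 36L)
  expect_identical(bt$clock_time[1], 0)
  expect_identical(bt$sample[1], "coverslip_01")
  expect_identical(bt$operation[1], "Add drug")
  expect_true(all(diff(bt$clock_time_mm) >= 0))

  # ties at interval 0 break by sample order
  s0 <- schedule_by_time(expand_schedule(fixation_protocol(n = 2), 0))
  expect_identical(s0$sample[1:2], c("coverslip_01", "coverslip_02"))

  # single sample: protocol order
  one <- schedule_by_time(expand_schedule(fixation_protocol(n = 1), 0))
  expect_identical(one$operation,
                   c("Add drug", "Wash + start fixation", "Wash + halt fixation"))
})

test_that("by-time and by-sample views hold identical (sample, op, start) multisets", {
  sched <- expand_schedule(fixation_protocol(), 26)
  bt <- schedule_by_time(sched)
  bs <- schedule_by_sample(sched)
  expect_identical(dim(bs), c(12L, 4L))
  long <- do.call(rbind, lapply(2:4, function(k) {
    data.frame(sample = bs$sample, operation = names(bs)[k], start = bs[[k]])
  }))
  a <- long[order(long$sample, long$operation, long$start), ]
  b <- data.frame(sample = bt$sample, operation = bt$operation,
                  start = bt$clock_time)
  b <- b[order(b$sample, b$operation, b$start), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  # stagger identity: row j minus row 1 equals (j-1) * interval
  for (k in 2:4) expect_equal(bs[[k]] - bs[[k]][1], (0:11) * 26)
})

test_that("gantt layout aggregates occupancy and conserves bar lengths", {
  p <- fixation_protocol(mode = "manual", manual_interval = 6)
  ev <- evaluate_manual_interval(p)
  layout <- gantt_layout(ev)
  expect_identical(layout$rows[13], "Hands-On Time")
  expect_identical(layout$subtitle,
                   sprintf("WARNING: %d conflicts at interval 6",
                           nrow(ev$conflicts[!ev$conflicts$same_sample, ])))
  hands_on <- layout$bars[layout$bars$kind == "hands_on" &
                          layout$bars$row <= 12, ]
  expect_equal(sum(hands_on$end - hands_on$start), 12 * (0.5 + 5 + 5))
  occ <- occupancy_track(ev$schedule)
  conflict_bars <- layout$bars[layout$bars$kind == "conflict", ]
  expect_equal(sum(conflict_bars$end - conflict_bars$start),
               sum(occ$end[occ$multiplicity >= 2] - occ$start[occ$multiplicity >= 2]))
  # valid schedules advertise their interval instead of warning
  ok <- gantt_layout(find_optimal_interval(fixation_protocol()))
  expect_match(ok$subtitle, "^Optimized staggering interval: 26 min$")
})

test_that("SVG rendering is structural and byte-deterministic", {
  layout <- gantt_layout(find_optimal_interval(fixation_protocol()))
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_gantt(layout, f1, "svg")
  render_gantt(layout, f2, "svg")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  svg <- readLines(f1)
  expect_identical(sum(grepl('<rect class="bar ', svg)), nrow(layout$bars))

  bad <- gantt_layout(evaluate_manual_interval(
    fixation_protocol(mode = "manual", manual_interval = 6)))
  fb <- withr::local_tempfile(fileext = ".svg")
  render_gantt(bad, fb, "svg")
  svgb <- paste(readLines(fb), collapse = "\n")
  expect_true(grepl('class="bar conflict"[^/]*fill="#D62728"', svgb))
  expect_error(render_gantt(layout, fb, "pdf"))
})

test_that("PNG rendering writes an image file", {
  layout <- gantt_layout(find_optimal_interval(two_step_protocol()))
  f <- withr::local_tempfile(fileext = ".png")
  render_gantt(layout, f, "png")
  expect_true(file.size(f) > 0)
  expect_identical(readBin(f, "raw", 8),
                   as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
})

test_that("report archives hold exactly five members and are reproducible", {
  doc <- load_session(fixture_path("fixation_parallel.json"))
  res <- find_optimal_interval(doc$protocol)
  z1 <- withr::local_tempfile(fileext = ".zip")
  z2 <- withr::local_tempfile(fileext = ".zip")
  export_report(doc, res, z1)
  export_report(doc, res, z2)
  listing <- utils::unzip(z1, list = TRUE)
  expect_setequal(listing$Name,
                  c("session.json", "schedule_by_time.csv",
                    "schedule_by_sample.csv", "gantt.svg", "summary.txt"))
  expect_identical(nrow(listing), 5L)
  expect_true(all(as.Date(listing$Date) == as.Date("1980-01-01")))
  expect_identical(readBin(z1, "raw", file.size(z1)),
                   readBin(z2, "raw", file.size(z2)))
  # the embedded session round-trips
  exdir <- withr::local_tempdir()
  utils::unzip(z1, exdir = exdir)
  inner <- load_session(file.path(exdir, "session.json"))
  expect_equal(inner, doc)
  # CSV uses CRLF and a header row
  csv <- readBin(file.path(exdir, "schedule_by_time.csv"), "raw",
                 file.size(file.path(exdir, "schedule_by_time.csv")))
  txt <- rawToChar(csv)
  expect_true(grepl("\r\n", txt, fixed = TRUE))
  expect_identical(strsplit(txt, "\r\n")[[1]][1],
                   "clock_time,sample,operation,duration")
})
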