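# shared builders and independent oracles

# 12-coverslip fixation protocol: drug 0.5 min / wait 60, fix-start 5 / wait
# 15, fix-halt 5; buffer 1, granularity 0.25
fixation_protocol <- function(n = 12, mode = "automatic", manual_interval = NULL) {
  protocol(list(operation("Add drug", 0.5, 60),
                operation("Wash + start fixation", 5, 15),
                operation("Wash + halt fixation", 5)),
           samples = sprintf("coverslip_%02d", seq_len(n)),
           buffer = 1, granularity = 0.25,
           mode = mode, manual_interval = manual_interval)
}

# minimal two-step protocol: 1 min hands-on, 10 min wait, 1 min hands-on
two_step_protocol <- function(n = 2, buffer = 1, granularity = 0.25) {
  protocol(list(operation("load", 1, 10), operation("read", 1)),
           samples = sprintf("s%d", seq_len(n)),
           buffer = buffer, granularity = granularity)
}

one_op_protocol <- function(d = 2, n = 2, buffer = 1, ...) {
  protocol(list(operation("op", d)), samples = sprintf("s%d", seq_len(n)),
           buffer = buffer, ...)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "labsched", mustWork = TRUE)
}

# independent all-pairs conflict oracle: plain double loop over every
# unordered pair of task instances, no sorting, no sweep
oracle_conflict_pairs <- function(schedule) {
  s <- schedule$start_mm
  e <- schedule$busy_end_mm
  samp <- schedule$sample_index
  opi <- schedule$op_index
  m <- nrow(schedule)
  ai <- integer(0); bi <- integer(0); lo_v <- numeric(0); hi_v <- numeric(0)
  if (m >= 2) {
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        lo <- max(s[i], s[j])
        hi <- min(e[i], e[j])
        if (hi > lo) {
          # order the pair: earlier start first, ties by sample then op
          a <- i; b <- j
          if (s[j] < s[i] ||
              (s[j] == s[i] && (samp[j] < samp[i] ||
                (samp[j] == samp[i] && opi[j] < opi[i])))) {
            a <- j; b <- i
          }
          ai <- c(ai, a); bi <- c(bi, b)
          lo_v <- c(lo_v, lo); hi_v <- c(hi_v, hi)
        }
      }
    }
  }
  res <- data.frame(first_sample = samp[ai], first_op = opi[ai],
                    second_sample = samp[bi], second_op = opi[bi],
                    overlap_start_mm = lo_v, overlap_end_mm = hi_v)
  res <- res[order(res$overlap_start_mm, res$first_sample, res$first_op,
                   res$second_sample, res$second_op), , drop = FALSE]
  rownames(res) <- NULL
  res
}

conflict_cols <- c("first_sample", "first_op", "second_sample", "second_op",
                   "overlap_start_mm", "overlap_end_mm")

random_session <- function() {
  p <- random_protocol()
  if (stats::runif(1) < 0.3) {
    p$mode <- "manual"
    p$manual_mm <- labsched:::as_mmin(sample(0:40, 1) * 0.25)
  }
  session(p,
          base_color = if (stats::runif(1) < 0.5) sprintf("#%06X", sample(0:16777215, 1)) else NULL,
          x_tick = if (stats::runif(1) < 0.5) sample(c(1, 5, 10, 15), 1) else NULL)
}
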