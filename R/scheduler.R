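# Schedule expansion and exact conflict detection.
#
# Coordinates: minutes from t = 0 at sample 1's first hands-on start; sample
# j (0-based index j-1 in formulas) is offset by (j-1) * interval. Every
# hands-on window is extended by the buffer into a half-open busy window
# [start, busy_end); two busy windows conflict iff they intersect with
# positive length, so windows that merely touch are compatible. All tests are
# exact integer comparisons on milliminutes -- no grid sampling, which could
# miss sub-granularity overlaps.

#' Expand a protocol into per-sample task instances
#'
#' Lays out one copy of the protocol per sample, consecutive samples offset
#' by the staggering interval. Within a sample, operation k starts when
#' operation k-1's hands-on window ends plus its wait; under the default
#' `buffer_policy = "window"` the buffer extends the occupied window only and
#' does not delay the sample's own subsequent operations (waits run from the
#' hands-on end, matching the buffer's role as a task-switching margin).
#' `buffer_policy = "shift"` is the alternative convention in which waits run
#' from the buffered end, pushing later operations back; it is exposed for
#' robustness checks.
#'
#' @param protocol a [protocol()]; must validate without errors.
#' @param interval staggering interval in minutes (>= 0).
#' @param buffer_policy `"window"` (default) or `"shift"`, see above.
#' @return a `lab_schedule`: a data frame with one row per task instance
#'   (columns `sample_index`, `op_index` -- both 0-based -- `sample`,
#'   `operation`, `start`, `hands_on_end`, `busy_end` in minutes, and exact
#'   `*_mm` milliminute counterparts), carrying the protocol and interval as
#'   attributes.
#' @export
expand_schedule <- function(protocol, interval,
                            buffer_policy = c("window", "shift")) {
  stopifnot(inherits(protocol, "lab_protocol"))
  buffer_policy <- match.arg(buffer_policy)
  assert_valid(protocol)
  delta <- as_mmin(interval, "interval")
  if (delta < 0L) stop("interval must be >= 0", call. = FALSE)
  d <- op_durations_mm(protocol)
  w <- op_waits_mm(protocol)
  b <- protocol$buffer_mm
  K <- n_ops(protocol)
  n <- n_samples(protocol)
  step <- if (buffer_policy == "window") d + w else d + b + w
  base <- cumsum(c(0, step[-K]))            # sample offset 0 start times
  samp <- rep(seq_len(n) - 1L, each = K)
  opi <- rep(seq_len(K) - 1L, times = n)
  start <- rep(base, times = n) + samp * as.numeric(delta)
  hoe <- start + d[opi + 1L]
  out <- data.frame(
    sample_index = samp,
    op_index = opi,
    sample = protocol$samples[samp + 1L],
    operation = op_names(protocol)[opi + 1L],
    start = mmin_to_min(start),
    hands_on_end = mmin_to_min(hoe),
    busy_end = mmin_to_min(hoe + b),
    start_mm = start,
    hands_on_end_mm = hoe,
    busy_end_mm = hoe + b,
    stringsAsFactors = FALSE)
  structure(out,
            protocol = protocol, interval_mm = delta,
            buffer_policy = buffer_policy,
            class = c("lab_schedule", "data.frame"))
}

schedule_protocol <- function(schedule) attr(schedule, "protocol")
schedule_interval_mm <- function(schedule) attr(schedule, "interval_mm")

#' Detect operator conflicts in a schedule
#'
#' Reports every unordered pair of task instances whose busy windows
#' `[start, busy_end)` intersect with positive length -- moments at which the
#' single operator would be needed in two places at once. Zero-length touches
#' are not conflicts. Implemented as a sweep over instances sorted by start
#' with an active set, so only candidate pairs are compared.
#'
#' Same-sample overlaps (possible when a wait is shorter than the buffer) are
#' included with `same_sample = TRUE`; they occur at every staggering
#' interval and are excluded from interval validity, which considers
#' cross-sample conflicts only.
#'
#' @param schedule a `lab_schedule` from [expand_schedule()].
#' @return data frame with one row per conflicting pair: 0-based
#'   `first_sample`, `first_op`, `second_sample`, `second_op` (the instance
#'   starting earlier is "first"; ties broken by sample then operation
#'   index), `overlap_start`, `overlap_end` (minutes), exact `*_mm` columns,
#'   and `same_sample`. Rows are sorted by overlap start, then first, then
#'   second instance.
#' @export
detect_conflicts <- function(schedule) {
  stopifnot(inherits(schedule, "lab_schedule"))
  m <- nrow(schedule)
  s <- schedule$start_mm
  e <- schedule$busy_end_mm
  samp <- schedule$sample_index
  opi <- schedule$op_index
  ord <- order(s, samp, opi)
  res_first <- integer(0); res_second <- integer(0)
  res_os <- numeric(0); res_oe <- numeric(0)
  active <- integer(0)
  for (idx in ord) {
    if (length(active)) {
      active <- active[e[active] > s[idx]]     # drop windows already closed
      hit <- active[pmin(e[active], e[idx]) > s[idx]]
      for (j in hit) {
        # j started no later than idx (ties resolved by the sort order)
        res_first <- c(res_first, j)
        res_second <- c(res_second, idx)
        res_os <- c(res_os, s[idx])
        res_oe <- c(res_oe, min(e[j], e[idx]))
      }
    }
    active <- c(active, idx)
  }
  if (length(res_first) == 0) {
    return(empty_conflicts())
  }
  out <- data.frame(
    first_sample = samp[res_first], first_op = opi[res_first],
    second_sample = samp[res_second], second_op = opi[res_second],
    overlap_start = mmin_to_min(res_os), overlap_end = mmin_to_min(res_oe),
    overlap_start_mm = res_os, overlap_end_mm = res_oe,
    same_sample = samp[res_first] == samp[res_second])
  out <- out[order(out$overlap_start_mm, out$first_sample, out$first_op,
                   out$second_sample, out$second_op), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_conflicts <- function() {
  data.frame(first_sample = integer(), first_op = integer(),
             second_sample = integer(), second_op = integer(),
             overlap_start = numeric(), overlap_end = numeric(),
             overlap_start_mm = numeric(), overlap_end_mm = numeric(),
             same_sample = logical())
}

cross_sample_conflicts <- function(conflicts) {
  conflicts[!conflicts$same_sample, , drop = FALSE]
}

#' Operator occupancy track
#'
#' Sweep-line decomposition of the timeline `[0, max busy_end]` into maximal
#' segments of constant multiplicity (the number of busy windows covering the
#' segment): `multiplicity == 0` is free time, `== 1` the operator is busy,
#' `>= 2` a conflict. This is the aggregated "Hands-On Time" row of the Gantt
#' chart.
#'
#' @param schedule a `lab_schedule`.
#' @return data frame with `start`, `end` (minutes), `start_mm`, `end_mm`,
#'   `multiplicity`, `state` (`"free"`, `"busy"`, `"conflict"`). Segments
#'   partition the horizon; adjacent segments differ in multiplicity.
#' @export
occupancy_track <- function(schedule) {
  stopifnot(inherits(schedule, "lab_schedule"))
  s <- schedule$start_mm
  e <- schedule$busy_end_mm
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  horizon <- if (length(e)) max(e) else 0
  if (length(s) == 0) {
    seg <- data.frame(start_mm = 0, end_mm = horizon, multiplicity = 0L)
  } else {
    pts <- sort(unique(c(0, s, e, horizon)))
    starts <- pts[-length(pts)]
    ends <- pts[-1]
    mult <- vapply(starts, function(p) sum(s <= p & p < e), integer(1))
    run <- rle(mult)
    stop_i <- cumsum(run$lengths)
    start_i <- c(1L, head(stop_i, -1) + 1L)
    seg <- data.frame(start_mm = starts[start_i], end_mm = ends[stop_i],
                      multiplicity = run$values)
  }
  state <- ifelse(seg$multiplicity >= 2L, "conflict",
                  ifelse(seg$multiplicity == 1L, "busy", "free"))
  data.frame(start = mmin_to_min(seg$start_mm), end = mmin_to_min(seg$end_mm),
             start_mm = seg$start_mm, end_mm = seg$end_mm,
             multiplicity = seg$multiplicity,
             state = state)
}

#' @export
print.lab_schedule <- function(x, n = 10, ...) {
  cat(sprintf("<lab_schedule> %d task instance(s), interval %s min\n",
              nrow(x), mmin_format(schedule_interval_mm(x))))
  print.data.frame(utils::head(as.data.frame(x)[, 1:7], n))
  if (nrow(x) > n) cat(sprintf("  ... %d more row(s)\n", nrow(x) - n))
  invisible(x)
}
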