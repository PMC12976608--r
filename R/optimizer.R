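# Staggering interval optimization: a linear first-hit scan over the
# candidate lattice g, 2g, 3g, ... Validity is not monotone in the interval
# (a larger offset can bring later operations back into collision), so the
# first conflict-free candidate on the lattice IS the lattice minimum and
# bisection would be incorrect. The scan stops, reporting failure, once the
# next candidate would exceed the protocol span P: beyond that samples run
# sequentially and staggering has no benefit.

#' Find the minimal conflict-free staggering interval
#'
#' Tests candidate intervals g, 2g, 3g, ... (g = the protocol's granularity)
#' in increasing order, expanding the full schedule and detecting conflicts
#' at each, and returns the first candidate with no cross-sample conflict.
#' If every candidate up to the protocol span P conflicts, the search fails:
#' no staggered schedule exists on the lattice within a single protocol's
#' duration (the guaranteed-valid interval P + buffer lies beyond it). A
#' single sample cannot conflict with itself across samples, so n = 1
#' short-circuits to a trivial result with interval 0.
#'
#' @param protocol a [protocol()]; must validate without errors and have
#'   granularity > 0.
#' @param verify if `TRUE`, re-check the returned interval with the
#'   independent all-pairs oracle [brute_force_valid()] before reporting.
#' @return an object of class `lab_optimization` with fields `status`
#'   (`"found"`, `"failed"` or `"trivial"`), `interval` (minutes; `NA` when
#'   failed), `interval_mm`, `tested` (data frame of candidates with their
#'   cross-sample conflict counts, in test order), and `schedule` (the
#'   conflict-free schedule, when found/trivial).
#' @examples
#' p <- protocol(list(operation("load", 1, 10), operation("read", 1)),
#'               samples = c("a", "b"))
#' find_optimal_interval(p)$interval  # 2
#' @export
find_optimal_interval <- function(protocol, verify = FALSE) {
  stopifnot(inherits(protocol, "lab_protocol"))
  assert_valid(protocol)
  g <- protocol$granularity_mm
  if (g <= 0L) stop("granularity must be > 0", call. = FALSE)
  tested <- list()
  if (n_samples(protocol) == 1) {
    sched <- expand_schedule(protocol, 0)
    return(new_optimization("trivial", 0L, empty_tested(), sched, protocol))
  }
  P <- protocol_span_mm(protocol)
  k <- 1L
  cand <- as.numeric(g)
  while (cand <= P) {
    sched <- expand_schedule(protocol, mmin_to_min(cand))
    n_conf <- nrow(cross_sample_conflicts(detect_conflicts(sched)))
    tested[[k]] <- n_conf
    if (n_conf == 0L) {
      if (verify && !brute_force_valid(protocol, mmin_to_min(cand))) {
        stop("internal error: sweep result rejected by brute-force oracle at interval ",
             mmin_format(cand), call. = FALSE)
      }
      return(new_optimization("found", cand, tested_df(g, tested), sched, protocol))
    }
    k <- k + 1L
    cand <- k * as.numeric(g)
  }
  new_optimization("failed", NA, tested_df(g, tested), NULL, protocol)
}

empty_tested <- function() {
  data.frame(candidate = numeric(), candidate_mm = numeric(),
             conflicts = integer())
}

tested_df <- function(g, tested) {
  if (length(tested) == 0) return(empty_tested())
  mm <- seq_along(tested) * as.numeric(g)
  data.frame(candidate = mmin_to_min(mm), candidate_mm = mm,
             conflicts = unlist(tested))
}

new_optimization <- function(status, interval_mm, tested, schedule, protocol) {
  structure(
    list(status = status,
         interval = if (is.na(interval_mm)) NA_real_ else mmin_to_min(interval_mm),
         interval_mm = interval_mm,
         tested = tested,
         schedule = schedule,
         protocol = protocol),
    class = "lab_optimization")
}

#' Evaluate a manually chosen staggering interval
#'
#' Expands the schedule at the protocol's `manual_interval` and annotates it
#' with every conflict. The schedule is valid iff there is no cross-sample
#' conflict; Gantt layouts built from an invalid evaluation carry a warning
#' subtitle.
#'
#' @param protocol a [protocol()] in manual mode with `manual_interval` set.
#' @return an object of class `lab_manual_eval`: list with `schedule`,
#'   `conflicts` (all conflicting pairs, see [detect_conflicts()]), `valid`,
#'   and `interval` (minutes).
#' @export
evaluate_manual_interval <- function(protocol) {
  stopifnot(inherits(protocol, "lab_protocol"))
  if (is.na(protocol$manual_mm)) {
    stop("manual evaluation requires a protocol with manual_interval set",
         call. = FALSE)
  }
  assert_valid(protocol)
  sched <- expand_schedule(protocol, mmin_to_min(protocol$manual_mm))
  conf <- detect_conflicts(sched)
  structure(
    list(schedule = sched,
         conflicts = conf,
         valid = nrow(cross_sample_conflicts(conf)) == 0L,
         interval = mmin_to_min(protocol$manual_mm),
         interval_mm = protocol$manual_mm,
         protocol = protocol),
    class = "lab_manual_eval")
}

#' Brute-force schedule validity oracle
#'
#' Independent all-pairs check: expands the schedule at the given interval
#' and tests every pair of task instances for positive-length busy-window
#' overlap directly, with no sweep, sorting shortcuts or shared code with
#' [detect_conflicts()]. Intended as a test oracle and for `verify` mode.
#'
#' @param protocol a [protocol()].
#' @param interval staggering interval in minutes.
#' @param buffer_policy forwarded to [expand_schedule()].
#' @return `TRUE` iff no two task instances of different samples overlap.
#' @export
brute_force_valid <- function(protocol, interval,
                              buffer_policy = c("window", "shift")) {
  sched <- expand_schedule(protocol, interval, match.arg(buffer_policy))
  s <- sched$start_mm
  e <- sched$busy_end_mm
  samp <- sched$sample_index
  m <- length(s)
  if (m < 2) return(TRUE)
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      if (samp[i] != samp[j] &&
          min(e[i], e[j]) > max(s[i], s[j])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' @export
print.lab_optimization <- function(x, ...) {
  cat("<lab_optimization> status:", x$status)
  if (x$status != "failed") {
    cat(sprintf(", interval %s min (tested %d candidate(s))",
                mmin_format(x$interval_mm), nrow(x$tested)))
  } else {
    cat(sprintf(" after %d candidate(s); no conflict-free interval <= span %s min",
                nrow(x$tested), mmin_format(protocol_span_mm(x$protocol))))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.lab_manual_eval <- function(x, ...) {
  n_cross <- nrow(cross_sample_conflicts(x$conflicts))
  cat(sprintf("<lab_manual_eval> interval %s min: %s (%d cross-sample conflict(s))\n",
              mmin_format(x$interval_mm),
              if (x$valid) "valid" else "INVALID", n_cross))
  invisible(x)
}
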