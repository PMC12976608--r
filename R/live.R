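# Live execution engine: a pure function of the schedule and the elapsed
# time. The wall clock is always injected by the caller, never read here, so
# behavior is fully deterministic and testable.

#' Live execution status of a schedule
#'
#' Classifies every task instance at a moment in time: `current` instances
#' have begun but their hands-on window has not ended (`start <= now <
#' hands_on_end`), `completed` instances have `hands_on_end <= now`, and
#' `next` is the earliest instance with `start > now` (ties broken by sample
#' then operation order). The countdown is the time remaining until `next`
#' begins -- what an operator's timer displays.
#'
#' @param schedule a `lab_schedule`, normally conflict-free.
#' @param now current wall-clock position (minutes, or anything
#'   subtractable from `run_start` to minutes, e.g. two [POSIXct] values).
#' @param run_start wall-clock position of the run start (minutes from the
#'   same origin as `now`; default 0, i.e. `now` is already elapsed minutes).
#' @return an object of class `lab_live_status`: list with `now` (elapsed
#'   minutes), `current` (data frame of running instances), `next_task`
#'   (1-row data frame or `NULL`), `countdown` (minutes, `NA` when nothing
#'   is left), `completed`, `remaining`, `total`.
#' @examples
#' p <- protocol(list(operation("load", 1, 10), operation("read", 1)), "s1")
#' st <- live_status(expand_schedule(p, 0), now = 0.5)
#' st$countdown  # 10.5: the read step starts at minute 11
#' @export
live_status <- function(schedule, now, run_start = 0) {
  stopifnot(inherits(schedule, "lab_schedule"))
  if (inherits(now, "POSIXt") && inherits(run_start, "POSIXt")) {
    elapsed_min <- as.numeric(difftime(now, run_start, units = "mins"))
    if (elapsed_min < 0) stop("now precedes run_start", call. = FALSE)
    elapsed <- round(elapsed_min * 1000)
  } else {
    now_mm <- as_mmin(now, "now")
    start_mm <- as_mmin(run_start, "run_start")
    if (now_mm < start_mm) stop("now precedes run_start", call. = FALSE)
    elapsed <- now_mm - start_mm
  }
  s <- schedule$start_mm
  hoe <- schedule$hands_on_end_mm
  cur <- s <= elapsed & elapsed < hoe
  done <- hoe <= elapsed
  upcoming <- which(s > elapsed)
  nxt <- NULL
  countdown <- NA_real_
  if (length(upcoming)) {
    up <- upcoming[order(s[upcoming], schedule$sample_index[upcoming],
                         schedule$op_index[upcoming])]
    nxt <- as.data.frame(schedule)[up[1], , drop = FALSE]
    rownames(nxt) <- NULL
    countdown <- mmin_to_min(s[up[1]] - elapsed)
  }
  structure(
    list(now = mmin_to_min(elapsed),
         current = {
       cd <- as.data.frame(schedule)[cur, , drop = FALSE]
       rownames(cd) <- NULL
       cd
     },
         next_task = nxt,
         countdown = countdown,
         completed = sum(done),
         remaining = sum(!done & !cur),
         total = nrow(schedule)),
    class = "lab_live_status")
}

#' @export
print.lab_live_status <- function(x, ...) {
  cat(sprintf("<lab_live_status> t = %s min: %d done, %d running, %d remaining\n",
              mmin_format(round(x$now * 1000)), x$completed, nrow(x$current),
              x$remaining))
  if (nrow(x$current)) {
    for (i in seq_len(nrow(x$current))) {
      cat(sprintf("  NOW: %s for %s (until %s min)\n",
                  x$current$operation[i], x$current$sample[i],
                  mmin_format(x$current$hands_on_end_mm[i])))
    }
  }
  if (!is.null(x$next_task)) {
    cat(sprintf("  next: %s for %s in %s min (at %s min)\n",
                x$next_task$operation, x$next_task$sample,
                mmin_format(round(x$countdown * 1000)),
                mmin_format(x$next_task$start_mm)))
  } else {
    cat("  schedule complete\n")
  }
  invisible(x)
}
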