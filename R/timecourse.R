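# Time Course Helper: turn requested absolute time points after an anchoring
# operation (e.g. "harvest at 5, 15, 30 and 60 min after label addition")
# into concrete repeated operations with computed inter-step waits.

#' Describe a time course expansion
#'
#' @param anchor_index 1-based position of the anchoring operation in the
#'   protocol (e.g. the drug-addition step the time points are measured from).
#' @param template_name name of the repeated operation (e.g. `"Harvest"`).
#' @param template_duration hands-on duration of each repeat, in minutes.
#' @param time_points strictly increasing time points, in minutes, at which
#'   each repeat's hands-on window must start, measured from the anchor
#'   reference. Consecutive points must be at least `template_duration`
#'   apart, otherwise the repeats themselves would overlap.
#' @param anchor_reference `"start_of_anchor"` (default): time points count
#'   from the moment the anchor's hands-on window begins -- the usual reading
#'   of "5 min after drug addition". `"end_of_anchor"`: from the moment it
#'   ends.
#' @return an object of class `lab_timecourse_request`.
#' @seealso [expand_time_course()]
#' @export
time_course_request <- function(anchor_index, template_name, template_duration,
                                time_points,
                                anchor_reference = c("start_of_anchor",
                                                     "end_of_anchor")) {
  anchor_reference <- match.arg(anchor_reference)
  stopifnot(length(anchor_index) == 1, anchor_index >= 1,
            anchor_index == as.integer(anchor_index),
            is.character(template_name), nzchar(template_name))
  tp <- as_mmin(time_points, "time_points")
  if (length(tp) < 1) stop("at least one time point is required", call. = FALSE)
  d_t <- as_mmin(template_duration, "template_duration")
  if (d_t < 0L) stop("template_duration must be >= 0", call. = FALSE)
  if (length(tp) > 1) {
    gap <- diff(tp)
    bad <- which(gap < d_t)
    if (any(gap <= 0L)) {
      i <- which(gap <= 0L)[1]
      stop(sprintf("time_points must be strictly increasing: t[%d]=%s, t[%d]=%s",
                   i, mmin_format(tp[i]), i + 1, mmin_format(tp[i + 1])),
           call. = FALSE)
    }
    if (length(bad)) {
      i <- bad[1]
      stop(sprintf(
        "time points %s and %s are closer than the template duration %s: the repeats would overlap",
        mmin_format(tp[i]), mmin_format(tp[i + 1]), mmin_format(d_t)),
        call. = FALSE)
    }
  }
  structure(
    list(anchor_index = as.integer(anchor_index),
         template_name = template_name,
         template_duration_mm = d_t,
         time_points_mm = tp,
         anchor_reference = anchor_reference),
    class = "lab_timecourse_request")
}

#' Expand a time course into concrete protocol operations
#'
#' Replaces everything after the anchoring operation with one operation per
#' requested time point, computing the waits so that repeat k's hands-on
#' window starts exactly at `anchor_reference + t_k`:
#' the anchor's wait becomes `t_1 - d_a` (start-of-anchor reference, where
#' `d_a` is the anchor's hands-on duration) or `t_1` (end-of-anchor), and the
#' wait between consecutive repeats is `t_{k+1} - t_k - d_T` -- the template
#' duration is subtracted so requested time points do not drift later with
#' each repeat. Generated operations are named `"<template_name> @ <t_k>"`.
#'
#' @param protocol a [protocol()].
#' @param request a [time_course_request()].
#' @param template_color optional hex color for the generated operations.
#' @return a new [protocol()] with the expanded operation list.
#' @examples
#' p <- protocol(list(operation("Add 4tU", 1)), samples = paste0("tc_", 1:12))
#' req <- time_course_request(1, "Harvest", 3, c(5, 15, 30, 60))
#' expand_time_course(p, req)
#' @export
expand_time_course <- function(protocol, request, template_color = NULL) {
  stopifnot(inherits(protocol, "lab_protocol"),
            inherits(request, "lab_timecourse_request"))
  if (request$anchor_index > n_ops(protocol)) {
    stop(sprintf("anchor_index %d is out of range: protocol has %d operation(s)",
                 request$anchor_index, n_ops(protocol)), call. = FALSE)
  }
  anchor <- protocol$operations[[request$anchor_index]]
  ref_offset <- if (request$anchor_reference == "start_of_anchor") {
    anchor$duration_mm
  } else 0L
  tp <- request$time_points_mm
  d_t <- request$template_duration_mm
  anchor_wait <- tp[1] - ref_offset
  if (anchor_wait < 0L) {
    stop(sprintf(
      "first time point %s precedes the end of the anchor's hands-on window (%s min): infeasible spacing",
      mmin_format(tp[1]), mmin_format(ref_offset)), call. = FALSE)
  }
  waits <- c(if (length(tp) > 1) diff(tp) - d_t else integer(0), 0L)
  new_anchor <- anchor
  new_anchor$wait_mm <- anchor_wait
  templates <- lapply(seq_along(tp), function(k) {
    o <- operation(sprintf("%s @ %s", request$template_name, mmin_format(tp[k])),
                   duration = 0, wait_after = 0, color = template_color)
    o$duration_mm <- d_t
    o$wait_mm <- waits[k]
    o
  })
  out <- protocol
  out$operations <- c(protocol$operations[seq_len(request$anchor_index - 1)],
                      list(new_anchor), templates)
  out
}

#' @export
print.lab_timecourse_request <- function(x, ...) {
  cat(sprintf("<lab_timecourse_request> '%s' (%s min) at t = %s min after %s of op %d\n",
              x$template_name, mmin_format(x$template_duration_mm),
              paste(mmin_format(x$time_points_mm), collapse = ", "),
              sub("_of_anchor", "", x$anchor_reference), x$anchor_index))
  invisible(x)
}
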