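# Protocol data model: ordered hands-on operations with wait times, a sample
# list, and the scheduling parameters (buffer, granularity, mode).

#' Define a protocol operation
#'
#' One step of a protocol: an action requiring the operator's constant
#' attention for `duration` minutes, followed by `wait_after` minutes of
#' unattended time (an incubation, a spin, ...) before the next step begins.
#'
#' @param name non-empty label for the step.
#' @param duration hands-on duration in minutes (numeric or decimal string).
#' @param wait_after wait time in minutes between the end of this step's
#'   hands-on window and the start of the next step. The final operation's
#'   wait defaults to 0 and is ignored by scheduling.
#' @param color optional hex color string for display (passthrough).
#' @return an object of class `lab_operation`.
#' @examples
#' operation("Add drug", duration = 0.5, wait_after = 60)
#' @export
operation <- function(name, duration, wait_after = 0, color = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.null(color)) stopifnot(is.character(color), length(color) == 1)
  structure(
    list(name = name,
         duration_mm = as_mmin(duration, "duration"),
         wait_mm = as_mmin(wait_after, "wait_after"),
         color = color),
    class = "lab_operation")
}

#' Define a protocol
#'
#' Bundles the ordered operations, the samples to be processed in parallel
#' (each running an identical copy of the protocol), and the scheduling
#' parameters. Content problems (negative times, duplicates, ...) are not
#' rejected here; [validate_protocol()] reports them as findings.
#'
#' @param operations list of [operation()] objects.
#' @param samples character vector of sample names.
#' @param buffer buffer time in minutes appended to every hands-on window to
#'   model task switching (default 1). Another operation may not be scheduled
#'   within `buffer` minutes after the end of any hands-on window.
#' @param granularity lattice spacing, in minutes, of candidate staggering
#'   intervals tested by the optimizer; also the first candidate (default 0.25).
#' @param mode `"automatic"` (search for the minimal interval) or `"manual"`
#'   (evaluate `manual_interval`).
#' @param manual_interval staggering interval in minutes, required when
#'   `mode = "manual"`.
#' @return an object of class `lab_protocol`.
#' @examples
#' p <- protocol(
#'   list(operation("Add drug", 0.5, 60),
#'        operation("Fix", 5, 15),
#'        operation("Quench", 5)),
#'   samples = paste0("well_", 1:12))
#' protocol_span(p)
#' @export
protocol <- function(operations, samples, buffer = 1, granularity = 0.25,
                     mode = c("automatic", "manual"), manual_interval = NULL) {
  if (inherits(operations, "lab_operation")) operations <- list(operations)
  stopifnot(is.list(operations), is.character(samples))
  ok <- vapply(operations, inherits, logical(1), what = "lab_operation")
  if (length(operations) && !all(ok)) {
    stop("operations must be a list of operation() objects", call. = FALSE)
  }
  mode <- match.arg(mode)
  structure(
    list(operations = operations,
         samples = samples,
         buffer_mm = as_mmin(buffer, "buffer"),
         granularity_mm = as_mmin(granularity, "granularity"),
         mode = mode,
         manual_mm = if (is.null(manual_interval)) NA_integer_
                     else as_mmin(manual_interval, "manual_interval")),
    class = "lab_protocol")
}

# exact accessors (integer milliminutes)
op_durations_mm <- function(p) vapply(p$operations, `[[`, integer(1), "duration_mm")
op_waits_mm <- function(p) vapply(p$operations, `[[`, integer(1), "wait_mm")
op_names <- function(p) vapply(p$operations, `[[`, character(1), "name")
op_colors <- function(p) vapply(p$operations, function(o) {
  if (is.null(o$color)) NA_character_ else o$color
}, character(1))
n_ops <- function(p) length(p$operations)
n_samples <- function(p) length(p$samples)

#' Validate a protocol
#'
#' Checks the protocol content and returns findings instead of throwing:
#' errors make the protocol unschedulable, warnings flag suspicious but
#' workable inputs. A wait shorter than the buffer (for any non-final step)
#' is warned about because the operator cannot honor the switching margin
#' within a single sample's own protocol; such overlaps occur at every
#' staggering interval and are therefore not treated as interval conflicts.
#'
#' @param spec a [protocol()].
#' @return data frame with columns `severity` (`"error"`/`"warning"`),
#'   `field`, `message`. Zero rows means a clean protocol.
#' @export
validate_protocol <- function(spec) {
  stopifnot(inherits(spec, "lab_protocol"))
  f <- list()
  add <- function(severity, field, message) {
    f[[length(f) + 1]] <<- data.frame(severity = severity, field = field,
                                      message = message)
  }
  if (n_ops(spec) == 0) add("error", "operations", "protocol has no operations")
  if (n_samples(spec) == 0) add("error", "samples", "protocol has no samples")
  if (anyDuplicated(spec$samples)) {
    add("error", "samples", "duplicate sample names")
  }
  if (any(!nzchar(spec$samples))) add("error", "samples", "empty sample name")
  for (i in seq_len(n_ops(spec))) {
    o <- spec$operations[[i]]
    if (!nzchar(o$name)) add("error", sprintf("operations[%d]", i), "empty operation name")
    if (o$duration_mm < 0L) {
      add("error", sprintf("operations[%d]", i),
          sprintf("negative duration for '%s'", o$name))
    }
    if (o$wait_mm < 0L) {
      add("error", sprintf("operations[%d]", i),
          sprintf("negative wait_after for '%s'", o$name))
    }
    if (o$duration_mm == 0L) {
      add("warning", sprintf("operations[%d]", i),
          sprintf("operation '%s' has zero hands-on duration", o$name))
    }
  }
  if (spec$buffer_mm < 0L) add("error", "buffer", "negative buffer time")
  if (spec$granularity_mm <= 0L) add("error", "granularity", "granularity must be > 0")
  if (spec$mode == "manual" && is.na(spec$manual_mm)) {
    add("error", "manual_interval", "manual mode requires a manual_interval")
  }
  if (!is.na(spec$manual_mm) && spec$manual_mm < 0L) {
    add("error", "manual_interval", "negative manual_interval")
  }
  # non-final waits shorter than the buffer: same-sample windows overlap at
  # every interval; surfaced here, not as interval-dependent conflicts
  if (n_ops(spec) > 1 && spec$buffer_mm > 0L) {
    w <- op_waits_mm(spec)
    short <- which(w[-n_ops(spec)] >= 0L & w[-n_ops(spec)] < spec$buffer_mm)
    for (i in short) {
      add("warning", sprintf("operations[%d]", i),
          sprintf("wait_after of '%s' (%s min) is shorter than the buffer (%s min)",
                  spec$operations[[i]]$name,
                  mmin_format(w[i]), mmin_format(spec$buffer_mm)))
    }
  }
  if (length(f) == 0) {
    return(data.frame(severity = character(), field = character(),
                      message = character()))
  }
  do.call(rbind, f)
}

# stop on validation errors; used by operations whose precondition is a
# validated protocol
assert_valid <- function(spec) {
  v <- validate_protocol(spec)
  errs <- v$message[v$severity == "error"]
  if (length(errs)) {
    stop("invalid protocol: ", paste(errs, collapse = "; "), call. = FALSE)
  }
  invisible(spec)
}

protocol_span_mm <- function(spec) {
  if (n_ops(spec) == 0) stop("protocol has no operations", call. = FALSE)
  d <- op_durations_mm(spec)
  w <- op_waits_mm(spec)
  sum(d) + if (length(w) > 1) sum(w[-length(w)]) else 0L
}

#' Protocol span
#'
#' The completion time, in minutes, of a single sample's last hands-on window:
#' the sum of all hands-on durations plus all waits except the final
#' operation's (buffer excluded). This is the base duration of one protocol;
#' the optimizer declares failure once candidate intervals exceed it, since
#' beyond that samples are simply processed sequentially.
#'
#' @param spec a [protocol()].
#' @return numeric minutes.
#' @export
protocol_span <- function(spec) {
  stopifnot(inherits(spec, "lab_protocol"))
  mmin_to_min(protocol_span_mm(spec))
}

#' @export
print.lab_protocol <- function(x, ...) {
  cat(sprintf("<lab_protocol> %d operation(s), %d sample(s)\n",
              n_ops(x), n_samples(x)))
  if (n_ops(x)) {
    d <- mmin_format(op_durations_mm(x))
    w <- mmin_format(op_waits_mm(x))
    for (i in seq_len(n_ops(x))) {
      cat(sprintf("  %2d. %-28s hands-on %s min, wait %s min\n",
                  i, op_names(x)[i], d[i], w[i]))
    }
  }
  cat(sprintf("  buffer %s min, granularity %s min, mode %s",
              mmin_format(x$buffer_mm), mmin_format(x$granularity_mm), x$mode))
  if (!is.na(x$manual_mm)) cat(sprintf(", manual interval %s min", mmin_format(x$manual_mm)))
  cat("\n")
  invisible(x)
}

#' @export
print.lab_operation <- function(x, ...) {
  cat(sprintf("<lab_operation> %s: hands-on %s min, wait %s min\n",
              x$name, mmin_format(x$duration_mm), mmin_format(x$wait_mm)))
  invisible(x)
}
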