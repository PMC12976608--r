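# Versioned JSON session documents.
#
# A session is the serializable form of a full planning session: the protocol
# plus display options. Times serialize as canonical decimal-minute strings
# ("0.25", "85.5") rather than JSON numbers so that round trips are exact for
# any input with <= 3 decimal places, and save -> load -> save is
# byte-identical.

SESSION_SCHEMA_VERSION <- 1L

#' Create a session document
#'
#' @param protocol a [protocol()].
#' @param base_color optional hex color from which per-sample display colors
#'   are derived by deterministic hue rotation.
#' @param x_tick optional Gantt x-axis tick interval in minutes.
#' @return an object of class `lab_session`.
#' @seealso [save_session()], [load_session()]
#' @export
session <- function(protocol, base_color = NULL, x_tick = NULL) {
  stopifnot(inherits(protocol, "lab_protocol"))
  if (!is.null(base_color)) stopifnot(is.character(base_color), length(base_color) == 1)
  structure(
    list(schema_version = SESSION_SCHEMA_VERSION,
         protocol = protocol,
         base_color = base_color,
         x_tick_mm = if (is.null(x_tick)) NA_integer_ else as_mmin(x_tick, "x_tick")),
    class = "lab_session")
}

#' Serialize a session document to canonical JSON
#'
#' Canonical form: fixed key order, two-space indentation, durations as
#' decimal-minute strings, explicit `null` for absent optional fields.
#'
#' @param doc a [session()].
#' @return a single JSON string (no trailing newline).
#' @export
session_json <- function(doc) {
  stopifnot(inherits(doc, "lab_session"))
  p <- doc$protocol
  ops <- lapply(p$operations, function(o) {
    list(name = jsonlite::unbox(o$name),
         duration = jsonlite::unbox(mmin_format(o$duration_mm)),
         wait_after = jsonlite::unbox(mmin_format(o$wait_mm)),
         color = if (is.null(o$color)) jsonlite::unbox(NA) else jsonlite::unbox(o$color))
  })
  body <- list(
    schema_version = jsonlite::unbox(doc$schema_version),
    protocol = list(
      samples = p$samples,
      operations = ops,
      buffer = jsonlite::unbox(mmin_format(p$buffer_mm)),
      granularity = jsonlite::unbox(mmin_format(p$granularity_mm)),
      mode = jsonlite::unbox(p$mode),
      manual_interval = if (is.na(p$manual_mm)) jsonlite::unbox(NA)
                        else jsonlite::unbox(mmin_format(p$manual_mm))),
    display = list(
      base_color = if (is.null(doc$base_color)) jsonlite::unbox(NA) else jsonlite::unbox(doc$base_color),
      x_tick = if (is.na(doc$x_tick_mm)) jsonlite::unbox(NA)
               else jsonlite::unbox(mmin_format(doc$x_tick_mm))))
  as.character(jsonlite::toJSON(body, pretty = 2, na = "null"))
}

#' Save a session document as JSON
#'
#' @param doc a [session()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
save_session <- function(doc, path) {
  writeLines(session_json(doc), path, useBytes = TRUE)
  invisible(path)
}

#' Load a session document from JSON
#'
#' Rejects documents whose `schema_version` is not 1 and documents carrying
#' unknown keys (a forward-compatibility guard: a newer schema is reported as
#' a versioning problem, not silently mis-read).
#'
#' @param path source file path, or a JSON string.
#' @return an object of class `lab_session`.
#' @export
load_session <- function(path) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("failed to parse session JSON: ", conditionMessage(e), call. = FALSE)
    })
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop(sprintf("unknown %s key(s) %s: not a schema_version %d session",
                   where, paste(sQuote(unknown), collapse = ", "),
                   SESSION_SCHEMA_VERSION),
           call. = FALSE)
    }
  }
  check_keys(raw, c("schema_version", "protocol", "display"), "top-level")
  if (is.null(raw$schema_version) || !identical(as.numeric(raw$schema_version), 1)) {
    stop("unsupported session schema_version: ",
         if (is.null(raw$schema_version)) "missing" else raw$schema_version,
         " (this build reads version ", SESSION_SCHEMA_VERSION, ")",
         call. = FALSE)
  }
  pr <- raw$protocol
  if (is.null(pr)) stop("session is missing the 'protocol' object", call. = FALSE)
  check_keys(pr, c("samples", "operations", "buffer", "granularity", "mode",
                   "manual_interval"), "protocol")
  check_keys(raw$display, c("base_color", "x_tick"), "display")
  ops <- lapply(pr$operations, function(o) {
    check_keys(o, c("name", "duration", "wait_after", "color"), "operation")
    operation(name = o$name, duration = o$duration,
              wait_after = if (is.null(o$wait_after)) "0" else o$wait_after,
              color = o$color)
  })
  p <- protocol(
    operations = ops,
    samples = vapply(pr$samples, as.character, character(1)),
    buffer = if (is.null(pr$buffer)) 1 else pr$buffer,
    granularity = if (is.null(pr$granularity)) 0.25 else pr$granularity,
    mode = if (is.null(pr$mode)) "automatic" else pr$mode,
    manual_interval = pr$manual_interval)
  session(p,
          base_color = raw$display$base_color,
          x_tick = raw$display$x_tick)
}

#' @export
print.lab_session <- function(x, ...) {
  cat(sprintf("<lab_session> schema_version %d\n", x$schema_version))
  print(x$protocol)
  invisible(x)
}
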