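# Exportable report bundle: session + both schedule tables + Gantt SVG +
# text summary, zipped reproducibly.

csv_field <- function(x) {
  needs <- grepl('[",\r\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

# RFC 4180 CSV: header row, CRLF line endings, times already formatted as
# decimal-minute strings by the caller
csv_text <- function(df) {
  header <- paste(csv_field(names(df)), collapse = ",")
  cols <- lapply(df, function(col) csv_field(as.character(col)))
  rows <- do.call(paste, c(cols, sep = ","))
  paste0(paste(c(header, rows), collapse = "\r\n"), "\r\n")
}

by_time_csv <- function(schedule) {
  bt <- schedule_by_time(schedule)
  csv_text(data.frame(clock_time = mmin_format(bt$clock_time_mm),
                      sample = bt$sample,
                      operation = bt$operation,
                      duration = mmin_format(bt$duration_mm),
                      stringsAsFactors = FALSE))
}

by_sample_csv <- function(schedule) {
  bs <- schedule_by_sample(schedule)
  for (k in seq_along(bs)[-1]) bs[[k]] <- mmin_format(round(bs[[k]] * 1000))
  csv_text(bs)
}

report_summary <- function(doc, result) {
  p <- doc$protocol
  lines <- c(
    "Staggered protocol scheduling report",
    "",
    sprintf("Samples: %d", n_samples(p)),
    sprintf("Operations: %d", n_ops(p)),
    sprintf("Protocol span: %s min", mmin_format(protocol_span_mm(p))),
    sprintf("Buffer: %s min", mmin_format(p$buffer_mm)),
    sprintf("Granularity: %s min", mmin_format(p$granularity_mm)))
  if (inherits(result, "lab_optimization")) {
    lines <- c(lines, sprintf("Mode: automatic (status: %s)", result$status))
    if (result$status != "failed") {
      lines <- c(lines,
        sprintf("Staggering interval: %s min", mmin_format(result$interval_mm)),
        sprintf("Candidates tested: %d", max(nrow(result$tested), 1L)))
    } else {
      lines <- c(lines, sprintf(
        "No conflict-free interval found on the granularity lattice up to the protocol span (%d candidates tested)",
        nrow(result$tested)))
    }
  } else {
    n_cross <- nrow(cross_sample_conflicts(result$conflicts))
    lines <- c(lines,
      sprintf("Mode: manual (interval %s min)", mmin_format(result$interval_mm)),
      sprintf("Valid: %s", if (result$valid) "yes" else "no"),
      sprintf("Cross-sample conflicts: %d", n_cross))
  }
  sched <- result$schedule
  if (!is.null(sched)) {
    lines <- c(lines, sprintf("Last hands-on window ends at: %s min",
                              mmin_format(max(sched$hands_on_end_mm))))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Export a report archive
#'
#' Writes a ZIP archive with exactly five members -- `session.json`,
#' `schedule_by_time.csv`, `schedule_by_sample.csv`, `gantt.svg`,
#' `summary.txt` -- for record keeping and sharing. Member timestamps are
#' zeroed and entries are stored deterministically, so exporting the same
#' session and result twice yields byte-identical archives.
#'
#' @param doc the [session()] the result was computed from.
#' @param result a `lab_optimization` (found/trivial) or `lab_manual_eval`.
#' @param path destination `.zip` path.
#' @return `path`, invisibly.
#' @export
export_report <- function(doc, result, path) {
  stopifnot(inherits(doc, "lab_session"),
            inherits(result, "lab_optimization") || inherits(result, "lab_manual_eval"))
  if (inherits(result, "lab_optimization") && result$status == "failed") {
    stop("cannot export a failed optimization: no schedule to report", call. = FALSE)
  }
  layout <- gantt_layout(result,
                         base_color = if (is.null(doc$base_color)) "#4C78A8" else doc$base_color,
                         x_tick = if (is.na(doc$x_tick_mm)) NULL else mmin_to_min(doc$x_tick_mm))
  sched <- result$schedule
  write_zip(path, list(
    "session.json" = paste0(session_json(doc), "\n"),
    "schedule_by_time.csv" = by_time_csv(sched),
    "schedule_by_sample.csv" = by_sample_csv(sched),
    "gantt.svg" = paste0(gantt_svg(layout), "\n"),
    "summary.txt" = report_summary(doc, result)))
  invisible(path)
}
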