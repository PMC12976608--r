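# Result views: chronological schedule, per-sample start-time table, and the
# Gantt layout with its aggregated "Hands-On Time" row.

#' Chronological schedule view
#'
#' Every task instance as a time-stamped row, sorted by clock time (minutes
#' from the first sample's first operation) with ties broken by sample then
#' operation order -- the list an operator works down during execution.
#'
#' @param schedule a `lab_schedule` from [expand_schedule()].
#' @return data frame with `clock_time`, `sample`, `operation`, `duration`
#'   (minutes) plus exact `clock_time_mm`/`duration_mm`.
#' @export
schedule_by_time <- function(schedule) {
  stopifnot(inherits(schedule, "lab_schedule"))
  ord <- order(schedule$start_mm, schedule$sample_index, schedule$op_index)
  x <- as.data.frame(schedule)[ord, , drop = FALSE]
  out <- data.frame(clock_time = x$start,
                    sample = x$sample,
                    operation = x$operation,
                    duration = x$hands_on_end - x$start,
                    clock_time_mm = x$start_mm,
                    duration_mm = x$hands_on_end_mm - x$start_mm,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-sample start-time table
#'
#' One row per sample, one column per operation; cell (j, k) is the start
#' time in minutes of operation k for sample j. Consecutive rows differ by
#' exactly the staggering interval in every column.
#'
#' @param schedule a `lab_schedule`.
#' @return data frame whose first column is `sample`, followed by one numeric
#'   column per operation.
#' @export
schedule_by_sample <- function(schedule) {
  stopifnot(inherits(schedule, "lab_schedule"))
  p <- schedule_protocol(schedule)
  K <- n_ops(p)
  starts <- matrix(schedule$start[order(schedule$sample_index, schedule$op_index)],
                   ncol = K, byrow = TRUE)
  out <- data.frame(sample = p$samples, starts, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- c("sample", op_names(p))
  out
}

# deterministic hue rotation around a base color; used for default operation
# colors when the data model carries none
palette_rotate <- function(base, k) {
  if (k == 0) return(character(0))
  rgb <- grDevices::col2rgb(base) / 255
  hsv <- grDevices::rgb2hsv(rgb[1] * 255, rgb[2] * 255, rgb[3] * 255)
  h <- (hsv[1] + (seq_len(k) - 1) / max(k, 1)) %% 1
  grDevices::hsv(h, pmax(hsv[2], 0.35), pmax(hsv[3], 0.55))
}

CONFLICT_COLOR <- "#D62728"   # red family
BUFFER_COLOR <- "#BBBBBB"
BUSY_COLOR <- "#555555"

# choose a tick step giving <= 16 ticks from a conventional ladder
auto_tick_mm <- function(horizon_mm) {
  ladder <- c(250, 500, 1000, 2000, 5000, 10000, 15000, 30000, 60000,
              120000, 240000, 480000)
  for (t in ladder) if (horizon_mm / t <= 16) return(t)
  ceiling(horizon_mm / 16 / 60000) * 60000
}

#' Build a Gantt layout
#'
#' Assembles the drawable form of a schedule: one row per sample carrying its
#' hands-on and buffer bars, plus an aggregated "Hands-On Time" row whose
#' bars are the busy and conflict segments of [occupancy_track()]. When
#' built from an invalid manual evaluation the subtitle carries the exact
#' warning string `"WARNING: <N> conflicts at interval <X>"` (N = number of
#' cross-sample conflicting pairs, X = interval in minutes).
#'
#' @param x a `lab_optimization`, `lab_manual_eval`, or `lab_schedule`.
#' @param base_color base color for the default operation palette.
#' @param x_tick x-axis tick interval in minutes (`NULL` = automatic).
#' @return an object of class `lab_gantt_layout`: list with `rows` (labels,
#'   samples first, then `"Hands-On Time"`), `bars` (data frame: `row`,
#'   `row_label`, `start`, `end`, `label`, `color`,
#'   `kind` in hands_on/buffer/conflict), `subtitle`, `title`, `x_ticks`.
#' @export
gantt_layout <- function(x, base_color = "#4C78A8", x_tick = NULL) {
  if (inherits(x, "lab_optimization")) {
    if (x$status == "failed") {
      stop("cannot lay out a failed optimization: no schedule", call. = FALSE)
    }
    schedule <- x$schedule
    subtitle <- sprintf("Optimized staggering interval: %s min",
                        mmin_format(x$interval_mm))
  } else if (inherits(x, "lab_manual_eval")) {
    schedule <- x$schedule
    n_cross <- nrow(cross_sample_conflicts(x$conflicts))
    subtitle <- if (x$valid) {
      sprintf("Manual staggering interval: %s min (valid)",
              mmin_format(x$interval_mm))
    } else {
      sprintf("WARNING: %d conflicts at interval %s", n_cross,
              mmin_format(x$interval_mm))
    }
  } else if (inherits(x, "lab_schedule")) {
    schedule <- x
    subtitle <- sprintf("Staggering interval: %s min",
                        mmin_format(schedule_interval_mm(x)))
  } else {
    stop("x must be a lab_optimization, lab_manual_eval or lab_schedule",
         call. = FALSE)
  }
  p <- schedule_protocol(schedule)
  cols <- op_colors(p)
  auto <- palette_rotate(base_color, n_ops(p))
  cols[is.na(cols)] <- auto[is.na(cols)]
  rows <- c(p$samples, "Hands-On Time")
  bars <- list()
  for (j in seq_len(n_samples(p))) {
    inst <- schedule[schedule$sample_index == j - 1L, , drop = FALSE]
    inst <- inst[order(inst$op_index), , drop = FALSE]
    bars[[length(bars) + 1]] <- data.frame(
      row = j, row_label = p$samples[j],
      start = inst$start, end = inst$hands_on_end,
      label = inst$operation, color = cols[inst$op_index + 1L],
      kind = "hands_on", stringsAsFactors = FALSE)
    has_buf <- inst$busy_end_mm > inst$hands_on_end_mm
    if (any(has_buf)) {
      bars[[length(bars) + 1]] <- data.frame(
        row = j, row_label = p$samples[j],
        start = inst$hands_on_end[has_buf], end = inst$busy_end[has_buf],
        label = "buffer", color = BUFFER_COLOR,
        kind = "buffer", stringsAsFactors = FALSE)
    }
  }
  occ <- occupancy_track(schedule)
  occ <- occ[occ$multiplicity >= 1L, , drop = FALSE]
  if (nrow(occ)) {
    conflict <- occ$multiplicity >= 2L
    bars[[length(bars) + 1]] <- data.frame(
      row = length(rows), row_label = "Hands-On Time",
      start = occ$start, end = occ$end,
      label = ifelse(conflict, "conflict", "busy"),
      color = ifelse(conflict, CONFLICT_COLOR, BUSY_COLOR),
      kind = ifelse(conflict, "conflict", "hands_on"),
      stringsAsFactors = FALSE)
  }
  bars <- do.call(rbind, bars)
  rownames(bars) <- NULL
  horizon_mm <- max(schedule$busy_end_mm, 1)
  tick_mm <- if (is.null(x_tick)) auto_tick_mm(horizon_mm) else as_mmin(x_tick, "x_tick")
  ticks <- seq(0, horizon_mm + tick_mm - 1, by = tick_mm)
  structure(
    list(rows = rows,
         bars = bars,
         subtitle = subtitle,
         title = sprintf("Staggered schedule: %d sample(s) x %d operation(s)",
                         n_samples(p), n_ops(p)),
         x_ticks = mmin_to_min(ticks),
         horizon = mmin_to_min(horizon_mm)),
    class = "lab_gantt_layout")
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

gantt_svg <- function(layout, width = 960) {
  stopifnot(inherits(layout, "lab_gantt_layout"))
  left <- 140; top <- 64; row_h <- 26; bar_h <- 18; bottom <- 40
  n_rows <- length(layout$rows)
  height <- top + n_rows * row_h + bottom
  plot_w <- width - left - 20
  xmax <- max(layout$horizon, max(layout$x_ticks), 1e-9)
  xpix <- function(t) left + t / xmax * plot_w
  fmt <- function(v) sprintf("%.2f", v)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="sans-serif">',
            as.integer(width), as.integer(height)),
    sprintf('<text x="%s" y="22" font-size="16" font-weight="bold">%s</text>',
            fmt(left), xml_escape(layout$title)),
    sprintf('<text x="%s" y="42" font-size="13"%s>%s</text>',
            fmt(left),
            if (startsWith(layout$subtitle, "WARNING")) sprintf(' fill="%s"', CONFLICT_COLOR) else "",
            xml_escape(layout$subtitle)))
  for (i in seq_along(layout$x_ticks)) {
    t <- layout$x_ticks[i]
    out <- c(out,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#DDDDDD" stroke-width="1"/>',
              fmt(xpix(t)), fmt(top - 6), fmt(xpix(t)), fmt(top + n_rows * row_h)),
      sprintf('<text x="%s" y="%s" font-size="10" text-anchor="middle">%s</text>',
              fmt(xpix(t)), fmt(top + n_rows * row_h + 14), mmin_format(round(t * 1000))))
  }
  for (r in seq_len(n_rows)) {
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="11" text-anchor="end">%s</text>',
      fmt(left - 8), fmt(top + (r - 0.5) * row_h + 4), xml_escape(layout$rows[r])))
  }
  b <- layout$bars
  for (i in seq_len(nrow(b))) {
    y <- top + (b$row[i] - 1) * row_h + (row_h - bar_h) / 2
    out <- c(out, sprintf(
      '<rect class="bar %s" x="%s" y="%s" width="%s" height="%s" fill="%s"><title>%s [%s, %s]</title></rect>',
      b$kind[i], fmt(xpix(b$start[i])), fmt(y),
      fmt(max(xpix(b$end[i]) - xpix(b$start[i]), 0.5)), fmt(bar_h),
      b$color[i], xml_escape(b$label[i]),
      mmin_format(round(b$start[i] * 1000)), mmin_format(round(b$end[i] * 1000))))
  }
  out <- c(out,
    sprintf('<text x="%s" y="%s" font-size="11">Time (min)</text>',
            fmt(left + plot_w / 2 - 26), fmt(height - 8)),
    '</svg>')
  paste(out, collapse = "\n")
}

#' Render a Gantt layout to an image file
#'
#' SVG output is generated directly and is byte-identical for identical
#' layouts; PNG goes through the graphics device.
#'
#' @param layout a `lab_gantt_layout` from [gantt_layout()].
#' @param path output file path.
#' @param format `"svg"` or `"png"`.
#' @param width image width in pixels.
#' @return `path`, invisibly.
#' @export
render_gantt <- function(layout, path, format = c("svg", "png"), width = 960) {
  stopifnot(inherits(layout, "lab_gantt_layout"))
  format <- match.arg(format)
  if (format == "svg") {
    writeLines(gantt_svg(layout, width), path, useBytes = TRUE)
  } else {
    render_gantt_png(layout, path, width)
  }
  invisible(path)
}

render_gantt_png <- function(layout, path, width) {
  n_rows <- length(layout$rows)
  height <- 104 + n_rows * 26
  grDevices::png(path, width = width, height = height, res = 96)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(3.2, 9, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  xmax <- max(layout$horizon, max(layout$x_ticks))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(n_rows + 0.5, 0.5),
                 xlab = "", ylab = "", axes = FALSE,
                 main = layout$title)
  graphics::mtext(layout$subtitle, side = 3, line = 0.2, cex = 0.85,
                  col = if (startsWith(layout$subtitle, "WARNING")) CONFLICT_COLOR else "black")
  graphics::axis(1, at = layout$x_ticks, cex.axis = 0.8)
  graphics::mtext("Time (min)", side = 1, line = 2.2, cex = 0.85)
  graphics::axis(2, at = seq_len(n_rows), labels = layout$rows, las = 2,
                 cex.axis = 0.75, tick = FALSE)
  b <- layout$bars
  graphics::rect(b$start, b$row - 0.35, b$end, b$row + 0.35,
                 col = b$color, border = NA)
}

#' @export
print.lab_gantt_layout <- function(x, ...) {
  cat(sprintf("<lab_gantt_layout> %d row(s), %d bar(s); subtitle: %s\n",
              length(x$rows), nrow(x$bars), x$subtitle))
  invisible(x)
}
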