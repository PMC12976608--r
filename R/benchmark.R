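# Benchmark harness: synthetic equal-step protocols parameterized by step
# count and hands-on density, and a sweep runner measuring optimizer wall
# time and peak memory. Timing and memory are reported for trend inspection
# only; they are hardware-dependent and never asserted as quantities.

#' Generate a synthetic benchmark protocol
#'
#' Builds `n_steps` identical operations whose hands-on duration is
#' `density * step_period` and whose wait is `(1 - density) * step_period`,
#' so each step accounts for exactly one period and the scenario's total
#' protocol time is `n_steps * step_period`. The final step keeps its wait
#' for this bookkeeping (scheduling ignores a final wait), so the hands-on
#' fraction of the total time equals `density` exactly.
#'
#' @param n_steps number of operations (>= 1).
#' @param density fraction of each step period that is hands-on, in `[0, 1]`.
#'   `density = 1` saturates the operator: no staggered schedule can exist
#'   for more than one sample.
#' @param n_samples number of samples (default 50).
#' @param granularity optimizer lattice in minutes (default 0.5).
#' @param buffer buffer time in minutes (default 0.25).
#' @param step_period period per step in minutes (default 10).
#' @return a [protocol()].
#' @examples
#' make_benchmark_protocol(5, 0.3)  # five steps: 3 min hands-on, 7 min wait
#' @export
make_benchmark_protocol <- function(n_steps, density, n_samples = 50,
                                    granularity = 0.5, buffer = 0.25,
                                    step_period = 10) {
  stopifnot(n_steps >= 1, n_steps == as.integer(n_steps))
  if (density < 0 || density > 1) {
    stop("density must be in [0, 1]", call. = FALSE)
  }
  period_mm <- as_mmin(step_period, "step_period")
  d_mm <- round(density * period_mm)
  if (abs(density * period_mm - d_mm) > 1e-6) {
    stop("density * step_period is not representable at milliminute resolution",
         call. = FALSE)
  }
  ops <- lapply(seq_len(n_steps), function(i) {
    o <- operation(sprintf("step_%02d", i), duration = 0, wait_after = 0)
    o$duration_mm <- as.integer(d_mm)
    o$wait_mm <- as.integer(period_mm - d_mm)
    o
  })
  protocol(ops, samples = sprintf("sample_%02d", seq_len(n_samples)),
           buffer = buffer, granularity = granularity)
}

peak_rss_mb <- function() {
  status <- "/proc/self/status"
  if (!file.exists(status)) return(NA_real_)
  lines <- readLines(status, warn = FALSE)
  hwm <- grep("^VmHWM:", lines, value = TRUE)
  if (!length(hwm)) return(NA_real_)
  as.numeric(gsub("[^0-9]", "", hwm[1])) / 1024
}

#' Run an optimizer benchmark sweep
#'
#' Runs [find_optimal_interval()] for each scenario (a row of benchmark
#' parameters) `repeats` times, recording the outcome, wall time and peak
#' resident memory.
#'
#' @param scenarios data frame with any of the columns `n_steps`, `density`,
#'   `n_samples`, `granularity`, `buffer`, `step_period`; missing columns
#'   take [make_benchmark_protocol()] defaults.
#' @param repeats repeats per scenario (default 1).
#' @return data frame with one row per (scenario, repeat): the scenario
#'   parameters, `rep`, `status`, `interval` (minutes, `NA` on failure),
#'   `candidates_tested`, `wall_time_s`, `peak_rss_mb`.
#' @export
run_benchmark <- function(scenarios, repeats = 1) {
  stopifnot(is.data.frame(scenarios), nrow(scenarios) >= 1, repeats >= 1)
  defaults <- list(n_steps = 5, density = 0.5, n_samples = 50,
                   granularity = 0.5, buffer = 0.25, step_period = 10)
  for (nm in names(defaults)) {
    if (is.null(scenarios[[nm]])) scenarios[[nm]] <- defaults[[nm]]
  }
  rows <- list()
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, , drop = FALSE]
    p <- make_benchmark_protocol(sc$n_steps, sc$density, sc$n_samples,
                                 sc$granularity, sc$buffer, sc$step_period)
    for (r in seq_len(repeats)) {
      t0 <- proc.time()[["elapsed"]]
      res <- find_optimal_interval(p)
      dt <- proc.time()[["elapsed"]] - t0
      rows[[length(rows) + 1]] <- data.frame(
        n_steps = sc$n_steps, density = sc$density, n_samples = sc$n_samples,
        granularity = sc$granularity, buffer = sc$buffer,
        step_period = sc$step_period, rep = r,
        status = res$status,
        interval = res$interval,
        candidates_tested = nrow(res$tested),
        wall_time_s = dt,
        peak_rss_mb = peak_rss_mb())
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
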