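# Random protocol generator for property tests and stress runs. Draws all
# times on a lattice (default 0.25 min) so generated values are exactly
# representable and conflict boundaries land on interesting coincidences.

#' Generate a random protocol
#'
#' Durations and waits are `lattice` multiples drawn uniformly up to the
#' given maxima; zero durations and waits are allowed (and occur) to exercise
#' degenerate windows. Uses the current R RNG state: seed with
#' [set.seed()] for reproducibility.
#'
#' @param max_ops,max_samples upper bounds for the uniformly drawn operation
#'   and sample counts (at least 1 of each).
#' @param lattice time lattice in minutes (default 0.25).
#' @param max_duration,max_wait maxima, in minutes, for hands-on durations
#'   and waits.
#' @param buffer buffer time in minutes; the default draws a lattice value
#'   in `[0, 2]`.
#' @param granularity optimizer granularity in minutes (default `lattice`).
#' @return a [protocol()].
#' @export
random_protocol <- function(max_ops = 5, max_samples = 6, lattice = 0.25,
                            max_duration = 5, max_wait = 10,
                            buffer = NULL, granularity = lattice) {
  lat_mm <- as_mmin(lattice, "lattice")
  stopifnot(lat_mm > 0)
  draw <- function(max_min) {
    steps <- as_mmin(max_min, "max") %/% lat_mm
    sample.int(steps + 1L, 1L) - 1L  # 0..steps lattice units
  }
  K <- sample.int(max_ops, 1)
  n <- sample.int(max_samples, 1)
  ops <- lapply(seq_len(K), function(i) {
    o <- operation(sprintf("op_%02d", i), duration = 0, wait_after = 0)
    o$duration_mm <- as.integer(draw(max_duration) * lat_mm)
    o$wait_mm <- if (i < K) as.integer(draw(max_wait) * lat_mm) else 0L
    o
  })
  b <- if (is.null(buffer)) mmin_to_min(draw(2) * lat_mm) else buffer
  protocol(ops, samples = sprintf("s%02d", seq_len(n)),
           buffer = b, granularity = granularity)
}
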