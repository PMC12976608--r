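---
title: "Staggered protocol scheduling: model, optimizer and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staggered protocol scheduling: model, optimizer and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labsched)
```

## The scheduling problem

Time-sensitive bench work — fixation, metabolic labeling, drug time courses —
is usually run on several samples in parallel by staggering: sample 2 starts
a fixed interval $\Delta$ after sample 1, sample 3 after sample 2, and so on,
so that one sample's incubations absorb another sample's hands-on steps.
Every sample runs the *same* protocol: an ordered list of operations $i = 1,
\dots, K$, each with a hands-on duration $d_i$ (the operator is occupied) and
a wait $w_i$ to the next operation (the operator is free). This is a
single-machine instance of the permutation flow-shop family, with the
experimentalist as the machine.

A staggering interval is *valid* when the operator is never needed in two
places at once. Too short an interval creates collisions; too long an
interval wastes the day. The package computes the minimal valid interval on
a user-chosen lattice, or evaluates an interval the user proposes.

## Occupancy model

Operation $i$ of sample $j$ (both 0-based in the formulas, 1-based in the R
API) starts at

$$ s_{ji} = j\,\Delta + \sum_{k < i} (d_k + w_k), $$

occupies the operator over the *busy window* $[s_{ji},\, s_{ji} + d_i + b)$,
where $b$ is a flat **buffer** appended to every hands-on window to absorb
task switching and human imprecision (default 1 min). A **conflict** is a
positive-length intersection of two busy windows. Three modelling choices
matter:

* **Half-open windows.** One operation may begin at the exact instant
  another's buffered window closes. With exact arithmetic this makes the
  "touching windows" case unambiguous.
* **The buffer occupies, it does not delay.** Waits run from the hands-on
  end, so the buffer widens the occupied window without shifting the
  sample's own later operations. The alternative convention (waits from the
  buffered end) is available as `expand_schedule(..., buffer_policy =
  "shift")` for robustness checks; it lengthens the protocol by $b$ per
  step.
* **Same-sample overlaps are protocol warnings, not conflicts.** If some
  $w_i < b$ the sample overlaps *itself* at every $\Delta$; treating that as
  a conflict would make every interval invalid, so `validate_protocol()`
  flags it once instead (for non-final operations; the final wait is ignored
  by scheduling).

All times are held as integer milliminutes (1/1000 min). Every comparison in
conflict detection is integer-exact; no floating-point tolerance appears
anywhere in the scheduling logic, and serialization uses decimal-minute
strings so session files round-trip byte-for-byte for inputs with up to
three decimal places.

`detect_conflicts()` is a sweep over instances sorted by start time with an
active window set. An earlier design sampled the timeline at granularity
steps; exact interval intersection is strictly stronger (a sub-granularity
overlap cannot slip between grid points) and faster. The independent
all-pairs oracle `brute_force_valid()` retains the naive double loop
precisely so the two routes share no code; the test suite holds them equal
on thousands of random instances.

## The optimizer

`find_optimal_interval()` tests $\Delta \in \{g, 2g, 3g, \dots\}$, where the
**granularity** $g$ (default 0.25 min) is both the first candidate and the
increment, and returns the first conflict-free candidate. The scan stops and
reports failure once the next candidate would exceed the protocol span

$$ P = \sum_i d_i + \sum_{i < K} w_i, $$

the completion time of a single sample's last hands-on window ($\Delta = P$
itself is still tested). $P + b$ is always valid — consecutive samples'
busy spans become disjoint — so failure means the minimal valid interval, if
one exists on the lattice, exceeds the span of one protocol and staggering
has lost its point.

Two deliberate choices:

* **Linear scan, not bisection.** Validity is not monotone in $\Delta$:
  enlarging the interval can slide a later operation of one sample into an
  earlier operation of another. First-hit scanning over the lattice is the
  only correct minimality procedure on this structure, and for lab-scale
  problems it is fast (the bundled examples optimize in well under a
  second).
* **$n = 1$ returns interval 0 with status `"trivial"`** rather than $g$: an
  offset between samples is meaningless with one sample, and 0 communicates
  that.

A coarser lattice can only produce an equal or larger interval (or a
failure); the suite asserts this coarsening property, e.g. between $g$ and
$5g$.

## Time Course Helper

`expand_time_course()` converts "repeat operation T at $t_1 < \dots < t_K$
minutes after the anchor" into concrete operations. With the default
`start_of_anchor` reference the requested points are measured from the
moment the anchor's hands-on window *begins* — the natural reading of
"harvest 5 min after label addition" — so the anchor's wait becomes $t_1 -
d_a$ and the wait between repeats $t_{k+1} - t_k - d_T$. Subtracting the
template duration $d_T$ is essential: without it each repeat drifts
$k \cdot d_T$ later than requested. `end_of_anchor` is kept as an option
because either convention is defensible when the anchor itself takes
appreciable time; the two change the computed waits, and hence optimal
intervals, whenever $d_a > 0$. Requests whose spacing would need a negative
wait ($t_{k+1} - t_k < d_T$, or $t_1 < d_a$) are rejected naming the
offending pair. The expansion replaces any operations after the anchor,
since the generated series *is* the tail of the protocol.

## Outputs and reproducibility

Three views are derived from a solved schedule: the Gantt layout (one row
per sample plus an aggregated "Hands-On Time" row whose segments come from
the sweep-line `occupancy_track()` — free, busy, or conflict when
multiplicity $\ge 2$), the chronological `schedule_by_time()` table (sorted
by clock time, ties broken by sample then operation order), and the
`schedule_by_sample()` start-time matrix. Invalid manual schedules carry the
exact subtitle `"WARNING: N conflicts at interval X"`, which is part of the
CLI contract.

SVG Gantt output is generated directly as text, so identical layouts render
byte-identically; PNG goes through the graphics device. `export_report()`
writes a five-member ZIP (session, both CSV tables, SVG, text summary)
through an internal stored-entry ZIP writer with member timestamps pinned to
the DOS epoch, making archives byte-reproducible; CSVs are RFC 4180 with
times as decimal-minute strings. The session JSON schema (version 1, field
layout documented in `?session_json`) is this package's own; unknown keys
are rejected as a versioning error rather than silently dropped, so a
future schema cannot be mis-read as the current one.

## Live execution

`live_status()` is a pure function of the schedule and the elapsed time:
instances with `start <= now < hands_on_end` are current, the earliest
instance with `start > now` drives the countdown, ties break by sample then
operation. The wall clock is always injected by the caller — the CLI `run`
loop passes `Sys.time()` once per second — so the classification logic is
deterministic and fully tested; the refresh loop itself is untested display
glue. No re-planning is attempted when the operator falls behind.

## Synthetic benchmark protocols

`make_benchmark_protocol(n_steps, density)` builds equal steps on a 10-min
period: hands-on $= \text{density} \times 10$ min, wait $= (1 -
\text{density}) \times 10$ min, with defaults of 50 samples, 0.5-min
granularity and 0.25-min buffer. The final step keeps its wait so the
scenario's total time is exactly `n_steps * step_period` and the hands-on
fraction equals the density exactly (scheduling ignores a final wait; the
constant is bookkeeping and is pinned by a unit test). `density = 1`
saturates the operator — no positive interval up to the span can avoid
overlap for two or more samples — and the optimizer must fail, which the
suite asserts. `run_benchmark()` sweeps scenario grids and records wall
time and peak resident memory (read from `/proc/self/status`, `NA`
elsewhere); these are reported for trend inspection only and never asserted
as values, since they are hardware-dependent. The qualitative trends the
suite does assert — runtime grows as granularity shrinks and as step count
grows — are checked at a reduced scale (20 samples, granularity down to
0.25 min, up to 10 steps), sized so the heavier search does several times
the work of the lighter one.

## What the random-protocol generator does and does not emulate

`random_protocol()` draws operation counts, sample counts, durations, waits
and buffers on a 0.25-min lattice, including zero durations and zero waits,
so boundary coincidences (touching windows, saturated stretches) occur
often. It emulates the combinatorics of small lab protocols, not their
semantics: real protocols have correlated structure (long incubations after
quick additions), non-lattice execution times, and operator variability
beyond a flat buffer. Passing the property suite therefore demonstrates the
*scheduling algebra* is exact and minimal on the lattice, not that a given
wet-lab plan is robust; the buffer parameter is the user's instrument for
the latter.

## Worked example

The bundled fixation session: 12 coverslips, each receiving a 0.5-min drug
addition, a 60-min incubation, a 5-min fixation start, a 15-min fixation,
and a 5-min fixation halt, with a 1-min buffer and 0.25-min granularity.

```{r usecase1}
doc <- load_session(system.file("extdata", "fixation_parallel.json",
                                package = "labsched"))
protocol_span(doc$protocol)
res <- find_optimal_interval(doc$protocol, verify = TRUE)
res
head(schedule_by_time(res$schedule), 4)
```

A 6-min stagger, by contrast, collides — under either buffer convention:

```{r usecase1-manual}
manual <- doc$protocol
manual$mode <- "manual"
manual$manual_mm <- 6000L
ev <- evaluate_manual_interval(manual)
ev
gantt_layout(ev)$subtitle
```

## Known limitations

* One operator, identical protocols, one shared interval: heterogeneous
  per-sample protocols, multiple operators and per-operation assignment are
  out of scope, as are metaheuristic searches (GA, simulated annealing,
  tabu) over richer schedule spaces.
* Minimality is relative to the granularity lattice; a finer optimum
  between lattice points is deliberately not chased.
* The live runner tracks the plan; it does not re-plan around a late
  operator.
* Reported benchmark wall times and memory are environment-specific trend
  data, not reproducible quantities.
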