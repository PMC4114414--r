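---
title: "GPS-based Lifespace: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GPS-based Lifespace: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifespace)
```

## The problem

Lifespace is the geographic area in which a person lives and conducts their
activities; it shrinks with declining mobility and health and is therefore a
candidate outcome measure for progressive movement disorders such as
Parkinson's disease. Traditional life-space instruments are self-report
questionnaires. This package instead derives Lifespace from passively
recorded smartphone GPS traces: timestamped latitude/longitude fixes
collected in daily charge-cycle sessions of a few hours, over a study period
of weeks.

From each participant's trace the package computes four per-participant
metrics: the furthest distance travelled from home, the mean daily distance,
the percentage of recorded time spent at home, and the frequency of trips
into the community (per week). Groups are compared nonparametrically, and
participants can be ordered by symptom severity to inspect
Lifespace-severity trends.

## The processing model

### Distance

All distances are great-circle distances on a sphere via the haversine
formula,
$$ d = 2R \arcsin \sqrt{\sin^2\!\tfrac{\Delta\phi}{2} +
  \cos\phi_1 \cos\phi_2 \sin^2\!\tfrac{\Delta\lambda}{2}}, $$
with $R$ the IUGG mean Earth radius, 6371.0088 km (configurable; the choice
of spherical over ellipsoidal geodesy is immaterial at the analysis'
500 m resolution). Inputs and outputs are decimal degrees (WGS84) and
kilometers; conversion to radians is internal.

### Sessions and days

Recording is intermittent by design (one charge cycle per day), so a trace
is segmented into sessions: a new session starts whenever the gap between
consecutive fixes is *strictly greater* than `session_gap_s` (default
300 s — the stream is nominally 1 Hz to 0.1 Hz, so any gap well beyond
that means the device was off, while 5 min tolerates brief GPS dropouts; a
boundary gap exactly at the threshold does not split). All time-based
quantities are sums over *within-session* consecutive-fix intervals; gaps
between sessions contribute nothing to any numerator or denominator.
Calendar dates are taken in a single configured timezone per study (default
UTC; set explicitly for real deployments — the original data's timezone is
study metadata, not something to guess).

### Home

Home is established mathematically as the statistical mode of the recorded
coordinates. A mode of continuous coordinates is undefined without
discretization, so fixes are binned on a fixed latitude/longitude grid of
pitch `cell_size_deg` (default 1e-4°, about 11 m — matched to the ~10 m
outdoor accuracy of smartphone GPS receivers). The home coordinate is the
arithmetic mean of the fixes in the most-populated cell. Two fixed
conventions make the estimate deterministic and order-invariant: cell ties
break to the lexicographically smallest (latitude index, longitude index)
pair, and the at-home predicate is *inclusive* (distance exactly equal to
the home radius counts as at home). Whether the original analyses binned,
rounded, or clustered before taking the mode is not documented anywhere we
know of; the grid is this package's determination and is exposed as
configuration.

Being at home is operationalized as being within `radius_km` (default
0.5 km) of the established home — a deliberately cautious threshold against
GPS error, especially indoors.

### Trips: the two-state machine

Trips to and from home are detected by a finite-state machine with two
states, SH (subject at home) and SNH (subject not at home), stepped through
the fixes in time order:

* SH → SNH fires at the first fix farther than the radius; that fix's
  timestamp is the departure. (The departure is the first fix *outside*,
  not the last fix inside.)
* SNH → SH fires at the first fix back within the radius; that fix's
  timestamp is the return.

Each closed SH → SNH → SH cycle is one trip. Trips shorter than
`min_trip_duration_min` (default 15 min) are retained but flagged
non-qualifying, so that time accounting and audits stay consistent while
counts exclude GPS-artifact excursions. Two open-trip cases are possible
and are both flagged `closed = FALSE` and excluded from counts unless
`count_open_trips` is set: a trace that *starts* beyond the radius (we
start the machine in SNH with the first fix as the departure rather than
invent a departure the data never shows) and a trace that *ends* beyond the
radius. Recording gaps inside a trip pass through untouched — the machine
sees only fixes; a gap-aware variant is deliberately out of scope.

The implementation is a vectorized run-length scan over the at-home mask;
the test suite holds it equal, trip by trip and field by field, to an
independent brute-force scan that materializes the state at every fix.

### Metrics

* **Furthest distance** — the maximum home distance over all fixes.
* **Mean daily distance** — ambiguous in the field's usage, so both
  readings are implemented behind `daily_distance_mode` and the mode used
  is stamped into every output: `path_length` (default; the summed
  fix-to-fix distance per day, reading "distance travelled" literally) and
  `max_home_distance` (each day's furthest excursion).
* **Percent of recorded time at home** — interval-weighted:
  each within-session interval contributes its duration to the at-home
  numerator according to the *earlier* fix's at-home status (left-constant
  interpolation, the natural convention for a dense stream). The
  denominator is recorded time only.
* **Trips per week** — qualifying-trip count × 7 / recorded days, because
  recording covers only part of the calendar.

Intervals spanning local midnight are split at the boundary, with duration
and path length apportioned linearly, so both dates receive their share.
Undefined metrics (empty trace, zero recorded days) are explicit `NA`s,
never zeros, so group statistics can exclude them.

### Group statistics

Cohorts of this size call for nonparametric methods: per-group medians and
IQRs (linear-interpolation quantiles, type 7) and a Mann-Whitney U test.
The test's conventions are fixed and stamped into each result object: U
counts wins of sample 1, midranks for ties, tie-corrected variance, no
continuity correction, two-sided p from the normal approximation. The
uncorrected normal p estimates the permutation *mid-p*; the acceptance
suite verifies by full enumeration that for all group sizes with
$3 \le n_1, n_2 \le 7$ and no ties it is within 0.05 of the exact mid-p at
every achievable U. (For groups of one or two, no z-approximation of any
convention achieves that agreement; such sizes are below the method's
validity and the package still computes but should not be trusted for
inference.) No multiple-testing correction is applied across the four
metrics; the comparison output says so.

Severity ordering sums the two baseline UPDRS self-report partial subscales
(motor 0–39, nonmotor 0–12) into a single score — summation is this
package's determination; the per-subscale columns are retained so either
ordering can be inspected. Ties break by participant id; participants with
missing scores are listed last with a flag, never silently dropped.

### Privacy-preserving visuals

Reporting operations emit only the mean-subtracted coordinate frame
(centroid removed), which preserves the shape of a Lifespace while
revealing no absolute location. The heatmap accumulates *dwell seconds*
per grid cell (each interval credited to the earlier fix's cell — point
counts would distort under irregular sampling; a count mode exists as an
option), on a default 100×100 grid over the mean-subtracted bounding box
padded 5%. Dwell mass is conserved exactly: the grid total equals the
recorded in-period seconds. Recording timelines split sessions at local
midnight for per-day barcode plots.

## The synthetic-trace generator

Real study traces of this kind are not redistributable, so the package
ships a simulator that generates the statistical structure the analysis
assumes, together with ground truth for recovery testing:

* one recording window per non-skipped day, start uniform 08:00–14:00,
  duration uniform 4–6 h (a charge cycle), fixes at `sample_interval_s`
  (default 10 s to keep traces light; 1 s reproduces a full-rate stream);
* days skipped with probability 0.25, emulating the irregular adherence of
  a carry-the-phone protocol over ~8 weeks;
* out-and-back trips: a Poisson daily count (mean 1/day by default),
  log-normal one-way distance (median 5 km) clamped to [1.2, 60] km,
  straight-line travel at uniform 20–50 km/h, 20–90 min dwell at the
  destination, and at least 20 min of home dwell between the window edges
  and each trip; trips that cannot fit the remaining window are re-sampled
  up to five times and then dropped, with the drop counted in the truth;
* isotropic Gaussian noise, σ = 10 m, converted meters → degrees in the
  local tangent plane at the home latitude (adequate at city scale).

The truth log records the true home, every placed trip with its exact time
beyond the 500 m radius (travel spends 0.5 km/speed inside the radius on
each leg), the recording windows, and the exact true percentage of window
time at home. The cohort generator derives child seeds deterministically
from a master seed, scales the PD group's trip rate by a descending
multiplier sequence, and (optionally) assigns UPDRS-style severity scores
anti-monotone to the planted trip rate, so severity analyses have a planted
signal to recover.

What the simulator does *not* emulate — and hence what passing recovery
tests do not establish about real data: road networks and realistic paths
(only home distance and timestamps matter to the analysis under test),
indoor GPS degradation and urban-canyon multipath (noise is homoscedastic),
multi-home living arrangements, device clock errors, and trips that span a
recording boundary. On real data those effects surface as the kinds of
artifacts the 500 m radius and 15 min filter exist to absorb, but their
rates cannot be estimated from simulation.

## Numerical and design choices

* Clamping of the haversine's `asin` argument to [0, 1] guards
  floating-point rounding at antipodal and near-zero separations.
* Duplicate timestamps keep the last record (devices occasionally re-emit a
  fix); traces are sorted on construction, making every downstream
  operation order-invariant.
* The trip-qualification comparison is `duration >= min_trip_duration_min`.
* An open-end trip's duration runs to the last observed fix.
* Degenerate Mann-Whitney inputs (all observations identical) raise an
  error rather than return z = 0.
* Heat-grid extents degenerate to a ~0.1 m box for constant traces so a
  single-cell grid is still produced.
* CSV writers format timestamps to 1 s (ISO-8601 UTC) and coordinates to
  6 decimal places (~0.1 m), so outputs are byte-deterministic and
  round-trip within those precisions.

## Validation problem sizes

The package chooses deliberately modest, fixed problem sizes for its
checked properties: geometry oracles over 10^3 random arcs and 10^5 random
triples; FSM-versus-brute-force equality over 500 random traces of up to
1000 fixes; parameter recovery on a simulated 9 + 7 cohort recorded 40 days
at 10 s sampling (home within 50 m, qualifying-trip counts exact, percent
time at home within 2 points of truth); Mann-Whitney calibration by full
enumeration for group sizes 3–7 plus a 2000-replicate null simulation
(rejection rate 3–7% at α = 0.05); exact dwell-mass conservation on 100
random traces; and byte-identical pipeline reruns on a fixed cohort. The
planted two-fold trip-rate effect is checked for one-sided detection in at
least 80% of replicates using ground-truth trip counts at a coarse sampling
interval — that property exercises the statistics layer and the planted
effect, not fix density.

## Limitations

Percent of *recorded* time at home is biased by when participants choose
to switch the phone on (plausibly when going out), so absolute values are
not comparable across groups with different recording behavior — only the
method, not the construct validity, is testable here. The home estimate
assumes a single fixed residence. The FSM's two states cannot represent
neighborhood zones or assistance, which the traditional life-space
instruments capture; that information is simply absent from GPS. And the
group test at n = 9 vs 7 has limited power — the package reports effect
direction and p-values but no claim of equivalence should be read into a
nonsignificant result.
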