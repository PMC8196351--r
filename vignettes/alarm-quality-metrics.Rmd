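---
title: "Alarm-quality metrics for ICU monitoring audit logs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alarm-quality metrics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alarmetrics)
```

## The problem

Continuous patient monitoring in intensive care alerts staff whenever a
vital parameter leaves its preset range. The resulting alarm volume —
often well above a hundred alarms per bed per day — desensitises staff
(*alarm fatigue*) and is itself a patient-safety hazard. Effective alarm
management starts with measurement: a unit cannot reduce what it has not
quantified. `alarmetrics` turns the audit log that a monitoring central
station already records (one timestamped row per alarm state change or
handling action) into a structured alarm-quality profile that a unit can
re-compute every quarter and discuss with its staff.

The analysis is organised in five quality dimensions:

* **Alarm load** — alarms per bed per day; per-parameter frequencies
  ("bad actors"); alarms per device group and per criticality (red =
  high-priority clinical, yellow = medium-priority clinical, blue =
  low-priority technical); 24-hour temporal profiles; alarm floods.
* **Avoidable alarms** — technical alarms (equipment-caused: lead off,
  cable disconnect, interrupted arterial measurement), which are
  avoidable regardless of clinical response.
* **Responsiveness and alarm handling** — alarm durations, obtained by
  pairing `generated` with `terminated` log entries. The log does not
  record whether a termination was manual, so these are durations, not
  response times.
* **Sensing** — usage of the alarm-pause function and the proper
  pause-to-pause ratio; overmonitoring of physiological quantities
  alarmed redundantly by two device groups (respiratory rate from both
  ECG impedance and the ventilator).
* **Exposure** — how alarms distribute over the unit: single- versus
  double-room beds, and the daily count of beds exceeding the unit
  average.

## Metric definitions

With $N$ alarms observed over $B$ beds and $D$ calendar days:

* alarms per bed per day $= N / (B \cdot D)$. The per-(bed, day) grid is
  zero-filled over the full day span, so the mean of the grid equals the
  pooled rate; the SD is reported both over bed-days and over the daily
  per-bed means, because "per-day spread" can be read either way and the
  two differ on real data.
* An **alarm flood** is a fixed (tumbling) 10-minute bin containing at
  least 10 alarms for one bed. Bins are anchored at the bed's first log
  entry — not at clock boundaries — and beds are independent. Flood
  sizes are histogrammed into the half-open classes $[10,20)$,
  $[20,40)$, $[40,100)$, $[100,\infty)$.
* **Alarm duration** is the difference between the `terminated` and
  `generated` log timestamps of one episode. Durations are strongly
  right-skewed, so the median is the centre of record; durations above
  8 hours (about one shift) are treated as outliers, excluded from
  summaries and reported separately.
* A **proper pause** is a pause actively terminated strictly before the
  monitor's default pause length (3 minutes) elapses. Pauses re-enabled
  within 3 minutes of a previous pause's end are merged into one
  continuous pause. The proper pause-to-pause ratio is proper / all
  pauses, reported as $x{:}1$.
* **Exposure** compares per-bed alarm counts between room types as
  $(\text{single}/\text{double} - 1) \times 100\%$, and counts, per
  day, the beds strictly above the unit's mean per-bed count together
  with the share of that day's alarms they issued.

## Tunable parameters

All constants live in `unit_config()` so another unit can adapt them:

| parameter | default | unit | rationale |
|---|---|---|---|
| `flood_window_s` / `flood_threshold` | 600 / 10 | s / alarms | the standard flood definition (10+ alarms in 10 min) |
| `pause_default_s` | 180 | s | the monitor's maximum pause length |
| `pause_merge_gap_s` | 180 | s | re-enable within one default length = one procedure |
| `duration_outlier_s` | 28,800 | s | 8 h, roughly one shift; longer "durations" are data artifacts |
| `min_device_count` | 500 | alarms | device groups below this are noise at dataset scale; they stay in totals |
| shifts | 06–14, 14–22, 22–06 | clock | 8-hour pattern with 30-min handover exclusion at each shift start |

The default unit layout is 21 beds in 15 rooms (9 single-room and 12
double-room beds).

## Design choices

**Action-text grammar.** Vendors do not publish their audit-log action
vocabulary, and it varies between installations. The package therefore
defines a canonical, documented grammar (`audit_dialect()`):
`"<RED|YELLOW|BLUE> ALARM <GENERATED|TERMINATED>: <PARAMETER>"` plus
`"ALARM PAUSE STARTED/ENDED"`, with every pattern and token map held in
a pluggable dialect object. A real export is adapted by supplying regex
tables, not by editing the analysis. The synthetic generator writes the
same grammar, so the whole pipeline is exercised end to end. Anything
the grammar does not match is classified `other` and retained — an
unrecognised action is information, not an error.

**Episode pairing is FIFO.** When alarms of the same (bed, parameter)
overlap, the log does not say which termination belongs to which
generation. We match each termination to the earliest open generation
(queue semantics, matching how monitors stack alarms); LIFO is available
behind `pairing = "lifo"` for sensitivity analysis. Generated events
still open at the end of the data are reported unmatched rather than
truncated — truncation would fabricate short durations. Terminations
caused by a higher-priority alarm pre-empting a lower one are not
distinguishable in the grammar; all terminations are treated alike.

**Tumbling, per-bed-anchored flood bins.** Consecutive fixed bins
anchored at the bed's first log entry (a sliding-window variant exists
behind a flag, off by default). When several files are analysed
together, the anchor is the first entry of the *combined* sorted
stream, so concatenating months is equivalent to analysing them at
once.

**Flood size classes are half-open.** Descriptions like "between 10 and
20" and "between 20 and 40" overlap at their endpoints; we resolve the
ambiguity as $[10,20)$, $[20,40)$, $[40,100)$, $[100,\infty)$ and make
the breaks configurable.

**Deidentification shifts by whole weeks.** The day offset must be a
multiple of 7, which makes weekday structure (and hence weekend
effects) provably invariant, and bed labels are replaced through an
injective pseudonym map. Time of day, inter-event intervals and season
are untouched.

**Merged pauses are never proper.** If a pause was re-enabled after a
timeout, the operator let at least one default length elapse, so the
merged record cannot count as responsible pause usage. Because merging
changes the denominator of the ratio, both pre- and post-merge figures
are always reported.

**Strict inequality for "above average".** A bed exactly at the unit
mean is not counted as exceeding it. Beds absent from the log on a day
count as zero alarms — the log carries no occupancy information — and a
variant restricted to beds with at least one alarm that day is emitted
alongside, labelled as such.

**Trend lines.** The 24-hour profile figures draw a centred 31-minute
rolling mean rather than a generalized-additive smoother: the smoother
is presentation, not a metric, and a rolling mean is reproducible to
the last byte without a model fit. Every figure is accompanied by its
plain CSV data table, and the report body never recomputes anything —
all numbers come from the bundle.

## Numerical conventions

Timestamps are parsed at second resolution in unit-local clock time and
stored timezone-naive (internally represented in UTC). Daylight-saving
transitions therefore appear as a 23- or 25-hour calendar day; all
per-day statistics group by calendar date, never by 86,400-second
arithmetic. Unsorted input is sorted stably, ties keeping file order.
The observation span is the inclusive calendar-day range of the
generated alarms; partially observed edge days enter as-is. Ranked
tables break count ties lexicographically by label so output is
deterministic. Empty inputs yield zero-valued summaries (documented
per function) rather than errors.

## The synthetic generator

Real audit logs cannot be shipped with the package, so
`generate_log()` produces seeded logs with the statistical structure
the analysis assumes: piecewise-homogeneous Poisson alarm streams per
(bed, parameter) with shift multipliers (default morning 1.3, afternoon
1.1, night 0.8 — alarm activity tracks care activity, which peaks in
the morning); a single-room rate multiplier (default 1.26, matching the
observation that single-room patients — who are often more severely ill
or delirious — alarm more); log-normal durations per device group
(default medians: NIBP 64 s, temperature 26 s, SpO2 16 s, IBP 14 s,
ventilator 7 s, ECG 4 s) with a small outlier probability; a pause
model (default 10.86 activations/bed/day, active-termination
probability 0.1); and an optional burst mode that superimposes
clustered lead-off alarms so the flood detector sees realistic floods
(off by default, since bursts add to the alarm total).
`expected_metrics()` returns the closed-form expectations — summed
parameter rate × time-averaged shift multiplier × bed-averaged room
factor for the rate; `exp(meanlog)` for log-normal medians; the
active-termination probability for the proper-pause share — which the
test suite uses as recovery targets.

What the generator does *not* emulate: patient trajectories, alarm
autocorrelation within a patient's deterioration, threshold
adjustments, occupancy turnover, or vendor-specific action vocabulary.
Passing recovery tests therefore shows that the metric implementations
are correct under the stated stochastic model — not that any particular
real unit's values will match.

## Problem sizes and test tolerances

The recovery suite runs the full pipeline on one simulated month of a
21-bed unit (about 112,000 alarms), which keeps the whole test run
under a minute while leaving Monte-Carlo standard errors small enough
for meaningful 3-SE checks; smaller 1–4 day logs back the unit and
property tests. Recovery tolerances are 3 standard errors (exact
Poisson/binomial/delta-method forms, computed in the tests) or 5%
relative where a closed-form SE is awkward (medians). The flood
detector is checked for exact equality against an independent
brute-force bin-assignment oracle on 100 random streams.

## Limitations

Counting alarms cannot itself establish alarm fatigue; it quantifies
exposure, one ingredient of a sociotechnical phenomenon. The log lacks
manual-termination flags (so durations are not response times), lacks
occupancy (so empty-bed days deflate per-bed rates), and typically
omits low-priority soft-inoperable technical alarms and non-monitor
devices such as perfusion pumps — the reported load is a lower bound.
The proper-pause ratio conflates careless pause usage with procedures
that genuinely outlast the default pause length; it should be read
together with staff feedback, not as a performance score.
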