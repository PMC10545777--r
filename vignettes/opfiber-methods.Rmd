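---
title: "Methods: signal processing and perievent analysis in opfiber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal processing and perievent analysis in opfiber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opfiber)
```

# Scope and data model

`opfiber` merges two data streams from operant self-administration
experiments: behavioral session logs and dual-channel fiber-photometry
recordings. The pipeline is organized around five containers:

* a **behavior session** — named event timestamps plus named intervals,
  all in seconds from session start;
* a **raw fiber file** — time, calcium-dependent signal, isosbestic
  control, in file order;
* **recordings** — the contiguous segments of a raw file, split at
  acquisition gaps, each with its own sampling rate
  `(n − 1) / (t_last − t_first)`;
* **normalized signals** — a recording's trace under a method tag
  (`"F"` for ΔF/F, `"Z"` for Z-difference);
* **epochs** — event-aligned excerpts with a relative time grid and a
  pre-event baseline, renormalized per epoch.

All behavioral timestamps are converted to seconds at parse time; the
raw unit of integer-coded logs is declared in the configuration
(default: milliseconds). Behavior and fiber clocks are assumed shared
(offset 0) unless a per-session offset is set on the session pair —
rigs that start the two clocks independently can declare the shift
explicitly.

# Behavioral parsing and interval algebra

Integer-coded (Imetronic-style) logs are parsed entirely through
configuration: an event is a set of required integer values at given
column indices plus a time column. This keeps the parser usable across
protocol variants without hard-coding any vendor message grammar.
Generic column-per-event files take event names directly from their
header row; headers must be unique ASCII, and columns may be ragged.

Intervals are derived by rule, in order:

* `paired_on_off` pairs each onset with the next offset; an unclosed
  onset closes at session end (deterministic behavior on truncated
  logs); an offset before any onset is ignored with a warning.
* `event_offset` builds `[t, t + duration]` per trigger — this encodes
  the 40 s post-injection time-out, an interval that exists nowhere in
  the log as an explicit on/off pair. Instances are clipped at session
  end and merged if overlapping, so same-name intervals never overlap.
* `set_op` provides AND / OR / DIFF over previously derived intervals
  (e.g. "drug period minus time-outs").
* `guarded_switch` re-emits an onset event under one of two labels
  according to whether a given interval was active during a lookback
  window before the onset. This distinguishes house-light onsets
  arriving from the drug light from those arriving from darkness
  (i.e. from inside a post-injection time-out); the two are different
  sensory transitions and should not be pooled. The lookback defaults
  to 1 s — the notion of "immediately preceding state" needs a
  horizon, and 1 s is short against every protocol interval involved
  (≥ 40 s) while long against log timestamp resolution (1 ms).

Membership is closed–open, `[start, end)`: an event exactly at a
period switch belongs to the next period, so nothing is double-counted
at boundaries. Session end is the maximum of the last event and the
last interval end.

Event selection supports `all`, `first_in_interval` (at most one time
per interval instance), and `ordinal_in_series(k, n)`, which partitions
occurrences between successive reinforcements into fixed-ratio series
and returns the k-th member of each complete series. Responses during
time-out intervals are excluded from series counting by default — the
protocol records them but gives them no consequences, so counting them
would desynchronize the series from the reinforcement schedule.

# Photometry normalization

**ΔF/F** (`compute_dff`). The isosbestic channel is fitted to the
signal channel by ordinary least squares *within one recording*, never
across gap-separated segments — bleaching levels and lamp conditions
differ between segments, and a pooled fit would bias every segment.
The trace is `(signal − fitted) / fitted`. Preconditions are enforced,
not assumed: a zero-variance control channel and any non-positive
fitted value are fatal (the latter with the offending sample index),
because a ratio against a non-positive baseline is meaningless.

**Z-difference** (`compute_zdiff`). Each channel standardized by its
own recording-wide mean and *sample* (n − 1) standard deviation, then
subtracted. The mean/SD scope is the whole recording; the sample-SD
convention is stated here because the formula itself does not pin it
down — at photometry sample counts the two differ negligibly, but
tests pin the choice.

The recording gap threshold defaults to 1 s: acquisition runs near
1000 Hz, so 1 s is three orders of magnitude above any timing jitter
while far below any deliberate pause. Splitting uses strictly greater
(`Δt > threshold`); segments spanning less than 5 s are discarded with
a warning, as too short to fit or standardize stably.

# Transient detection

Detection runs on non-overlapping windows of `window_s` (default 10 s;
the last window may be short, and a window with fewer than two samples
is skipped). Windowing exists to limit the impact of photobleaching:
thresholds estimated over a whole decaying recording would
under-detect late transients. Within each window, standard scores are
computed per window by default (`scope = "per-window"`; a
whole-recording scope is available), and deviations `d` are measured
from the window median:

1. `th₁ = bmad_k · MAD(window)` with `bmad_k = 2.5`; samples with
   `d ≤ th₁` are the baseline bulk.
2. `th₂ = pmad_k · median(d[d > th₁])` with `pmad_k = 3.5`: the spread
   estimate of the second stage is the median deviation of the
   *remaining* (supra-threshold) samples, still centered on the window
   median. Samples with `d > th₂` are transient candidates.
3. A refractory filter keeps only the highest sample within any run of
   candidates spaced closer than `spacing_ms` (default 50 ms, the
   GCaMP6f rise time): two supra-threshold samples 20 ms apart are one
   transient, not two.

The centering choice in stage 2 is deliberate and is the one genuinely
open design point of the detector. The remaining data is a one-sided
tail, so re-centering the MAD on the tail's own median would measure
the tail's internal spread around a biased center; keeping the window
median as the center makes `median(d[d > th₁])` a scale estimate of
how far the extreme tail sits above baseline. For Gaussian noise this
puts the effective threshold near 7 noise-SD — essentially zero false
positives over a minute of 1000 Hz data — while transients an order of
magnitude above the noise MAD survive. Re-centered variants put the
second threshold at 2–3 noise-SD and flag hundreds of noise samples
per minute, which contradicts the intended "true peak" semantics.
Both MAD multipliers and the anchor behavior are configurable.

MAD is everywhere the raw `median(|x − median(x)|)` with no 1.4826
consistency constant; thresholds are expressed in multiples of this
raw MAD. Degenerate windows (zero MAD or zero variance, e.g. constant
signal) yield no peaks, with a warning. Peak time is the time of the
maximal sample of its run — no sub-sample interpolation; amplitude is
reported in the units of the input trace.

A known limitation follows from the stage-2 construction: a transient
whose decay occupies a large fraction of its window contributes many
samples to the supra-threshold tail and thereby raises the very
threshold that must catch it. Impulse-like or fast-decaying transients
(decay ≪ window) are detected reliably; a borderline-amplitude
transient with a decay of several hundred milliseconds inside a 10 s
window can self-mask. Shortening `window_s` does not help (it
increases the occupied fraction); raising it, or using amplitudes well
above ten noise-SD, does.

# Perievent analysis

Epochs take every sample in the closed window
`[event − pre, event + post]`; the baseline is the whole pre-event
span (a sub-span can be configured, but the full span is the default
because the definition of the baseline is simply "the time preceding
the event"). Renormalization offers classical Z
(`(x − mean(bl))/SD(bl)`) and robust Z
(`(x − median(bl))/MAD(bl)`); the robust variant exists for
heavy-tailed baselines, where single outliers move mean and SD but
barely move median and MAD. Epochs whose window crosses a recording
edge, or whose baseline has zero spread, are *rejected with a recorded
reason* and surface in the exclusion report; the accounting invariant
`accepted + excluded = selected` is enforced by tests.

Perievent renormalization can start from either ΔF/F or Z-difference
values; the method tag is carried through and reported in the summary
table's `normalization` column.

Summaries per epoch: pre/post AUC by trapezoid over seconds (split
exactly at t = 0, interpolating a cut point when no sample falls on
zero; not time-normalized, so a constant c over span L gives c·L);
pre/post means of the native trace and of both renormalizations; and
pre/post transient statistics from the detector run on the epoch
itself.

For averaging across sessions, epochs are linearly interpolated onto a
uniform common grid over `[−pre, +post]` whose sample count is the
*maximum* count among epochs (configurable; the maximum loses no
resolution from the densest epoch, at the cost of mildly oversampling
the others). Grid points just outside an epoch's own support take the
nearest endpoint value, so no NA propagates into the mean trace.

# The synthetic generator

The generator defines the study conditions under which the pipeline is
validated. `session_template()` encodes the emulated protocol: three
40-min drug periods alternating with two 15-min drug-free periods;
fixed ratio 5; cue 1 s after the completing poke, lit for 4 s; pump
1 s after cue onset; 40 s time-out from the injection. Nose-pokes are
homogeneous Poisson per period type (defaults 0.05/s active during
drug periods, 0.02/s during no-drug, 0.01/s inactive — a few hundred
active pokes and a few dozen injections per 2.5 h session, the order
observed in trained rats). Reinforcement is gated to drug periods;
time-out pokes are emitted but have no consequences, so
series-counting logic is genuinely exercised. Timestamps are drawn at
1 ms resolution, the native resolution of the integer-coded log
format, which makes writer→parser round trips exact.

`photometry_template()` encodes the signal model:

* shared baseline `B(t) = baseline · exp(−t/τ_bleach)` with
  `baseline = 0.15` a.u. and `τ_bleach = 7200 s` (roughly 30% decay
  per hour — slow but visible bleaching);
* transients enter the signal channel only, multiplicatively:
  amplitude `a` means a fractional (ΔF/F) excursion of `a`. The kernel
  is a difference of exponentials (rise 50 ms, decay 400 ms,
  GCaMP6f-like), normalized to unit peak and time-shifted so the
  stated transient time is the *peak* time; spontaneous transient
  amplitudes are log-normal (median 2% ΔF/F) so the robust-Z path
  sees heavy tails;
* the isosbestic channel is `0.85·B(t) + 0.02` — affinely linked to
  the signal baseline, which is exactly the assumption the OLS ΔF/F
  correction relies on, so with noise, transients and artifact all
  zeroed, ΔF/F is identically zero to numerical precision (tested to
  1e-10);
* a shared AR(1) motion artifact (SD 1e-4 a.u., 2 s time constant)
  enters both channels additively and equally;
* independent white measurement noise of SD 2e-4 a.u. per channel;
* recording blocks default to 60 s around the two drug→no-drug light
  shifts (2370–2430 s and 5670–5730 s), mirroring the practice of
  recording around the transitions of interest, and giving the file
  two discontinuous recordings;
* the default event-locked transient (5% ΔF/F, 0.2 s after each house
  light onset) is the planted effect that end-to-end tests must
  recover: the batch mean interpolated trace must peak within 50 ms of
  +0.2 s and within 15% of 0.05.

What the generator does *not* emulate: wavelength-specific optics,
hemodynamic contamination, non-exponential bleaching, sensor
saturation, or correlated (non-white) measurement noise. Passing tests
therefore demonstrate that the implementation computes its defined
quantities correctly under the model's assumptions — not that those
assumptions hold for any particular rig. In particular, real 1000 Hz
photometry noise is temporally correlated, which makes transient
detection *easier* than on the white-noise synthetic traces used here.

All randomness flows through R's generator from a single integer seed;
session i of a study uses `seed + i − 1` (behavior) and
`seed + 1000 + i − 1` (photometry), and emitted files are
byte-identical across runs with the same seed.

# Numerical conventions and problem sizes

* Exported CSVs print numerics with 17 significant digits, so
  export→import round trips are bit-exact, and CSV/HDF5 twins of one
  recording compare identical.
* Formula-level tests (MAD, OLS ΔF/F, Z-difference, epoch Z / robust
  Z) assert agreement with independent direct evaluation at 1e-9.
* Behavioral round trips assert times to 1e-9 s (the only error being
  one-ulp differences between `x·0.001` and `x/1000`).
* Test problem sizes: detector fixtures use 60 s at 1000 Hz; the
  end-to-end study uses 3 sessions × two 60 s blocks at 1000 Hz —
  large enough for stable statistics, small enough that the whole
  suite runs in well under a minute.

# Known limitations

* Single-site recordings only; one signal/control pair per file.
* No detrending beyond the two implemented normalizations (no
  exponential fit subtraction).
* The transient detector's stage-2 threshold scales with the occupancy
  of the extreme tail, with the self-masking behavior described above.
* No statistical group comparisons: summary tables are exported for
  external statistics.
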