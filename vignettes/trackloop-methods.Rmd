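---
title: "trackloop: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trackloop: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackloop)
```

trackloop is a software-only control plane for head-fixed 1D navigation
experiments, plus the neural analyses used to validate such rigs.  This
vignette is the package's own account of the models it implements, why
the defaults are what they are, and what the validation suite does and
does not demonstrate.

## The control plane

### Messaging

All rig components exchange small JSON datagrams.  A message carries a
`route` (an array of route names; the head selects the receiving
subsystem, the remainder is a sub-route), an `action`, a `payload` of
scalars and flat arrays, a monotone per-sender `id`, and a timestamp
`t_ms` relative to the experiment's synchronizing start.  Two numerical
choices matter:

* Encoded datagrams are limited to 1400 bytes so each message fits in a
  single MTU and is never fragmented; oversized messages fail at
  *encode* time, where the caller can react.
* Doubles are serialized with 17 significant digits, so
  `decode(encode(m))` is bit-exact and golden-file tests are stable.

Delivery can be acknowledged: a sender retries an identical message id
until an `{route:["ack"], payload:{id}}` reply arrives or
`1 + max_retries` sends are exhausted.  Receivers deduplicate by id, so
a retried datagram actuates at most once.  Transports are injectable;
the scripted in-process variants (lossless, drop-list, fixed-delay) are
part of the public API precisely so that delivery logic is testable
without sockets.

### Position tracking

Rotary-encoder ticks arrive as signed deltas and are integrated as
`position += ticks * scale_mm_per_tick`.  Crossing the configured track
length advances the lap counter and wraps by subtraction, so residual
distance is preserved exactly; backward motion floors at 0 within a lap
(wrapping backward past the seam would decrement laps, which no
downstream analysis could interpret — flooring is a deliberate choice
and is confined to one code path should a rig need the other
behavior).

A physical lap-reset sensor re-anchors the integrated position to 0
once per belt revolution and reports the signed drift along the shorter
arc.  Because a reset can race the arithmetic wrap, a *guard window* of
L/4 of travel after a wrap suppresses double lap counting.  L/4 is far
larger than any plausible per-lap slip (tens of mm) and far smaller
than a lap, so the window's exact value is uncritical within an order
of magnitude.

Calibration divides a known belt length by the mean tick count over
complete revolutions — the mean, not the median, because tick-count
noise is symmetric measurement jitter, not outlier-contaminated.

### The context engine

A *context list* groups stimuli that switch together: a set of zones
(centre + radius, circular distance on circular tracks; no zones =
global), device targets messaged on activation edges, and a stack of
*decorators*.  Every decorator is a conjunction — lap parity, time
window, lap range, or block alternation ANDed onto the inner rule — so
stacking order cannot change an activation trace (a property the test
suite checks by permuting random stacks).  Disjunctive decorators are
deliberately not offered: OR-composition makes activation traces
depend on evaluation order, and none of the supported paradigms need
it.

Reward rules: `non_operant` triggers on zone entry; `operant` requires
a lick while inside the zone.  Both latch once per lap per zone; the
latch rearms when the lap counter increments.  Licks are latched per
event-loop step (any lick since the previous step counts), which
debounces the sensor at the step timescale.

The event loop advances a logical clock in 10 ms steps, mirroring a
100 Hz position-controller poll.  Within a step, inbound messages
(position deltas, lap resets, licks, acks) are applied before context
evaluation, and contexts are evaluated in settings-file order.  Every
emitted message and state change becomes a timestamped record.  With an
injected clock, a seeded rig, and a fixed wall-clock header, an entire
session log is byte-identical across runs — determinism is a contract,
not an accident.

### Behavior log

One JSON object per line, appended and flushed per record: a crash
loses at most a partial final line, which the reader skips with a
warning.  Times are integer-valued milliseconds relative to the sync
start record (the header holds the wall-clock epoch).  Time
regressions are monotonized and flagged with an error record rather
than rejected, because a log that drops records is worse than a log
that documents its own repairs.  `load_session()` reconstructs position
traces, lick/reward times and paired context intervals; an interval
still open at end of file is closed at the last timestamp and flagged.

### The virtual rig

The simulated mouse runs at an Ornstein–Uhlenbeck-fluctuating speed
(mean 200 mm/s, SD 40 mm/s, relaxation 1 s⁻¹) with random pauses
(0.05 s⁻¹, 1 s long) and licks as per-window Bernoulli events (0.5 Hz
baseline, elevated to ~8 Hz inside reward zones).  These statistics are
plausible for a motivated mouse on a 2 m belt but are *not* fitted to
any dataset; they are documented defaults, chosen once.  Encoder ticks
are quantized displacement with the fractional remainder carried
forward, which makes the conservation check (`sum(ticks) * scale` vs
true displacement) exact to within one tick.  Belt slip is modelled by
letting the physical belt complete a revolution only every
`L + slip` of wheel-measured distance; the lap-reset sensor follows
the physical belt, which is exactly the failure mode the reset feature
exists to correct.

All rig randomness flows from one seed through named substreams
(motion, licks, cell parameters, event draws), so components are
independently reproducible.

## The analysis suite

### From event amplitudes to tuning curves

Analyses start from deconvolved event-amplitude trains.  Events are
kept when their amplitude exceeds `median(raw) + 4 * MAD(raw)`; the MAD
is *unscaled* (consistency constant 1, configurable), matching the
plain reading of "4 median absolute deviations".  Separately, a
3-SD-above-mean mask selects significant fluorescence transients for
amplitude/frequency summaries only — it plays no role in field
detection.

Binarized events are binned into 4 cm spatial bins, divided by per-bin
dwell time, and smoothed with a Gaussian of SD 2 bins (8 cm), truncated
at 4 SD and wrapped circularly on circular tracks.  Never-visited bins
get rate 0 and a flag rather than NaN.

### Place-field detection

The null distribution comes from 1000 circular shuffles: within each
lap, event times are rotated relative to position by an independent
uniform offset (uniform over the lap's frame count — offsets are
otherwise unconstrained).  This preserves occupancy, per-lap event
counts, and within-lap event clustering, destroying only the
event–position relationship.  The per-bin 99th percentile of the
surrogate smoothed curves is the significance threshold.  Candidate
fields are maximal supra-threshold runs (wrapping allowed) kept when
they span 3–24 bins (12 cm to under 100 cm) *and* events occurred
within the run on at least 50% of laps.  No additional multiple-testing
layer is applied on top of these three rules; the calibration analysis
below measures what they deliver jointly.

Per cell, sensitivity is the fraction of laps with an in-field event;
specificity is the per-lap in-field fraction of events averaged over
laps — laps with zero events are excluded from that average (an
undefined 0/0 should not drag the mean), and a cell with no events at
all returns a flagged NA.  Multi-field cells average per-field values.
Spatial information is the standard occupancy-weighted bits-per-event
sum, with zero-rate bins contributing zero; it is 0 for a flat curve
and log2(B) when all activity sits in one of B equally occupied bins.

For remapping, rate-map correlation is the Pearson correlation of a
cell's two smoothed curves.  On belts, where fields can anchor to the
physical seam, the population-vector alignment first finds the single
circular shift maximizing the mean per-bin across-cell correlation
(ties to the smallest shift) and applies it to all cells of the second
session.

### Position decoding

The naive-Bayes posterior over bins for an activity vector *a* is

$$P(pos \mid a) = C \Big(\prod_i f_i(pos)^{a_i}\Big)\,
  e^{-\tau \sum_i f_i(pos)}$$

with `f` the cells-by-bins mean binarized activity over training
frames.  Numerical choices: computed in log space; `f` floored at 1e-4
events/frame so a cell silent in training cannot produce an all-`-Inf`
posterior; argmax ties break to the lowest bin index; τ is interpreted
as the decoding *time* window in seconds (one frame period by default)
rather than the spatial bin — the alternative reading exists, so τ is
an explicit argument.  Activity `a` is the per-frame binarized event
indicator.

Cross-validation is leave-one-lap-out (trial = lap throughout the
package).  To compare populations of different sizes, each of 50
repeats subsamples 500 cells without replacement by default.  The
validation runs use a 200-cell synthetic population with a 150-cell
subsample and 20 repeats — sizes chosen so the whole validation suite
stays fast while the subsampling machinery is still exercised — and the
chance level for the circular belt is L/4 (50 cm at 2 m), with the
label-shuffle estimator available for any geometry: permute cell
identities of the test activity, decode, and read the observed error's
rank (reported as the permutation estimator `(1 + #{shuffle ≤ obs}) /
(1 + n)`).

### The synthetic populations

Tuned cells have circular-Gaussian rate profiles (baseline 0.2 Hz, peak
2.5 Hz ± 20%, SD 100 mm) and untuned cells sit at baseline; events are
Bernoulli per 30 Hz frame with probability `rate × dt` (the generator
refuses configurations where this exceeds 1), with lognormal
amplitudes.  Bernoulli-per-frame rather than Poisson counts is
deliberate: the analysis binarizes immediately, so per-frame occurrence
is the quantity that needs exact ground truth.  The default population
is 600 cells at 40% tuned — bracketed by the place-cell proportions
typically reported for visual-VR and belt systems — while the
benchmark families use 200 cells over ~30 laps, the size at which the
shuffle-null calibration is specified.

The generator emulates lap-structured running, zone-directed licking,
and spatially tuned event trains.  It does **not** emulate imaging
noise, deconvolution artifacts, slowly drifting baselines,
non-stationary representations, or correlated population noise.
Passing the validation suite therefore shows that the *pipeline* is
correct and calibrated on data satisfying its own assumptions — not
that real recordings will yield any particular place-cell fraction.

## What the validation suite checks

* the two-proportion z statistic on published place-cell counts
  reproduces to two decimals;
* the circular chance level L/4 agrees with a 10⁶-pair Monte-Carlo
  estimate within 3 standard errors;
* the detector's admissible field widths are exactly 12 cm up to (but
  excluding) 100 cm;
* on 200 untuned cells the 99th-percentile threshold is exceeded in
  ~1% of bins and the full place-cell criterion misfires in well under
  1% of cells;
* on the tuned-rich population ≥90% of true fields are recovered with
  centre error ≤ 2 bins and almost no untuned cells are flagged;
* decoding beats L/4 and collapses back to it under label shuffling,
  and the posterior always sums to 1;
* a seeded closed-loop session tracks ground truth within one tick plus
  one update interval of travel, rewards each completed lap exactly
  once under guaranteed in-zone licking, balances every context
  start/stop pair, bounds injected 3 mm/lap belt slip at the lap-reset,
  and replays byte-identically;
* messages round-trip losslessly and acknowledged delivery behaves
  correctly under scripted loss.

All of these are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* The wire schema and settings-file keys are this package's own design;
  they are *compatible inventions*, not a claim about any particular
  hardware rig's original format.
* Only conjunctive decorators exist; between-lap timeouts are expressed
  as time-window decorators rather than a dedicated mechanism.
* Backward motion floors at 0 rather than wrapping backward.
* The decoder's τ ambiguity (temporal vs spatial bin) is resolved to
  the temporal reading and exposed as an argument.
* No deconvolution, motion correction, segmentation, or cross-day
  registration: the analysis starts at event-amplitude trains.
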