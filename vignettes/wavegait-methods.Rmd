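---
title: "Analysing larval wave gaits with wavegait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing larval wave gaits with wavegait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavegait)
```

## The scientific problem

Beetle larvae such as *Tribolium castaneum* walk with six thoracic legs
and, unlike most adult hexapods, use a bilaterally symmetric
posterior-to-anterior *wave* gait: the metathoracic (T3) leg pair swings
first, the mesothoracic (T2) pair follows about a third of a cycle later,
and the prothoracic (T1) pair another third after that, with left and
right legs of a segment moving together. At slow speeds this coordination
degrades — legs drop swings and contralateral synchrony loosens — while
the posterior-to-anterior sequence is preserved. The animals also engage
their pygopods (paired ventral terminal abdominal appendages) as anchors
during challenging locomotion, planting them around leg-swing initiation,
and express whole-animal exploratory behaviours such as headsweeps and a
turn–reverse–turn manoeuvre ("backtrack and redirect").

wavegait turns the point-tracking output of such experiments (leg-tip
trajectories, body-centroid tracks with a bending angle, plant-event
frame lists) into the standard kinematic quantities: swing/stance
segmentation, cycle period, duty cycles, stride length, intra- and
intersegmental phase, multitaper coherence against an anchor leg,
T3-to-T1 walk-cycle extraction, event-triggered statistics, and path
metrics. Because such tracking data are rarely deposited, the package
ships a seeded generator that emits the same file dialects with exact
ground truth, so every estimator can be validated by parameter recovery.

## Conventions

* Frames are 0-based; intervals are half-open `[start, end)` in frames;
  all reported durations are in seconds and lengths in mm. Velocity
  sample `i` describes motion during frame interval `[i, i+1)`.
* Phase differences are expressed in degrees of the cycle. Negative
  values are temporally earlier. Intrasegmental phases are wrapped to
  `[-180, 180)` and summarised as circular means of absolute offsets;
  intersegmental phases (next target onset after each anchor onset) lie
  in `[0, 360)`.
* Coherence phase is `Arg(S_xy)` with `S_xy = <Conj(X) Y>`, so a
  *delayed* second signal has *negative* phase at the delay frequency
  (a quarter-period delay gives -90 degrees).

## The gait model behind the generator

`simulate_gait()` schedules swing onsets for leg *k* of segment *s* at

```
t = n T + (phase_s / 360) T + jitter,   phase_T3 = 0, phase_T2 = lag, phase_T1 = 2 lag
```

with `lag = 120` degrees by default, left/right legs identical up to
Gaussian jitter, and each scheduled swing dropped independently with
probability `skip_prob`. The leg tip is stationary in the lab frame
during stance and advances by one stride during swing following a
half-sine velocity pulse — the pulse is smooth, vanishes at both ends,
and makes the peak speed analytic (`pi * stride / (2 * s_w)`), which the
tests use to set relative noise levels. Tracking error is emulated as
white Gaussian velocity noise along the direction of motion; isotropic
2-D noise would rectify into a positive stance-speed floor (~1.25 x the
per-axis SD) that no threshold segmentation could see through, which is a
property of speed magnitudes, not of any estimator.

Defaults describe fast straight walking as observed in these larvae:
period `T = 0.2` s, swing duration `s_w = 0.07` s, 120-degree
intersegmental lag, no jitter or dropout, 1.8 mm/s forward speed, 100
frames/s (the frame rate at which swing start/stop frames are resolvable
to a single frame). Slow walking is emulated by raising `T` at constant
`s_w` — stance absorbs the whole difference — together with nonzero
`skip_prob` and `intraseg_jitter_sd` (10 degrees is a realistic
contralateral jitter for the slow regime). Pygopod plant events are
generated at swing onsets with probability `pygopod_prob` (default 0.1,
consistent with plant rates near 0.8 Hz at slow-cycle swing-onset rates)
and Gaussian timing jitter (`pygopod_jitter_sd`, default 0.02 s).

Ground truth records continuous onset/offset times, integer frame labels
under the majority-overlap rule (a frame is a swing frame when most of it
lies in the swing interval), true phases, and per-event source onsets.

`simulate_path()` analogously builds a 2-D exploration path: a
constant-speed heading walk carrying injected headsweeps (smooth
body-angle excursions past the 210/150-degree thresholds), pauses, and
backtrack-and-redirect episodes (turn, backwards displacement along the
frozen prior heading at straight body angle, contralateral turn; 3–6 s
total). `mean_speed` is the *overall* mean instantaneous speed — the
profile is normalised after episode injection — so the default 1.8 mm/s
matches what a tracker would report for the whole recording.

## Estimators and numerical choices

**Speed and smoothing.** Leg speed is the forward-difference step length
times `fps * mm_per_px`, low-pass filtered with a Savitzky–Golay filter
(window `max(5, odd(0.05 s * fps))`, order 2 — wide enough to suppress
tracking jitter, short enough to pass a 5 Hz gait) and clipped at zero.

**Swing segmentation.** Swings are maximal runs of the smoothed trace
above the exit threshold that reach the entry threshold at least once
(hysteresis): entry = 0.3 x the per-leg robust peak (95th percentile
speed), exit = half of that; runs shorter than 2 frames are dropped. An
all-zero trace yields an empty series. Boundary *timing* is then refined
on the raw trace: the SG window smears a 7-frame pulse outward by about a
frame per side, so the exit-threshold crossing of the raw speed is
linearly interpolated to sub-frame precision. The systematic part of the
remaining bias is common to all legs and cancels exactly in phase
differences. Integer frame labels are the rounded refined times
(majority-overlap rule, matching the generator's labels).

**Period, duties, phases.** Per-leg cycle frequency is the mean
swing-onset rate; the animal's period is the reciprocal of the mean
frequency. Swing duty is mean swing duration over the period per segment,
stance duty its complement (stance is defined as the complement of
swing, so the two sum to one by construction). Intrasegmental phase pairs
each left onset with its nearest right onset (ties to the earlier one);
intersegmental phase takes the next target onset after each anchor (T3L)
onset. Under swing dropout the estimated period inflates (missing onsets
lower the onset rate), so nearest-onset pairings that land a full cycle
away no longer wrap to zero — estimated intrasegmental phase therefore
grows with dropout, reproducing the empirical slow-mode pattern without
any extra generator machinery.

**Stride length** is the net leg-tip displacement over a swing. The
alternative reading — body advance per cycle — is not implemented; with
the generator's stationary-stance model the two coincide.

**Spectra and coherence.** The anchor leg's stepping frequency is the
periodogram peak with explicit plateau handling: bins within
`plateau_tol` (relative, default 5%) of the maximum form contiguous
plateaus; the middle bin of the winning plateau is returned (upper-middle
for even lengths), and of two tied blocks the higher-frequency one wins.
The DC bin is excluded; raw (not log) power is compared. Coherence uses
DPSS multitapers computed from the classical tridiagonal formulation,
averaged over `K` tapers (default 7, time-bandwidth `NW = 4`) and `R`
non-overlapping segments (default 1 s each, demeaned). The significance
threshold is the analytic null quantile

```
threshold = sqrt(1 - alpha^(1 / (dof/2 - 1))),   dof = 2 R K,
```

which the test suite cross-checks by Monte-Carlo false-positive
calibration at dof 8, 40 and 100 (within ±0.02 of alpha = 0.05), and the
estimator is verified against an independently coded averaged-periodogram
oracle in the boxcar/K = 1 limit. Magnitude is clamped to `[0, 1]` and is
invariant to amplitude scaling; `phase(x, y) = -phase(y, x)`.

**Walk-cycle extraction.** T3 onsets from either side that fall within a
quarter period are one cycle start (bilateral synchrony); a candidate is
accepted iff the next T2 onset and then the next T1 onset occur before
the following T3 onset, resolved greedily left to right. Stance durations
above `median + 1 sd` (per animal) are discarded as pauses; the bound is
upper-only, since a lower bound would re-admit pauses. This rule is
exactly idempotent on tied stance distributions (the canonical fixture);
on continuously distributed stances a second application would trim the
new upper tail, so the filter is applied once, per animal.

**Pygopod events.** Offsets are to the globally closest swing onset over
all six legs, positive when the event follows the initiation. Histograms
use the Freedman–Diaconis width `2 IQR / n^(1/3)` with bins centred on
zero; a zero IQR falls back to Sturges-count binning. Note that events
quantised to integer frames alias against FD bins of comparable width —
with 0.01 s frames and ~0.01 s bins the sample mode can sit a bin or two
off centre at single draws; analyses of mode location should pool events
or use sub-frame event times where available. The event-triggered
average extracts velocity on `[-w, +w]` around each event, drops events
with incomplete windows and divides by the mean over all included windows
(a z-score normalisation is available as an option).

**Path metrics.** Stillness uses a speed tolerance of 0.05 mm/s (a
literal 0 never occurs in floating point); the straight/bent boundary is
±30 degrees around 180, deliberately matching the 210/150 headsweep
thresholds so that "bent" and headsweep excursions coincide. Curviness is
total path length over net displacement (≥ 1, dimensionless,
rotation/scale invariant). The backtrack detector is a three-stage state
machine — headsweep, backwards run (negative displacement projected on
the heading of the 0.5 s window preceding the first headsweep, frozen for
the episode, with at least 0.3 mm accumulated over ≥ 0.3 s at near-
straight body angle), contralateral headsweep — all within a 10 s window.
Left/right labels flip under mirror reflection of the path. The headsweep
bias test is the exact binomial test of proportion 0.5 — the same null as
an intercept-only binomial model, but well behaved when every event falls
on one side (where the Wald test degenerates); it is mildly conservative
at small counts.

## What the generator does and does not emulate

The generator reproduces the statistical structure the estimators assume:
phase-locked onsets with speed-dependent stance, constant swing duration,
bilateral symmetry, swing dropout, velocity noise, phase-locked plant
events, and labelled path episodes. It does **not** emulate body
kinematics (leg joint angles, substrate deformation), tracking artefacts
such as identity swaps or dropped frames, non-stationary speed drift
within a bout, or correlated (non-white) tracking noise. Passing
parameter-recovery tests therefore demonstrates estimator correctness
under the stated model, not robustness to every failure mode of real
video tracking; the I/O layer treats gaps in real tracking files as hard
ingestion errors for the same reason.

## Problem sizes used in validation

The shipped checks use 20-cycle simulations at 100 frames/s (4 s, 401
frames per leg) for parameter recovery; 5 simulations for frame-agreement
scoring; 20 seeds per dropout level; 1000 replicates per dof for
coherence calibration (64-sample segments); 150-cycle simulations
(~500 events) for event alignment; and twenty 120 s paths at 30 frames/s
for the backtrack detector. These sizes give stable Monte-Carlo summaries
(binomial SE under 1% on calibration rates) while keeping the whole suite
fast.

## Known limitations

* Cycle-period estimation assumes at least two swings per leg; sparse
  records return `NA` and downstream phases are flagged undefined.
* The plateau rule compares raw power with a relative tolerance; very
  noisy spectra can fragment a broad peak into multiple plateaus, in
  which case the higher-frequency tie rule decides.
* The pause filter's threshold depends on the observed stance
  distribution; with fewer than ~5 stances the SD is unstable.
* `stride_length` reports leg-tip displacement; for animals that slip
  during stance this is not the body advance per cycle.
* The backtrack detector requires an estimable heading (speed > 0 over
  the reference window) and will not fire at recording edges.

## A minimal end-to-end run

```{r example, eval = FALSE}
g <- simulate_gait(gait_params(seed = 1))
summary_tables <- gait_summary(g$track)
summary_tables$animal

coh <- leg_coherence(g$track)
coherent_leg_fraction(coh)

cycles <- extract_t3_to_t1_cycles(summary_tables$swings)
extraction_fraction(cycles, (g$track$n_frames - 1) / g$track$fps)
```

The same pipeline is scriptable from a shell through
`inst/scripts/wavegait.R` (subcommands `simulate`, `gait`, `coherence`,
`cycles`, `events`, `path`), which writes tidy CSV tables and a JSON run
manifest.
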