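---
title: "Methods: quantifying isochrony, homothety and the steering law from pen trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying isochrony, homothety and the steering law from pen trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penlaws)
```

# The measurement problem

Handwriting difficulties are usually assessed only after handwriting is
mastered, by subjective inspection of the product.  A more quantitative
route is to test whether a child's pen movements obey the kinematic
regularities that typical handwriting shows: **isochrony** (speed rises
with gesture size so that duration is roughly conserved), **homothety**
(the relative time given to each letter or symbol of a sequence is
conserved across sizes and speeds), and the **speed–accuracy tradeoff**
in its continuous, path-steering form (movement time linear in the index
of difficulty `ID = A/W` of a tunnel-shaped path).  Because symbol
drawing is acquired years before writing, these laws can be probed at
preliteracy age by replacing words with symbols.

`penlaws` implements the complete measurement chain for both tasks —
a *copy* task (copy a word or symbol under five instruction modalities)
and a *tunnel* task (steer word- or symbol-shaped tunnels at five
difficulty levels) — together with a synthetic trajectory generator so
that the chain can be validated end to end without child data.

# Data model and units

All analyses run on `TrialRecording`s: ordered samples `(t, x, y,
pen_down, pressure)` at a nominal 50 Hz.  The canonical frame is
millimetres, y increasing upward; session files carry device metadata
(`pixels_per_mm`, `y_axis`, and `canvas_height_px` for y-down devices)
and readers convert on input, so speeds are comparable across devices.
Timestamps stay as recorded — no resampling — and every downstream
formula uses actual time differences, tolerating sampling jitter.
Two on-disk dialects are supported (long CSV for spreadsheets, nested
JSON for fidelity, the latter carrying optional manual segmentation
boundaries and the tunnel-geometry catalogue).  Structurally invalid
trials are quarantined with reasons rather than silently dropped.

# Copy-task kinematics

The per-execution speed scalar driving the isochrony analysis is
computed as: discard the first and last 5% of the samples (border
effects at pen landing and lift; the fraction is counted in samples, a
choice discussed below), form discrete speeds
`v_i = ||Δ(x,y)_i|| / Δt_i` at pair midpoints, low-pass filter at 10 Hz,
and average.  Choices worth recording:

- **Filter realisation.** Fourth-order Butterworth applied
  forward–backward (zero phase), so filtering cannot bias event timing
  downstream.  `signal::filtfilt` assumes zero initial conditions,
  which drags the ends of short signals toward zero; the package pads
  both ends with odd reflections (up to 60 samples) before filtering,
  which restores unit DC gain to near machine precision.
- **When filtering is refused.** Runs shorter than 15 points, runs
  whose inter-sample intervals deviate more than 20% from their median,
  and rates not exceeding twice the cutoff cannot be filtered; the mean
  speed falls back to raw speeds with a warning rather than failing the
  trial.
- **Pen lifts.** Speed pairs spanning a lift are excluded; multi-stroke
  trials are filtered per stroke.  The airborne pen is unobserved on
  most tablets, so lifts contribute no speed evidence.
- **5% by samples, not arc length.** Border effects are temporal
  transients; a spatial definition would trim more of slow trials.  The
  fraction is configurable.

# Segmentation and fraction times

For cursive words, the transition between letters is the lowest point of
the trace between them.  The detector works on the concatenated pen-down
trace: smooth y at 6 Hz (zero phase — cursive letter content sits well
below this), collect interior local y-minima at least 5% of the total
arc length from each other and from the trace ends, keep the
`n_letters - 1` lowest, then refine each pick to the y-argmin of a
10-Hz-smoothed copy within a ±1.5% arc window.  The two-stage form is
deliberate: heavier smoothing finds valleys reliably under tremor but
drags their location toward the flatter neighbouring letter, while the
light-smoothed argmin restores the position.  Only y is ever smoothed —
cursive traces contain near-cusps (loop tops, arch peaks) whose
geometry any coordinate smoothing visibly distorts, which is also why
arc-length coordinates are read off the raw polyline.  A trial whose
minima cannot satisfy the separation rule raises a segmentation-failure
error and can carry `manual_boundaries` instead; an unexpected pen lift
inside a word is tolerated (strokes are concatenated in time, making the
lift point a candidate transition).

Sequences segment trivially: one stroke per symbol, delimited by the
first and last pen-down frames.  Fraction times divide each element's
duration by the summed element durations; for sequences the airborne
time between symbols is excluded from numerator and denominator by
default ("time dedicated to an element" is ink-on-surface time, matching
the stroke-based definition of symbol start and end), with
`include_penup = TRUE` available since the opposite convention is also
defensible.

# Tunnel task

`make_geometry()` builds center polylines for circle and square tunnels
and a cursive "ele" word template scaled to a requested amplitude, with
`ID = A/W` exact by construction.  The five default IDs per family
(symbols 8–40, word 6–32, roughly geometric) span comparable difficulty
with even regression leverage; they are fully configurable, as the
deployed difficulty levels are a clinical design choice.

Movement time uses only the central section of an execution, where
steering is stationary: symbols are steered twice around and MT is the
time from progress `0.5 P` to `1.5 P` (one full central lap — equally
the central circle, or the central four of eight square sides); words
are steered once and MT runs from the first crossing of the entry gate
to the last crossing of the exit gate (gates default to 10% and 90% of
the path, configurable, since the exact gate placement at the first/last
letter is a template convention).  Sample-to-path projection unwraps arc
progress with hysteresis — consecutive projections may not jump more
than 25% of the path length — which prevents aliasing where the word
path self-intersects at loops.  Crossing times are linearly
interpolated, so ideal traces recover programmed MTs to well under one
sample period.  Trials with more than 40% of their traced length outside
the borders (midpoint rule, strict inequality, so exactly 40% is
retained) are excluded; incomplete traversals are flagged, never
silently skipped.

Per subject and item, `fit_steering()` runs OLS `MT = a + b·ID`, with
`R² `, `RMSE = sqrt(SSres/n)`, the slope F-test on `(1, n-2)` df, and
`IP = 1/b` defined only for significant fits with positive slope;
`global_MT` is the median MT across all difficulty levels.  With the
default 14 trials per regression (12 residual df), the significance
boundary at α = .05 sits at `critical_r2(12, .05)` ≈ 0.28.

# Statistical battery

All cohort-level tests are nonparametric, suiting the small group sizes
the task targets (n ≈ 15–19): Wilcoxon matched pairs (compliance,
post hocs), Friedman (modality and item effects), Mann–Whitney U
(group contrasts), Bonferroni adjustment over all pairwise post hocs.
The in-package implementations use midranks under ties and exact
p-values below fixed sizes — signed-rank by enumeration of all `2^n`
sign assignments (n ≤ 12), Mann–Whitney over all labelings (pooled
n ≤ 12), Friedman by a convolution over per-subject rank permutations
(≤ 6 subjects × ≤ 4 conditions) — and tie-corrected normal/chi-square
approximations above, so study-sized samples take the approximate path
as any standard package would.  Two-sided exact p-values double the
smaller tail (capped at 1), the same convention `stats::wilcox.test`
uses, and the test suite checks the exact modes against brute-force
enumeration oracles and the approximate modes against base R.  One
boundary case is resolved pragmatically: a design in which every
subject's row is constant returns statistic 0 and p = 1 flagged
`degenerate`, rather than erroring, because an all-tied block design is
an answer ("no evidence of an effect"), not a malformed input.  The
post-hoc pair test is pairwise Wilcoxon signed-rank — the standard
companion to Friedman on paired designs.

# The synthetic generator

`generate_cohort()` emulates the study protocol: 15 primary-school and
19 kindergarten subjects; copy trials for word (primary only —
kindergartners cannot yet write), circle, square, triangle and the
three-symbol sequence under five modalities; tunnel trials on circle,
square and word paths, 14 per subject and item.  Its parameters *are*
the study conditions for every simulation-based check in the package.

- **Speed structure.** Overall trial speed is
  `base_speed × size_factor^β × speed_factor`, with modality factors
  big ×2 / small ×0.5 in size and fast ×1.5 / slow ×0.6 in speed
  (invented defaults, chosen to exceed measurement noise comfortably).
  `β = 1` realises isochrony exactly (duration independent of size);
  `β = 0` is the violation profile (duration scales with size).
- **Within-element profile.** Per-element minimum-jerk speed bells,
  concatenated; minimum-jerk is the standard kinematic stand-in where
  child speed profiles are unspecified.  A constant-speed shape is
  available for calibration fixtures.
- **Homothety.** Element durations follow a fraction template
  (defaulting to template arc shares) perturbed by exchangeable Gaussian
  noise (sd 0.02) and renormalised — so fraction times are
  modality-invariant by construction, and the per-element Friedman
  false-rejection rate is a genuine type-I calibration check.
- **Steering.** Target central-section MTs are drawn from
  `a + b·ID + N(0, mt_noise_sd)` and realised at constant speed with
  lead-in/lead-out at the same speed.  Lateral deviation is an
  Ornstein–Uhlenbeck process (so its stationary sd is directly the
  tremor amplitude), plus optional programmed excursions beyond the
  borders to exercise the exclusion rule.
- **Copy-trial tremor** is white Gaussian noise on coordinates
  (sd 0.3 mm primary, ×1.5 kindergarten).  White positional noise
  inflates a raw polyline's length, and relatively more where the pen
  is slow; this is why measured big/small length ratios sit below the
  programmed factor of 4 (≈ 2.7 at defaults) while all rank-based
  conclusions are unaffected.  Test assertions about positions *along
  the path* therefore use the generator's recorded clean arc coordinate
  as the measuring stick.
- **Group differences** follow the developmental direction expected of
  the steering parameters without claiming magnitudes: kindergarten
  steering slope ×1.8, MT noise ×2, lateral noise ×1.5.  Base speed is
  deliberately equal across groups (spontaneous-speed group contrasts
  are expected null).  Subject-level heterogeneity is lognormal on base
  speed and steering parameters.
- **Determinism.** Identical configuration and seed give byte-identical
  session files.

What the generator does *not* emulate: biomechanical pen dynamics,
handwriting-style variability beyond the template primitives, pressure,
banded (non-white) sensor noise on copy trials, or any empirical
distribution of a real cohort — the magnitudes are conventions, not
estimates.  Passing the simulation checks therefore demonstrates that
the measurement chain is correct and calibrated under its stated model,
not that real children behave like the model.

# Problem sizes and numerical conventions

The simulation-based checks run at the sizes their properties are
defined over: 200 replicates for isochrony detection power (and 200 for
the β = 0 violation profile), 500 for the homothety type-I calibration
and the steering-slope Monte-Carlo, 100 words for segmentation
recovery, 1000 for the Friedman null calibration.  Plumbing tests
(round trips, report rendering) use reduced cohorts of 4–10 subjects,
which exercise every code path at a fraction of the cost.  Tolerances
follow the quantity's own scale: exact identities to 1e-9, single-rate
sampling artefacts to one sample period (0.02 s), simulation rates to
their binomial bands.  Report tables fix floats to six significant
digits so reruns are byte-identical.

# Known limitations

- Letter segmentation presumes the cursive convention that letters join
  at low points; block letters or disconnected cursive need the manual
  boundary channel.
- The fraction-time convention for sequences (exclude pen-up time) and
  the 5%-by-samples trim are documented choices among defensible
  alternatives; both are configurable and both alternatives are
  implemented.
- The steering analysis assumes the trace starts near the path origin
  and follows the instructed direction; free-order steering would need
  a more general progress model.
- Exact Friedman p-values are limited to designs where the permutation
  distribution is enumerable; larger designs use the chi-square
  approximation, which is anti-conservative for very small n (visible
  in demo-sized cohorts, immaterial at the study's n).
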