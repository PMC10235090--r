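---
title: "Models and methods behind vibtrials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vibtrials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibtrials)
```

`vibtrials` analyzes playback trials in which a male insect on a plant
cutting is challenged to locate a shaker playing a female reply while a
second shaker plays interfering vibrations. This vignette documents the
models and conventions the package commits to, the tunable parameters and
their defaults, what the synthetic-trial generator does and does not
emulate, and the design choices made where the underlying protocol leaves
the analysis open.

## The arena as a metric tree

The arena is a plant cutting reduced to six sections — stem above and
below the stem–stalk crossing, two stalks, two leaves — joined at a single
crossing. Defaults are the nominal cutting dimensions: 100 mm of stem on
either side of the crossing, 30 mm stalks, 80 mm leaves (420 mm total).
Each section is divided into 10 equal subsections, because movement is
annotated at subsection resolution ("nearest subsection"), and that
resolution is all the downstream metrics can honestly use. Three
conventions follow:

* **Locations are subsection midpoints**, and all distances are tree path
  distances between midpoints. The default start (apex of the upper stem)
  and target (distal subsection of the ipsilateral leaf) are therefore
  201 mm apart rather than the naive 210 mm: each endpoint sits half a
  subsection in from its section end.
* **The crossing is a zero-length junction**; the first subsection of each
  adjoining section is adjacent to it. The plant has one branching point,
  so the tree has exactly one degree-4 vertex and four free ends.
* **Boundary ties round toward the distal subsection** in
  `nearest_subsection()`; the rule is arbitrary but deterministic and
  documented.

Lateral extent of leaves is ignored (movement across a leaf's width was
not annotated), and no continuous 3-D geometry is modeled.

## Per-trial metrics

Signal sections are annotated intervals labeled Me0–Me3 or `click`. A
maximal run of Me sections with silent gaps strictly shorter than 2 s is
one *signal* if it contains Me3 (the section that triggers the reply) plus
at least one other section; otherwise it is an interrupted *fragment*. A
lone Me3 is a fragment under a literal reading of that rule. Click runs
merge into masking *bouts* under the same gap rule, independently of the
Me runs; a bout's duration is its span, mirroring the annotation practice
of marking an uninterrupted click sequence as one selection.

Total signal duration sums the durations of all marked sections —
Me sections and click bouts — and the duty cycle divides that by the trial
duration. Per-signal composition ratios (e.g. the Me3 share) use the sum
of a signal's member-section durations as the denominator; silent gaps
inside a signal do not count as signal time.

Path metrics replay the trajectory on the arena tree: total and
search-class traversed distance, the starting distance `d_start`, the
closest approach `d_min`, `approach = 1 − d_min/d_start` clipped to
[0, 1] (0 = never closer than the start, 1 = reached the target),
`path_efficiency = d_start / total distance` and
`search_ratio = search distance / total distance`. The printed definition
of approach ("ratio between closest approach and starting distance")
contradicts its own anchor examples; the package follows the anchors,
which are unambiguous. The target counts as found when `d_min` is within
one subsection length of the target's section — the finest claim the
annotation resolution supports. Trials whose male never moved are flagged
`excluded` rather than scored. Note that path efficiency can exceed 1 for
males that moved less than the starting distance; for males that reached
the target it is necessarily ≤ 1.

### Overall efficiency

```
eff = (1 − duty_cycle) / log10(distance / approach)
```

combines signaling economy with localization. Two numerical conventions
make it total:

* **Distance unit.** The stated maximum — eff = 1 for a straight silent
  walk to the target — only emerges if a straight walk corresponds to
  `log10(distance/approach) = 1`. The default unit scale
  (`eff_unit_scale()`) therefore maps the starting distance to 10 formula
  units. A literal-millimeter mode (`unit_scale = 1`) is also provided,
  since the distance unit of the original analysis is not recoverable.
* **Degenerate inputs.** `approach = 0` gives `eff = 0` (the limit as the
  denominator grows without bound). For very short walks where
  `log10(distance/approach) ≤ 0.1` the denominator is floored at 0.1,
  keeping eff finite and positive rather than sign-flipping.

`eff` is monotone — decreasing in duty cycle and distance, increasing in
approach — which the test suite asserts on grids.

## Playback schedules and masking statistics

Treatment timelines are built from the playback design: the reply lasts
10.0 s; the rival masking signal (5.5 s) starts 4.1 s before the end of
the male signal and ends 1.4 s after; the duet reply runs from 1.5 s
before to 8.5 s after the looped male playback's end; the heterospecific
signal (14.9 s) loops with 10 s pauses; anthropogenic noise plays
continuously. Two free conventions are made explicit:

* The manually triggered reply of the non-duet playback treatments is
  anticipated by a configurable offset before the Me3 end (default 1.0 s);
  the operator triggered it on hearing the amplitude diminish, and no
  number is recorded in the protocol.
* The noise loop's phase is 0 at trial start by default and configurable,
  because phase relative to male behavior was uncontrolled.

All intervals are half-open `[begin, end)`: an onset exactly at a noise
offset is *not* in noise. Overlap statistics are purely temporal — no
spectral masking model. `expected_onset_fraction()` is the schedule duty
cycle (≈ 59.8% for the heterospecific loop, the "about 60%" random-onset
expectation), and `coverage_fraction()` averages per-interval overlap
either unweighted (per-trial averaging of reply masking) or pooled by
duration.

## Transmission analysis

At the playback's dominant frequency (430 Hz by default), a stem or stalk
point traces an ellipse in the plane perpendicular to the rod. The
analysis chain is:

1. `complex_amplitude()` — single-bin discrete Fourier projection over the
   largest whole number of cycles, flat window. This is exact for
   noiseless sinusoids over commensurate windows and was chosen for
   verifiability over any particular spectral estimator, since the
   original measurement method is not recorded. Amplitudes are peak, not
   RMS; any consistent convention cancels in dB ratios.
2. `ellipse_axes()` — closed-form semi-axes from the two channel
   amplitudes and their phase difference, with orientation from the
   two-argument arctangent. The identities `a² + b² = Ax² + Ay²` and
   `a·b = Ax·Ay·|sin Δφ|` hold exactly and are asserted in tests against a
   parametric-sampling oracle.
3. `amplitude_map()` — per plant, semi-major amplitudes in dB relative to
   that plant's reference-point recording (leaf points, measured in a
   single plane, use the plain channel amplitude); across plants, an
   arithmetic mean of dB values at equivalent locations. Averaging in the
   dB domain matches how such maps are reported; a linear-domain mode is
   provided as a switch.
4. `gradient_diagnostics()` — per-path strict monotonicity toward the
   source and the Pearson correlation of dB amplitude against path
   distance, quantifying whether the map offers a usable search gradient.

WAV input is read by a minimal uncompressed PCM/float RIFF reader;
CSV sample tables are the equivalent text path. No wave-propagation or
resonance modeling is attempted.

## The synthetic-trial generator

`simulate_trial()` runs an event-driven continuous-time simulation with
exponential waiting times:

* **Signaling** is a renewal process: silent gaps are lognormal
  (default meanlog log 35 s, sdlog 0.6), signal durations normal
  (mean 17.9 s — the average advertisement-signal duration — sd 2.5 s,
  floored at 5 s), split into Me0–Me3 sections by fixed proportions
  (0.05/0.25/0.30/0.40). With probability 0.05 a signal is interrupted
  before Me3 and becomes a fragment.
* **Gap avoidance** thins the onset hazard by a factor γ while the looped
  interferent plays. Thinning (rather than onset displacement) directly
  yields the onset-in-noise statistic: the expected fraction of onsets in
  noise is `γD/(γD + 1 − D)` for noise duty cycle `D`. The default
  γ = 0.23 inverts that relation at `D = 14.9/24.9` against the reported
  pooled onset-in-noise fraction of about a quarter; γ = 1 recovers the
  random-onset expectation and γ = 0 forbids onsets in noise, both of
  which the acceptance suite verifies by Monte Carlo.
* **Replies** follow the treatment's trigger rule from each complete
  signal's Me3 end (duet replies follow the looped playback instead, so a
  silent duet male still hears duets — the precondition for satellite
  behavior). Each reply triggers a search bout with probability 0.8.
* **Movement** is a random walk on the subsection graph: walking steps at
  0.04 steps/s with a persistent heading and a 0.3 per-step reversal
  probability on non-target chains; search bouts (mean 8 steps at
  1 step/s) move directedly, drawing the target branch at the crossing
  with probability `p_correct` (default 0.5 — a coin-flip at the branching
  point, matching the observed near-random junction behavior). Walk and
  search differ only in label and rate; speed itself is not modeled, as
  the metrics only consume class labels.
* **Stopping** follows the trial protocol: 900 s cutoff, or the male
  reaches the target, or leaves the plant (a small hazard, default
  1/3600 s⁻¹), whichever comes first.

`simulate_cohort()` layers lognormal random intercepts for male, plant
and operator (default SDs 0.2, 0.2, 0) on the movement and signaling
rates, applies per-treatment fixed-effect multipliers, tests each male
five times (the protocol's repetition count), and returns the records
plus the tidy metrics table.

**What the generator does not emulate.** Real males respond to amplitude
gradients, show satellite behavior, habituate, and vary far more than a
four-parameter walk; the simulator's males are, for instance, much more
successful at finding the target than real ones, because the ambiguous
transmission gradients that the real arena exhibits are not coupled into
the movement model. Passing tests therefore demonstrate that the pipeline
computes its metrics correctly and that the statistical layer is
calibrated — not that the simulator reproduces real behavioral
distributions. Quantities that depend on unconstrained defaults
(inter-signal intervals, movement rates) are labeled as such.

## The statistical layer

`fit_and_contrast()` fits the full mixed model — treatment fixed, male,
plant, repetition and operator random intercepts — and removes random
terms by stepwise backward elimination, dropping whichever removal most
improves AIC until none does. Two choices deserve note:

* **REML-based AIC for the Gaussian elimination.** All candidate models
  share their fixed effects, which is the setting where REML likelihoods
  are comparable and recommended for selecting the random structure; the
  `lm` endpoint of the path is compared on its REML-type log-likelihood.
  In null simulations, ML-based elimination dropped true random
  intercepts often enough to inflate the familywise error of the
  downstream contrasts several-fold, while the REML path holds the
  nominal 5% level within Monte-Carlo error (the acceptance suite
  measures this on 150 null cohorts with male-level pseudo-treatment
  labels). Binomial models (target finding) use ML deviance AIC, as REML
  has no binomial analogue.
* **Tukey contrasts and letters.** Estimated marginal means and
  Tukey-adjusted pairwise tests come from emmeans on the chosen model;
  the compact letter display is computed in-package by the standard
  insert-and-absorb algorithm on the non-significance graph, so that two
  treatments share a letter exactly when their adjusted p ≥ 0.05.

`rm_corr()` estimates the common within-subject correlation by the
ANCOVA decomposition: regress `y` on subject indicators plus `x`, take
`sign(slope)·sqrt(SS_x/(SS_x + SS_err))`, with `df = N − k − 1` for `k`
subjects, a two-sided t test on that df, and a 95% CI from the Fisher z
transform with `se = 1/sqrt(df − 1)`. Subjects without within-subject
variation in `x` carry no information and are excluded; repetition enters
the mixed models as a random intercept, following the stated model
specification rather than an ordered-factor reading.

## Numerical conventions and problem sizes

* Half-open intervals everywhere; schedule intervals are merged and
  clipped to the trial window on construction.
* Oracle-backed testing: tree distances against an independent
  shortest-path graph search, interval overlaps against 1 ms
  rasterization, ellipse axes against dense parametric sampling with
  local refinement (absolute agreement 1e-6 on 1000 random inputs),
  path metrics against an event-by-event replay on 500 simulated trials,
  and `rm_corr` against explicit centered sums of squares (1e-10 on 100
  fixtures).
* Monte-Carlo suites use fixed seeds and moderate sizes chosen for tight
  statistical bounds at interactive runtimes: 200 trials for the
  onset-in-noise convergence check (3 standard errors), 150 null cohorts
  of 30 males × 5 trials for the familywise-level check, and one 84-male
  cohort (14 per treatment, 5 trials each) for effect recovery.

## Known limitations

* The movement model has no amplitude-gradient coupling, so simulated
  search success is optimistic; treatment effects on search metrics must
  be injected rather than emerging from transmission physics.
* Temporal masking only; a reply fully covered by noise is "masked"
  regardless of spectra or levels.
* The rival treatment's published percent-of-reply-masked figure is not
  reconstructable from the protocol tables and is not used anywhere.
* Compact letters are one minimal cover of the non-significance graph;
  like all letter displays they are not unique.
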