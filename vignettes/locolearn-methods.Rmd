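---
title: "Methods: behavioral quantification of eyeblink conditioning, gait, and split-belt adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral quantification of eyeblink conditioning, gait, and split-belt adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locolearn)
```

## Scope

`locolearn` implements the analysis chain for three linked behavioral
assays of cerebellum-dependent learning in mice:

1. **Delay eyeblink conditioning** in head-fixed mice free to walk on a
   wheel: eyelid video is reduced to normalized closure traces,
   conditioned responses (CRs) are classified per trial, and learning is
   quantified per session — with the animal's locomotor state carried
   along as a trial-level covariate, because walking speed modulates
   both CR amplitude trial-to-trial and the speed of acquisition across
   sessions.
2. **Overground gait quantification**: paw tracks are segmented into
   strides and summarized by the standard individual-limb and interlimb
   parameter suite, swing-trajectory averages, coefficients of
   variation, and a z-score → PCA → LDA discriminant mapping.
3. **Split-belt treadmill adaptation**: per-trial asymmetry series
   (fast − slow) reduced to initial error, change over the split
   period, and aftereffect, plus percent-adaptation normalization,
   stance-speed compliance checks and mixed-model group comparisons.

A synthetic-data module generates every input with known ground truth,
so the entire chain is exercised and calibrated without animal data.

## Eyeblink conditioning

### Trial structure

An acquisition session presents 100 CS–US paired trials and 10 CS-only
trials, separated by inter-trial intervals drawn uniformly from 5–20 s.
The CS precedes the US by a fixed inter-stimulus interval (ISI) of
300 ms (500 ms variants supported), and the two stimuli co-terminate:
with a 50 ms air-puff US the CS therefore lasts 350 ms. Eyelid video is
sampled at 900 Hz.

### From video to closure

`extract_eyelid_distance()` binarizes each frame (Otsu's threshold by
default, with a manual override since acquisition conditions vary),
keeps the largest connected component, and takes the full minor axis of
the ellipse fitted to that component by its second-order pixel moments.
The moments fit is closed-form and deterministic: for a filled ellipse
the pixel-coordinate covariance eigenvalues are $(a/2)^2$ and
$(b/2)^2$, so the axes are recovered as $4\sqrt{\lambda}$. The minor
axis is rotation-invariant by construction. A frame with no foreground
(or a degenerate, sub-pixel component) is reported as distance 0 with a
closed-eye flag rather than an error, since full blinks produce exactly
this picture.

`normalize_session()` maps distances to closure
$c = (d_\mathrm{open} - d)/(d_\mathrm{open} - d_\mathrm{closed})$,
clipped to $[0,1]$, with anchors shared across a session. The anchors
are percentiles rather than extremes — the 1st percentile of all frame
distances for the full-blink anchor (every paired trial contains a full
blink) and the 97.5th percentile of pre-CS baseline distances for the
open-eye anchor — because single-frame tracking glitches otherwise
corrupt the whole session's scale. The percentiles are exposed as
arguments; explicit anchors bypass the rule entirely.

### CR classification and learning curves

A trial is a CR if closure reaches **at least 0.1** normalized units
inside the response window. The window opens 100 ms after CS onset
(inclusive) — earlier responses are reflexive or spontaneous, not
anticipatory — and closes at US onset (exclusive), so that the
US-elicited reflex blink can never be counted. On CS-only trials there
is no US to mask the response, and the window extends through the time
the US would have occupied (CS + ISI + US duration, inclusive); these
trials also report the CR peak time, which for well-timed CRs sits near
the ISI. Amplitude is the window maximum whether or not it crosses
threshold.

Session-level summaries are %CR and mean CR amplitude. The %CR
denominator includes all CS-bearing trials (paired and CS-only): both
types are classifiable and the assay does not distinguish them for this
purpose. The **learning onset** is the first session whose mean CR
amplitude strictly exceeds 0.1.

### Locomotor state

`locomotor_state()` integrates wheel speed over the trial
(trapezoidal rule) for distance, takes the time-averaged speed, and
calls a trial **stationary** iff mean speed < 0.05 m/s (strict;
0.05 m/s itself is ambulatory). The fraction of time walking uses a
0.01 m/s instantaneous threshold — low enough to count slow locomotion,
above sensor noise; it is a config value, as no principled constant
exists. The 150 m/session value used to split animals into low/high
activity groups is likewise exposed as an argument.

### Statistical contracts

Trial-level amplitude–speed coupling is estimated with
`fit_speed_amplitude_mixed()`: a random-slopes, random-intercepts
linear mixed model (`amplitude ~ speed + (1 + speed | mouse)`) with the
fixed slope tested by an F test with Satterthwaite degrees of freedom.
A single-mouse table degrades to OLS with a warning rather than a
random-effects fit that cannot be identified. Per-animal onset-session
versus mean-distance relations use `robust_onset_vs_activity()` —
bisquare-weighted IRLS (tolerance 1e-8, at most 50 iterations), with an
exact-OLS shortcut when the residual scale is numerically zero (the
IRLS weights are undefined there). Group-by-phase comparisons of
adaptation metrics use a mixed model with animal as a random effect and
Tukey-corrected post-hoc contrasts, one observation per animal per
level.

The calibration of the mixed-model contract is measured against
`sim_mixed_trials()`, which generates the matching data-generating
process exactly (Gaussian random intercepts/slopes, i.i.d. noise). The
test suite checks 95% CI coverage of a known slope (0.5 closure per
m/s, 10 mice × 200 trials, noise SD 0.05) over 100 seeded cohorts and
the null rejection rate over 500 replicates of 10 mice × 50 trials; the
smaller null cohorts keep the 500-replicate sweep proportionate while
preserving the per-mouse replication the test depends on.

## The synthetic eyeblink cohort

No quantitative acquisition model exists for this assay, so the
generator's dynamics are a deliberately minimal stand-in, not a claim
about biology: a latent learning state $L \in [0,1]$ grows on every
paired trial by logistic increments
$\Delta L = g\,(1 + w\,v)\,L(1-L)$, with gain $g$
(`acquisition_gain`), speed weight $w$ (per m/s) and trial speed $v$.
This is the smallest model producing the qualitative structure the
analyses must detect: faster-walking animals accumulate learning
faster, hence earlier onset sessions. Trial amplitude is
$L\,(a_0 + \beta v)$ plus Gaussian noise, clipped to $[0,1]$, giving
the trial-level amplitude–speed coupling ($\beta$,
`speed_amplitude_slope`). Each mouse's characteristic speed is drawn
from its group's activity distribution (defaults 0.04 and 0.12 m/s,
a hypoactive and a control-like group, SD 0.02 m/s); trial speeds
scatter around it (SD 0.04 m/s, truncated at zero).

Default dynamics parameters ($g = 2\times10^{-4}$, $w = 10$,
$a_0 = 0.4$, $\beta = 1$, noise SD 0.05) place learning onset around
sessions 7–12 of a 20-session, 100-paired-trial acquisition — the
realistic range for this preparation — with the control-like group
onsetting several sessions earlier than the hypoactive one. Rendered
traces carry a Gaussian CR ramp peaking at the would-be US time and, on
paired trials, a UR plateau at 1.0 (the normalization's full-blink
anchor) starting 10 ms after US onset.

What the generator does **not** emulate: spontaneous blinks, session
drift of tracking quality, oculomotor artifacts, correlated
within-session speed dynamics, or any particular acquisition time
course beyond monotone saturation. Passing recovery tests therefore
show the analysis chain is correct and calibrated on its design
assumptions, not that real data meet those assumptions.

## Gait kinematics

### Synthetic gaits and stride segmentation

`gen_gait_session()` renders periodic quadruped tracks: during stance a
paw is on the ground (stationary overground, moving backward at belt
speed on a treadmill), during swing it returns forward with a half-sine
vertical lift; phases, duty factor, stride duration, body width and
step height are configurable, and the closed-form per-stride parameters
implied by a configuration are available from `gait_expected_params()`
as the oracle for round-trip tests.

`segment_strides()` detects touch-downs as local maxima of the paw's
forward position relative to the body center, and lift-offs as local
minima. "Simple peak detection" needs two guards to be robust:
candidate peaks must have a topographic prominence of at least 20% of
the signal excursion (so tracking noise cannot create strides), and
peaks closer than half the median inter-peak interval are pruned,
keeping the higher (so a jittered apex cannot split a stride). Events
are then forced to alternate; of two same-type neighbors the more
extreme survives. A constant track yields zero strides — an empty
result, not an error — while NaNs are an error, since silent
propagation would corrupt every downstream parameter.

### Parameters

Per-stride individual-limb parameters follow their defining
arithmetic: stride duration between consecutive stance onsets, cadence
its inverse, duty factor stance/stride duration, stride length the
touch-down-to-touch-down forward displacement, swing velocity the
swing displacement over swing duration. On a treadmill, displacements
default to the **ground (belt-compensated) frame** — adding
belt speed × time to x — because that is the frame in which treadmill
and overground stride lengths are comparable (`frame = "belt"` gives
raw treadmill-frame values). Interlimb parameters: step length (paw
minus contralateral homolog at the paw's stance onset), stance phase
((stance time − reference stance time)/stride duration, wrapped to
[0, 1), reference FR — the only dimensionally sensible reading of the
conventional formula), base of support (lateral front-pair and
hind-pair widths during stance), double support (touch-down of a paw to
contralateral lift-off, as % of the stride), and center of oscillation
(midpoint of stance- and swing-onset positions relative to the body
center, hence translation-invariant like everything else).

Support categories are computed per frame from paw–ground contact,
defined as z below 1 mm (configurable; contact is a measurement on z,
so near lift-off and touch-down a swing paw at sub-threshold height
still counts as contact — an intended property of a height-threshold
definition, visible as slightly longer contact than kinematic stance).
Reported categories are 3-paw, 2-paw diagonal, and 2-paw non-diagonal;
4-, 1- and 0-paw configurations fall in an `other` bucket so the
categories partition every frame of the stride.

Swing trajectories are aligned to swing onset, linearly resampled to
100 points, averaged within speed bins (stride speed = stride
length/duration), and smoothed with a first-order, 3-point
Savitzky–Golay filter — which on interior points is exactly the
3-point moving average, an identity the tests pin down. Variability is
reported as coefficients of variation (sd/mean; undefined and an error
at zero mean).

### Discriminant mapping

`discriminant_map()` z-scores the feature table, performs PCA by
eigendecomposition of the covariance matrix (after z-scoring the
eigenvalues sum to the number of retained features — a test invariant),
keeps the leading 10 PCs by default (PCA first, because LDA on
correlated features overfits), runs LDA on the scores, and back-projects
feature contributions as the product of the PCA and LDA mappings.
Constant features are dropped with a warning; retaining at least as
many PCs as observations is an error.

## Split-belt adaptation

Two protocols are built in, exactly as designed: a single-session
protocol (2 tied + 8 split + 8 tied one-minute trials, split speeds
0.175/0.375 m/s — a 2.14:1 ratio) and a five-session protocol (10
trials per day: 3 tied + 7 split; 10 split; 10 split; 3 split + 7
tied; 10 tied, at 0.125/0.275 m/s split and 0.2 m/s tied). The
single-session tied speed is not part of the printed design; the
midpoint of the split speeds (0.275 m/s) is used so that the average
belt speed is continuous across the split transition.

The generator follows the classic single-rate exponential picture:
asymmetry jumps to `initial_error` at split onset and decays by a
fraction $r$ per trial, so split trial $i$ sits at
$e_0 (1-r)^{i-1}$ and the change over $n$ split trials is
$e_0\,[(1-r)^{n-1} - 1]$; on washout an aftereffect of opposite sign,
`retention` times the adapted amount, decays at the same rate. Phase
metrics use strictly the first/last split trial (not averages), and the
aftereffect is the first washout trial **minus the baseline mean** —
the definition that makes a zero-drift series yield a zero aftereffect;
the plain first-washout-trial variant is available via
`aftereffect_baseline = FALSE`. Percent adaptation normalizes by the
group-mean initial error as a ratio of magnitudes, after the
conventional sign inversion that makes all three epochs comparable;
100% is complete adaptation, and the percentage is invariant to
relabeling fast/slow.

Stance-speed compliance checks that animals actually walked the
imposed speeds: per split trial, each side's stance speed (mean |x
velocity| during stance, treadmill frame) must match its belt speed
within ±20% on at least 80% of split trials — both thresholds are
arguments, as no standard numeric criterion exists.

## Numerical choices and degenerate inputs

- Window boundaries: lower bounds inclusive, US-onset bound exclusive,
  with a 1 ns slack against floating-point drift of sample times.
- Thresholds: "at least 0.1" means attaining the threshold counts;
  onset requires strictly exceeding 0.1; stationary is strictly below
  0.05 m/s.
- Empty speed bins and paws without strides are reported as missing,
  never as zero.
- Constant sessions (no eyelid dynamic range), zero-mean CV inputs,
  zero group initial error, single-trial sessions and missing protocol
  phases are errors that name the offending quantity.
- All generators are deterministic functions of their seed; identical
  configurations give byte-identical outputs.

## Problem sizes in the test suite

The packaged tests run the full chain at sizes chosen to make every
check sharp but quick: gait round trips use 3 s sessions at 1 kHz
(8–10 strides per paw, quantization one frame period); split-belt
recovery uses the 18-trial protocol across 100 seeds; mixed-model
calibration uses 100 cohorts of 10 × 200 trials (coverage) and 500 of
10 × 50 (null rejection); the activity→onset property uses 100 cohorts
of 2 × 4 mice × 14 sessions × 22 trials with a proportionally larger
gain (0.015) so learning completes within the shortened acquisition.
The defaults of the generators themselves remain the full-scale designs
described above.

## Known limitations

- The acquisition dynamics are a stand-in; parameter estimates from
  fits to real data should not be interpreted through this model.
- The eyelid extractor assumes a pre-cropped eye ROI and a single
  bright eye region; it does no eye detection or ROI tracking.
- Paw tracking itself is out of scope; the gait module consumes tracks.
- The percentile normalization anchors assume each session contains
  full blinks (true when paired trials are present); CS-only-only
  sessions need explicit anchors.
- HDF5 containers are not supported; all I/O is CSV/YAML (one trace
  per trial, wide CSV for tracks).
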