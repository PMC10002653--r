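---
title: "Quantifying long-term larval crawling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying long-term larval crawling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(larvawalk)
```

`larvawalk` quantifies multi-hour crawling behavior of *Drosophila*
larvae in robot-assisted arenas, and simulates such experiments so that
every analysis stage can be validated against ground truth. This
vignette documents the underlying models, the tunable parameters and
their defaults, the numerical choices, and what a passing test does and
does not establish.

## The locomotion model

Larval exploration is modeled as a run-and-turn random walk observed at
the camera frame rate (10 Hz, 22 × 22 cm arena, millimetre coordinates
with the origin at the lower-left corner, y up, warm direction +x).

**Runs.** The animal advances along its heading at the current crawl
speed, with Gaussian heading diffusion of `heading_diffusion`
(default 2 deg/√s). Crawl speed starts at `base_speed` (0.55 mm/s) and
declines linearly at `speed_decline_rate` (−6.9 × 10⁻⁵ mm/s²) for the
first hour, then stays at the plateau (≈ 0.30 mm/s), floored at
`min_speed` (0.1 mm/s). The piecewise-linear decline matches the
reported first-hour slope followed by a plateau; the base and floor are
package choices consistent with larvae crawling "well below 1 mm/s".

**Turns.** Turn initiation is a Poisson process at `base_turn_rate`
λ (2 events/min), thinned per frame as `1 − exp(−λ_eff dt)`. A turn
rotates the heading by a drawn size over `turn_duration_s` (2 s) with
translation reduced to `turn_translation_frac` (10%) of run speed. Turn
sizes are |Gaussian| with mean 60°, sd 30°, truncated to [20°, 180°];
the distribution's family is a package choice (only its qualitative
range is documented for real animals), and every parameter is exposed.
Turn direction is left (counter-clockwise) with probability
`handedness_bias` (0.5). During a turn the body bend follows a
half-sine head-cast profile with peak `head_cast_amplitude_deg` (60°)
*independent of the eventual heading change* — real head casts are
large even when the resulting reorientation is small, and this is what
makes small turns detectable at all in a 30-pixel animal.

**Thermotaxis.** Cold avoidance is implemented as pure klinokinesis:
`λ_eff = λ (1 + g · max(0, −cos ψ))` where ψ is the angle between the
heading and the warm axis, so the turn rate is elevated while crawling
toward the cold side and unchanged otherwise. No weathervaning and no
turn-direction bias are modeled — turn-rate modulation is the one
mechanism the source experiments explicitly implicate, and the simplest
that produces warm-ward drift. The gain `thermotaxis_gain` was
calibrated once (12 animals × 1 h per candidate gain) so that g = 1
yields a population navigation index ≈ 0.13 under the default gradient,
matching the scale reported for real larvae; g = 0 disables taxis.

**The thermal field** is affine along its axis: 0.035 °C/mm, centred at
17 °C (so a 220 mm arena spans roughly 13–21 °C). The steepness is
reported inconsistently at the source (0.035 vs 0.032 °C/mm, and the
endpoint values imply 0.036); 0.035 is the default and any value is
accepted.

**The transport robot** triggers when an animal enters the
`edge_margin_mm` band (15 mm; the trigger distance is not documented —
this is a package choice). Pick-up succeeds per attempt with
probability 0.90 (drop-off 0.95); after `perturb_after` failures the
probability is nudged up by `p_boost` per attempt, modeling the
controller's self-recalibration, and `max_attempts` failures leave the
animal in place with a logged failure — it is never silently lost. A
successful manipulation transports the animal to the arena centre
(Gaussian scatter, sd 2 mm), randomizes its heading (it is rolled off
the nozzle), and drops `occlusion_s` (10 s; not documented, exposed) of
frames because the arm occludes the camera — the *entire* frame is
dropped, so co-housed animals gap simultaneously. Scheduled feeding
(hourly, when enabled) pauses the trajectory for `feed_duration_s`;
whether feeding perturbs locomotion beyond the pause is not quantified
anywhere, so the simulator only pauses.

**Random streams.** Each animal owns a behavior stream and a controller
stream derived from the experiment seed, so adding animals never
perturbs existing trajectories, and identical seeds reproduce
trajectories, events and frames bit for bit.

## Rendering and tracking

A 1 mm larva at 0.1 mm/px is an elongated cluster of ≈ 30 uniformly
bright pixels: the renderer stamps a fixed half-width (1.2 px) band
along a midline bent at its midpoint by the bend angle, and represents
the 2200 × 2200 frame sparsely (only lit pixels are stored); frames
export as plain-text PGM. Any shape model producing ≈ 30 px elongated
clusters would serve equally.

Detection is connected components (8-connectivity) above an intensity
threshold, gated to [`min_area`, `max_area`]; centroids are
intensity-weighted. Identity linking is greedy minimum-distance
assignment within a 3 mm gate (≈ 6× the per-frame displacement at
0.5 mm/s — generous but far smaller than inter-animal distances), with
ties broken deterministically toward the lower animal id. The animal
count is fixed at the first frame; a lost track reclaims the nearest
leftover detection without a gate, which is what re-acquires an animal
the robot has just relocated 100 mm away. Touching animals merge into
one blob; a detection larger than 1.6× the running median area is
attached to every gated track at frozen offsets and flagged `contact`.
How the real system maintains identity through contact is not
documented; freeze-and-flag is a declared substitute that prevents
identity swaps at the cost of positional accuracy during contact.
Detection gaps up to `max_gap` (150 frames, spanning a 10 s occlusion)
are bridged by linear centroid interpolation and flagged; longer or
boundary gaps become flagged track breaks.

## Posture

The learned posture network of the original pipeline is replaced by a
classical equivalent that reproduces its two stated design intents —
use of temporal information and a cost on head/tail flips — without
claiming numeric parity: Zhang–Suen thinning of the crop, the
skeleton's longest geodesic path as the midline (tips re-extended into
the mask to undo thinning erosion), resampled to 11 points with the
central point anchored at the bend apex. The bend angle is 180° minus
the interior angle between the midpoint→head and midpoint→tail chords
(straight = 0); it is invariant to rigid motion. At this resolution the
recovered bend is accurate to roughly ±15° for moderate bends and
saturates for deep folds (> 100°), where the two body arms begin to
merge in the mask.

Head/tail assignment maximizes, per frame, the projection of the
head−tail axis onto the smoothed centroid velocity, minus
`flip_penalty` when the orientation would flip. The penalty defaults to
3× the median per-frame motion evidence, so one corrupted frame can
never flip an established orientation, but persistent contrary evidence
(a real reversal of the axis) flips it after a few frames. Below
`v_min` (0.05 mm/s) motion evidence is ignored and the prior
orientation is retained; a stationary sequence start defers orientation
until the first informative frame and back-fills.

## Run/turn classification

The learned bidirectional state classifier is likewise replaced by a
symmetric-window rule on the two cues it is described as using: path
bends (smoothed absolute heading rate from positions) and head swings
(body bend). A frame is a turn candidate when the heading rate is
≥ 20 deg/s or the bend is ≥ 30°; candidates grow in both directions
while the rate stays ≥ 10 deg/s or the bend ≥ 15° (hysteresis). All
series are centrally smoothed (11 frames = 1.1 s), so labels are a pure
function of a symmetric window and time-reversing a track exactly
reverses its labels. Thresholds were chosen to recover ≥ 90% frame
agreement on the default simulator and are all exposed; downstream
statistics should always be reported together with them. Frames
contaminated by excluded data (dropped, interpolated, contact, feeding)
are masked, and the mask is dilated by the smoothing window — a robot
relocation otherwise leaves an arbitrarily large apparent heading rate
in the adjacent frames and would be scored as a turn.

Turn size is the magnitude of the wrapped difference between the
circular mean headings over the second after and the second before the
segment; positive (counter-clockwise, y-up) differences are left turns,
an exact 180° tie breaks left (probability zero under continuous
headings, logged convention). Turns without a clean 1 s run flank keep
their segment but carry missing size/direction.

## Features

Speed, heading and curvature come from boxcar-smoothed (1.1 s)
centrally differenced positions; curvature |dθ/ds| is missing below
`v_min`. The navigation index is the ratio of means ⟨v_x⟩/⟨v⟩ — not a
mean of per-frame ratios — over frames at or above `v_min`, matching
its defining formula; a runs-only switch exists because whether turn
frames enter the published index is unstated (the default includes
them). Time-binned population summaries use the animal, not the frame,
as the statistical unit (10 min bins by default; the source bin width
is unstated). The peri-event analysis t-tests each post-event minute
against the pooled pre-event baseline with no multiple-testing
correction, mirroring the single-comparison usage it reproduces — a
deliberate, flagged choice, so a correctly sized test still flags ≈ 5%
of effect-free minutes. Stitching translates each post-drop-off
sub-path rigidly onto the pre-pickup end point; path length sums only
genuine crawl displacements and is invariant under the stitching
translations.

The optional shared "activity" latent (Ornstein–Uhlenbeck, off by
default) modulates speed and turn rate with log-normal multipliers of
log-correlation ρ, for studying speed/turn-rate coupling. Two caveats
established during validation: binned turn rates carry Poisson counting
noise that attenuates the measured correlation (≈ 10% at 30 turns per
bin), and correlation recovery needs the latent timescale to be short
relative to the observation window so that enough independent bins
exist — the coupling test uses τ = 5 min against 10 min bins over 8 h,
and correlates *run-frame* crawl speed (turn frames dilute binned speed
and induce a spurious negative coupling with turn rate).

## Variability and bimodality

The hierarchical observation model draws each animal's latent mean from
the inter-animal law — a Gaussian (sd `sigma_inter`) or, for the
bimodal regime, a 50/50 mixture at μ_pop ± Δ with Δ = 2σ_intra — and
then Gaussian observations around it (sd `sigma_intra`). Defaults
(40 animals × 100 observations, σ_intra = 0.15, σ_inter = 0.03) are
scaled to a navigation-index-like observable: high within-animal and
low between-animal spread in the unimodal regime, well-separated
per-animal means in the bimodal one.

Sarle's bimodality coefficient uses the bias-corrected sample skewness
and excess kurtosis; the uniform distribution attains the critical
value 5/9 (the asymptotic form on exact uniform moments equals 5/9
exactly), a Gaussian gives 1/3 and a symmetric two-point distribution
approaches 1. BC is computed on per-animal summary values (one number
per animal): the phenomenon of interest is the distribution of
per-animal means, which can be bimodal while the pooled population
distribution stays broad and unimodal; an all-observations mode exists.
The source reports a significant BC increase without naming a test, so
significance here is a label-permutation p-value with a case-resampling
bootstrap CI — a package choice. BC is moment-based and unstable below
about 8 animals per condition, which attaches a warning rather than an
error. (The source text calls the statistic a "binomial coefficient";
the 5/9 critical value identifies it unambiguously as the bimodality
coefficient, and the name is treated as a typo.)

## What the synthetic world does and does not establish

The simulator realizes the stated experimental conditions (arena, frame
rate, gradient, decline slope, robot success rates, ≈ 30 px animals)
with package-chosen values where none are stated, as documented above.
A green test establishes that the pipeline recovers the generative
parameters of *this* world — Poisson turn statistics, rigid-body
rendering, white heading diffusion — within stated tolerances. Real
video differs in ways the generator does not emulate: non-uniform
illumination and background texture, peristaltic body-shape dynamics
within runs, pauses and reversals outside the run/turn dichotomy,
larva–larva interaction, and developmental drift beyond a linear speed
decline. Headline real-data values (navigation indices 0.032/0.130,
BC 0.48/0.67, correlation 0.572) therefore serve only as calibration
scales, never as test targets.

## Numerical choices

Headings are degrees in (−180°, 180°], unwrapped before smoothing;
smoothing is a centred boxcar with edge replication (symmetric, so
time-reversal symmetry is exact); differentiation is central with
mirrored one-sided stencils at the ends. Interpolation across gaps is
linear and exact for linear motion. Histograms for occupancy
distributions default to 41 equal bins over the pooled range. The
trajectory CSV serializes numbers at 17 significant digits so
write-then-read is the identity; the flat TOML config round-trips
losslessly; every pipeline output embeds an FNV-1a hash of the
configuration and the seed.

## Known limitations

Deep bends (> ≈ 100°) are under-estimated at 30 px resolution. The
tracker's contact handling freezes positions rather than resolving
them. The classifier cannot see turns whose head cast and heading rate
both stay below threshold (by design, none exist in the default world).
The peri-event test inherits the 5% per-minute false-positive rate of
its uncorrected design. The renderer's PGM export is per-frame;
multi-page containers are out of scope in a text-only deliverable.
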