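---
title: "Methods: quantifying collective motion in small shoals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying collective motion in small shoals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalkit)
```

shoalkit analyses the collective motion of small groups of individually
tracked fish — the motivating system is groups of four female guppies
swimming in an annular arena, filmed at 25 fps and tracked to per-frame
(x, y) coordinates — and compares treatments (familiar versus unfamiliar
group-mates) across two sampling periods with repeated-measures mixed
models. This vignette documents the models and statistics, the choices
made where conventions were genuinely open, and what the bundled simulator
does and does not emulate.

## From positions to kinematics

Trajectories enter as either idTracker-style text exports or a tabular CSV
(`frame,id,x,y`, frame 0-based), are scaled to millimetres at read time,
and all downstream arithmetic is in mm and seconds. Tracking gaps
(occlusions) are carried as an explicit mask; runs of at most `max_gap`
frames (default 5, i.e. 0.2 s at 25 fps) flanked by valid fixes are
linearly interpolated, longer runs stay missing. Interpolating only short
runs keeps occlusion artefacts from fabricating behaviour; the cap is
configuration, not inference.

Velocities use central differences by default,
$v_k = (x_{k+1} - x_{k-1})\,\mathrm{fps}/2$, with one-sided differences at
the trial ends. Central differencing halves high-frequency tracking noise
relative to forward differences at the cost of a known chord-factor bias on
curved paths ($\sin(\omega\Delta t)/(\omega\Delta t)$ for circular motion at
angular rate $\omega$) — negligible at 25 fps for fish-scale turning rates.
No smoothing is applied by default; an optional centred moving average is
available but off, since any smoother also attenuates genuine turns.

Headings are unit velocity vectors, and a heading is only accepted when the
speed is at least `min_heading_speed` (default 1 mm/s): the direction of a
near-zero velocity is tracking jitter, and letting it through corrupts every
orientation statistic downstream. Speeds themselves are kept wherever the
velocity is computable, whether or not the heading threshold is met —
discarding slow frames from the speed statistics would bias the median
upward, so the package carries two validity masks (`speed_valid` for
speeds, `valid_mask` for headings).

## The three response variables

**Polarization.** Per frame, $P = \lVert \sum_i \hat h_i \rVert / m$ over
the $m \ge 2$ fish with valid headings — the mean resultant length of unit
headings, the standard order parameter of collective motion, 1 for a
perfectly aligned group and 0 for directions that cancel. Frames with fewer
than two valid headings are skipped, not zero-filled; every usable frame of
a sampling window contributes to the window mean. For reference, four
independent uniform-random headings give $E[P] \approx 0.45$, so values
near 0.45 mean "no alignment", not "half-aligned".

**Nearest-neighbour distance.** Per fish and frame, the Euclidean distance
to the nearest other fish with a valid fix; the per-fish time average is the
cohesion measure. A fish's frames are averaged only when that fish and at
least one other are fixed, which keeps occlusion gaps from biasing the mean.

**Median speed.** Per fish, the median of its valid frame speeds. The
median, not the mean, because individual speed distributions are positively
skewed — bursts inflate a mean but barely move a median.

## Pairwise directional correlation and focal alignment maps

For every unordered pair and frame where both fish carry headings, the
directional correlation is $r = \hat h_a \cdot \hat h_b = \cos\Delta\theta$,
recorded with the pair's mutual speed (the mean of the two speeds) and
distance. Observations are binned on a half-open speed × distance grid
(default 0–200 mm/s × 0–200 mm in steps of 10) and averaged per cell;
observations beyond the outer edges are counted in an overflow tally so the
grid conserves mass. This is the zero-lag statistic; leader–follower delays
are out of scope.

For the focal-frame maps, every fish serves as focal in turn: the world is
translated and rotated so the focal fish sits at the origin heading along
+x, and each partner contributes its relative position and heading
difference $\Delta\theta \in (-\pi, \pi]$. Per spatial cell (default
−100..100 mm, 10 mm cells) the package reports the circular mean of
$\Delta\theta$ (the arrow field) and its mean resultant length $R$ (the
alignment surface). $R$ per cell is, by construction, exactly the
polarization operator applied to that cell's angle set — the suite asserts
this cross-module identity to 1e−12. Ordered pairs are pooled across fish,
frames and trials of a treatment × period; sampling one focal per frame
would only thin the data without changing the estimand.

Cells with fewer than 10 observations are reported as undefined in exports
and plots — a handful of angles gives a noise-dominated mean — but the
underlying grid object keeps every non-empty cell so that export masking is
a presentation choice, not a data loss.

## Repeated-measures inference

The group-level response (mean polarization) is fitted with
`nlme::lme(polarization ~ familiarity * period, random = ~1 | trial)`
(REML), familiarity being the between-subjects factor and sampling period
the within-subjects factor. Individual-level responses (median speed, mean
NND) add individual nested in group:
`random = ~1 | trial / fish`, and are fitted on the natural-log scale —
both are positively skewed on the raw scale, and the log is declared here
as the transform convention. Non-positive values are a data error, named
row by row.

Denominator degrees of freedom follow nlme's containment method, which for
the reference design (12 groups × 2 periods; 4 fish per group) gives df =
10 for every term of the group model and df = 10 (familiarity) / 46
(within-individual terms) for the individual models — matching the
published analyses this package re-implements. t statistics are reported
signed; confidence intervals come from `nlme::intervals` on the fitted
scale and are deliberately not back-transformed (the back-transformation
convention in the source material is ambiguous, so the package reproduces
estimate/t/df/p and leaves CI-scale reconciliation to the analyst).
Reference levels are `unfamiliar` and `period1`, so the familiarity
estimate is the familiar-minus-unfamiliar difference in period 1.

Normality is checked per cell with Shapiro–Wilk plus exported Q–Q data, and
variance homogeneity with the median-centred (Brown–Forsythe) Levene test.
Multiplicity over the nine tests of the three models is controlled with the
Benjamini–Hochberg step-up procedure at q = 0.05, treating the nine as one
family; a "<0.001" entry is encoded as 0.0005 for the decision, which is
insensitive to any encoding at or below 0.001. A degenerate, exactly
constant response returns zero effect estimates with undefined standard
errors and a warning rather than an optimizer failure.

## The shoal simulator

The simulator exists so every stage of the pipeline can be exercised,
calibrated and power-checked without the original recordings. It is a
kinematic (speed-prescribed) agent model, not a mechanical one — the
analyses only consume positional and heading statistics.

Per frame and fish, a desired direction is the sum of the fish's current
heading (persistence, weight 1), `alignment_weight` times the mean heading
of neighbours within `interaction_range`, and an attraction term toward the
neighbour centroid whose strength ramps with the centroid distance and
scales with `(1 + alignment_weight)` — the zonal-model device that pulls a
spreading group back together before it fragments, however strong the
alignment signal. The heading turns a fraction `turn_rate` of the way
toward the desired direction, then wall avoidance takes over near either
wall of the annulus: within `wall_zone` (20 mm) the fish is steered toward
a blend of the wall tangent (in its direction of travel) and the escape
normal, with a weight that ramps to full override at the wall. Steering
along the tangent rather than the raw inward normal lets an aligned group
curve along the channel instead of being scattered by reflections — with a
pure normal-sum formulation, wall encounters at high alignment weights
actually *reduce* group polarization, inverting the parameter's meaning.
Finally the heading receives wrapped-normal noise (`heading_noise_sd`
rad/step) and the fish steps by a per-frame lognormal speed draw; any step
that would leave the annulus is reflected.

Defaults encode the reference conditions and were fixed once on realism
grounds: 4 fish; annulus radii 135/330 mm (a 195 mm channel); 25 fps;
5-minute windows; lognormal speeds with median 60 mm/s (about two body
lengths per second) and log-sd 0.5, giving the positive skew real speed
distributions show; alignment 0.5, attraction 0.2, noise 0.5 rad/step,
interaction range 100 mm (~3 body lengths, so correlation decays with pair
distance as observed in real shoals); gap rate 0.005/frame to mimic
occlusions. Groups start clustered at a random channel location, mirroring
release from a holding cylinder — scattered starts let subgroups circulate
independently, an artefact the release protocol excludes. Under these
defaults an unfamiliar group polarizes at ~0.67, NND sits near 50 mm, and
the familiarity increment (`familiarity_alignment_delta = 0.5` on the
alignment weight) raises polarization by ~0.15, the same order as the
published familiar-versus-unfamiliar contrast.

Study-level simulation derives one seed per trial × period from the master
seed (a fixed integer hash, kept below $2^{31}$), so studies are exactly
reproducible while trials stay independent; period-2 segments can be
regenerated with per-parameter multipliers (e.g. a habituation-like decline
in alignment).

What the simulator does **not** emulate: body shape and collision
avoidance, vision-cone occlusion, hydrodynamic interaction, identity-swap
tracking errors, and — importantly for inference — between-group
heterogeneity beyond sampling noise: every simulated group of a treatment
shares one parameter set, so simulated group-to-group variance is smaller
than in real data and simulated t statistics are correspondingly larger.
Passing recovery and calibration tests on this generator therefore
demonstrates that the pipeline measures what the model injects, not that
real guppy shoals satisfy the model.

## Problem sizes and numerical conventions

The test suite runs the replicate-heavy calibrations on reduced problem
sizes chosen to keep the whole suite comfortably interactive: 24 s sampling
windows for the 200-replicate familiarity-recovery check and the
1000-replicate null calibration of the familiarity test (rejection rate
~5% at q = 0.05), and 60 s windows for the 20-seed-per-level monotonicity
check of polarization against alignment weight. The calibrated expectation
used by the recovery check is recomputed from independent single-trial
simulations at the same window length, never hard-coded.

Other conventions: angles wrap to $(-\pi, \pi]$; all bins are half-open
$[a, b)$; binning agreement is asserted against brute-force oracles
exactly, circular statistics against a direct unit-vector sum to 1e−12;
rigid-motion invariance of polarization and of the focal maps is asserted
to 1e−12 (1e−9 where a rotation matrix enters twice); trajectory CSVs are
written with 17 significant digits so a write → read round-trip is
bit-exact.

## Known limitations

Beyond the simulator's idealizations listed above: the package does not
re-implement video tracking (idTracker output is the interface); it offers
no probability-based track repair, no time-lagged correlation analysis, no
convex-hull or centroid-speed metrics; and confidence intervals for the
log-scale models are reported on the fitted scale only.
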