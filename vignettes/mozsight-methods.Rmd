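---
title: "Methods: the ommatidial eye model and the flight-track pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ommatidial eye model and the flight-track pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mozsight)
```

# The eye model

## Geometry

Mosquito compound eyes carry a few hundred ommatidia, each with its own lens
and a wide receptive field; spatial resolution is coarse and neighboring
receptive fields overlap heavily. The model represents the patch of the eye
aimed at a target as 37 ommatidia: one central viewing axis plus three
hexagonal rings (populations 6, 12 and 18) with nearest-neighbor angular
spacing equal to the interommatidial angle, 8° by default. Each receptive
field is a circular angular disk of 40° full width (radius 20°) centered on
its axis. Both values are compile-time defaults of `eye_parameters()`, not
constants, so other optical geometries can be explored.

The patch is centered on the gaze direction, and the gaze always points at
the target center. This reflects what the model is for — the best-case
detection range of a target the animal is looking at — not a claim about
where mosquitoes look.

## Projection

All overlap computations happen in a gaze-centered tangent plane under an
azimuthal-equidistant convention: a direction at true angular distance
$\theta$ from the gaze axis is placed $\theta$ degrees from the origin,
along its true bearing. Circles centered on the gaze axis remain exact
circles, and angular distances from the center are preserved, so the
hexagonal axis lattice and the receptive-field disks are represented without
distortion. Off-axis shapes acquire second-order distortion that grows with
eccentricity; at the eccentricities relevant here (images and receptive
fields within ~45° of the gaze) this is small relative to the 0.5-percentage-
point accuracy we validate against analytic oracles.

A vertical disk of diameter $D$ at distance $d$, centered on the gaze axis,
projects to a circle of angular radius $\arctan(D/2d)$. A horizontal
(floor-lying) disk viewed from altitude $h$ is projected point by point: each
of the `polygon_resolution` (default 360) boundary points is mapped through
the eye position into the tangent plane. The result is the familiar
foreshortened outline, vertically compressed, whose near and far edges sit at
depressions $\arctan(h/(d - D/2))$ and $\arctan(h/(d + D/2))$ below the
horizon. Distance is always the horizontal distance from the eye to the
target *center*; geometries with the eye above the disk ($d \le D/2$) are
rejected rather than special-cased.

## Stimulation and the detection rule

Per-ommatidium stimulation is the percentage of the receptive-field disk
covered by the image,
$s_i = 100 \cdot \mathrm{area}(I \cap RF_i) / \mathrm{area}(RF_i)$, computed
by polygon clipping (Vatti algorithm via the `polyclip` package) with two
exact fast paths: when every image vertex lies inside the receptive-field
disk the image polygon's own area is the overlap (the disk is convex), and
when bounding circles are disjoint the overlap is zero. The receptive field
is discretized at the same `polygon_resolution` as the image, and full
coverage is normalized against the discretized disk so that a covering image
reports exactly 100.

Detection aggregates the patch in two steps. An ommatidium *counts* when its
stimulation reaches the individual threshold (20% of its receptive-field
area, inclusive with a $10^{-9}$ slack so floating point cannot flip a
boundary case). Counting ommatidia then contribute to the eye total, and the
target is detected when the total reaches the total threshold (100
percentage points). Two contribution rules are implemented:

- **`"excess"` (default):** each counting ommatidium contributes
  $s_i - 20$, its stimulation in excess of the threshold. This treats the
  individual threshold as a response baseline — a rectified-linear unit
  response, the standard first-order model of thresholded neural summation.
- **`"sum"`:** each counting ommatidium contributes its full $s_i$; the
  threshold acts only as a gate.

The two rules produce the same qualitative behavior but different absolute
ranges; the gate-only rule yields systematically larger detection distances
(by roughly a third across the default target set: 50/29/95/47 cm versus
42/24/76/38 cm for 30 and 15 cm disks, horizontal then vertical). We ship
`"excess"` as the default because, with the default optical parameters, it
reproduces published detection-range estimates for *Anopheles coluzzii*
(roughly 39/25/72/36 cm for the same four cases) to within a few percent,
while the gate-only rule overshoots them by about a third; both rules remain
available through `eye_parameters(summation_rule = )`.

`detection_distance()` sweeps distance from `scan_step_cm` to `scan_max_cm`
(defaults 1 and 500 cm) in fixed steps and reports the *largest* detected
distance together with the full sweep trace. We do not assume detection is
monotone in distance: for oblique horizontal targets the image area and its
position on the patch change in opposite directions, so the sweep keeps
every evaluation. For horizontal targets, distances at which the eye would
hover over the disk are excluded from the sweep rather than erroring the
whole scan.

## Numerical accuracy

With 360-vertex polygons the clipped overlap agrees with the closed-form
circle–circle lens area to well under 0.5 percentage points across the
vertical-target grid, and with a $10^5$-point Monte-Carlo point-sampling
oracle to the same tolerance (both oracles live in the test suite, not in
the package, so they stay independent of the code path they check). Doubling
the polygon resolution moves detection distances by at most one sweep step.
Six-fold symmetry of the lattice is respected: for a centered vertical
target, ommatidia at equal angular distance from the gaze axis receive equal
stimulation to within 0.05 percentage points.

# The track pipeline

## Coordinates and cleaning

Tracks are ordered 3D point sequences sampled at 50 frames/s in a
120 × 120 × 200 cm arena; we fix x lateral (0–120 cm), y along the airflow
with upwind positive (0–200 cm), z vertical (0–120 cm), origin at the
downwind-floor-left corner. All lengths are cm.

Cleaning has three stages, in order:

1. **Outlier removal.** Points outside the arena are dropped, as are
   isolated spikes: points whose implied speed to *both* neighbors exceeds
   `outlier_speed_cms` (default 400 cm/s, about 17 times the mean flight
   speed — far above anything a flying mosquito produces, so only tracking
   glitches trigger it). Speeds are frame-aware, so pre-existing gaps do not
   create false positives, and the operation is idempotent.
2. **Gap interpolation.** Runs of up to `max_gap_frames` (default 5) missing
   frames are filled by per-axis linear interpolation and flagged
   `interpolated`; longer gaps split the track. Observed points are never
   altered and frames are never reordered.
3. **Smoothing.** A per-axis cubic smoothing spline evaluated at the
   original frames. The penalty is expressed on the frame scale (internally
   divided by the cubed frame range, since `smooth.spline` defines its
   penalty on inputs rescaled to the unit interval), so one value behaves
   identically on short and long tracks. The default (10) corresponds to an
   equivalent kernel bandwidth of about 1.8 frames: it roughly halves
   sub-frame tracking jitter while passing maneuvers slower than ~25 Hz, and
   it leaves constant-velocity flight exactly unchanged because straight
   lines lie in the penalty's null space. A penalty of 0 disables the stage.

Smoothing exists to suppress *measurement* jitter. The synthetic corruption
model below injects gaps and spikes but no per-frame jitter, so the
end-to-end recovery validation runs the pipeline without the smoothing stage:
applying a curvature penalty to jitter-free piecewise-linear fixtures can
only round their corners and would measure the fixture, not the cleaning.

## Visits and metrics

A target's region of interest is a cuboid: the target footprint grown by
10 cm per side in x and y, extruded from the floor to 30 cm (horizontal
targets) or 60 cm (vertical targets). Membership uses half-open intervals
$[\min, \max)$ on every axis so a boundary point can never be counted by two
adjacent regions. A *visit* is a maximal run of consecutive in-cuboid
points; runs shorter than 2 points (a 20 ms crossing at 50 fps) are
discarded as behaviorally meaningless. For vertical targets each visit is
labeled upwind or downwind of the target plane by its mean y.

Per visit: duration $(n-1)/f$, 3D path length as the sum of consecutive
Euclidean steps, mean speed as path over duration, and tortuosity as path
length divided by the entry-to-exit chord — the reciprocal of the usual
straightness index, 1 for straight flight. Chords shorter than 0.1 cm make
tortuosity a 0/0; such visits report `NA` rather than infinity. Per-target
summaries emit both totals and per-visit means, since either aggregation is
defensible and downstream statistics may want either. Landing counts are
external per-assay integers (the tracking system cannot observe landed
animals); the package only normalizes them to landings per 100 cm² of
target surface.

# The synthetic-track generator

`simulate_track()` is a correlated random walk: each new heading is the
unit-normalized mix $p \cdot \hat{u}_{t-1} + (1-p)\,\hat{r}$ of the previous
heading and an isotropic random direction (persistence $p = 0.95$ by
default), per-frame speeds are drawn from a normal truncated at zero (mean
24 cm/s — a typical host-seeking flight speed in wind-tunnel assays — s.d.
6 cm/s), and arena walls reflect. Persistence and speed spread are
conventions chosen to give plausibly tortuous, arena-filling flight; only
the mean speed, the frame rate and the arena are anchored to the assay
conditions the simulator emulates. Everything is deterministic given
`rng_seed` (the global RNG state is saved and restored).

`corrupt_track()` emulates the two defect classes the cleaner targets:
missing-frame gaps (per-frame start probability, lengths uniform on
`gap_length_range`, default 1–8 frames so both interpolable and
track-splitting gaps occur) and spurious points displaced 50 cm in a random
direction. Defects are kept *isolated* — gaps whole, never touching the last
frame, at least two intact frames between defects — so every recorded defect
keeps its drawn size and each can be attributed during validation.
Overlapping defects do occur in real data, but a corruptor whose recorded
ground truth can silently disagree with its effective corruption is useless
for validation.

`make_visit_scenario()` builds piecewise-linear constant-speed tracks that
visit given cuboids per plan. Each visit enters perpendicular to the
downwind face, flies an axis-aligned serpentine through the interior (5 cm
inside every face) whose in-cuboid path length equals
`dwell_s * mean_speed_cms` exactly (plus one frame of path compensating the
half-frame quantization of the entry and exit crossings), and leaves through
the same face. Ground truth is computed arithmetically from the constructed
points, independent of the segmentation code. Because approach legs are
straight, linear gap interpolation reconstructs them exactly, which is what
makes exact visit-count recovery a fair expectation.

## What the simulator does and does not show

The generator reproduces the *data defects* and the *geometry* of wind-tunnel
tracking — not mosquito behavior. There is no anemotaxis, casting, surging,
odor modulation or landing; speeds are i.i.d. rather than autocorrelated;
corruption carries no per-frame jitter. Passing the recovery tests therefore
demonstrates that the pipeline's bookkeeping (filtering, interpolation,
splitting, segmentation, metric arithmetic) is correct under known
corruption, and nothing about how well the metrics capture real behavior.

## Validation problem sizes

The end-to-end recovery check uses 50 seeded scenario tracks of 120 s
(6001 frames each, three 2 s visits), corrupted with gap rate 0.01/frame
(lengths 1–5) and spike rate 0.005/frame, and requires exact visit-count
recovery with total time, path and speed within 2%. The geometry oracle
grid is 20 lens cases plus three $10^5$-point Monte-Carlo cases. The full
suite runs in well under a minute on one CPU.

# Known limitations

- The eye patch is 37 ommatidia with a single interommatidial angle; real
  eyes have regional gradients in both spacing and receptive-field width.
- Contrast, illumination, adaptation state, spectral content and motion are
  all outside the model: targets are binary silhouettes.
- Only circular targets are modeled; rectangular targets of equal area are
  resolved at slightly different ranges.
- The azimuthal-equidistant convention is one defensible projection choice;
  at image eccentricities beyond ~45° its distortion of off-axis shapes
  becomes material.
- Detection distances inherit the 1 cm sweep step and are reported at that
  granularity.
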