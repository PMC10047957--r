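---
title: "Comparing mono- and multi-segment foot models in toe-walking gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing mono- and multi-segment foot models in toe-walking gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itwgait)
```

## The problem

Idiopathic toe walking (ITW) is a persistent forefoot-contact gait seen in
otherwise typically developing children. Its clinical severity is commonly
staged from sagittal ankle kinematics: the presence of a *heel (first)
rocker* shortly after foot contact, and a *premature forefoot (third)
rocker*, i.e. peak dorsiflexion arriving abnormally early in the gait
cycle. Those kinematic features depend on how the foot is modelled.
Mono-segment models (Plug-in-Gait, PiG; Davis, DAV) treat the whole foot
as one rigid body whose longitudinal axis runs from the posterior calcaneus
marker (CA) to a forefoot marker; any motion of the intrinsic foot joints
therefore changes that axis and is read as *ankle* motion. The
multi-segment Oxford foot model (OFM) computes the ankle as hindfoot
relative to tibia, using only calcaneal markers for the hindfoot, and is
immune to midfoot compliance.

`itwgait` implements the full comparison pipeline: marker-level
kinematics under all three models, the clinical parameter set, rule-based
rocker classification, a 3 (model) x 2 (walking condition) within-subject
factorial analysis, and a forward-kinematics synthetic gait generator with
known ground-truth joint angles that makes every stage testable.

## Processing pipeline

1. **Filtering.** Raw marker coordinates are low-pass filtered with a
   fourth-order Butterworth at 12 Hz. We realize "fourth order" as a
   forward-backward pass of a second-order design: the net attenuation is
   fourth-order while the phase response is identically zero, so the
   timings of kinematic features (reported in % gait cycle) are not
   shifted. Edge transients are suppressed by odd-symmetric end padding
   with steady-state initial conditions, making the DC gain exactly 1.
   The filter is applied to coordinates, never to computed angles.
2. **Events.** Foot contact (foot off) is the first vertical-GRF sample
   rising above (falling below) a 20 N threshold that holds for at least
   10 ms. Both threshold and hold time are configurable; they are our
   operationalization, as force-plate event rules are rarely reported in
   full.
3. **Frames and angles.** Segment frames are right-handed and orthonormal;
   the sagittal ankle angle is the leading rotation of the
   flexion-first Euler decomposition of the tibia-to-foot rotation,
   dorsiflexion positive, zeroed on a static standing trial. Samples where
   the second (inversion) rotation comes within 1 degree of gimbal lock
   are flagged and dropped.
4. **Cycles.** Each contact-to-contact span is linearly resampled to 101
   samples (0-100 % gait cycle). Cycles overlapping marker gaps are
   discarded rather than gap-filled.
5. **Per-subject summary.** A representative cycle per subject, model and
   condition minimizes the trapezoidal area to the set's pointwise median
   waveform. Inter-subject consistency is screened with the linear fit
   method (LFM); the cohort is consistent when mean R^2 > 0.5.
6. **Statistics.** The six clinical parameters (angle at foot contact,
   peak dorsiflexion and its timing, peak plantarflexion and its timing,
   ROM) feed a fully-within-subject 3 x 2 ANOVA with partial eta-squared
   effect sizes; a per-cell Shapiro-Wilk screen routes non-normal tables
   to an aligned-rank-transform (ART) fallback; Bonferroni post-hocs use
   the two families implied by the design (3 model pairs within a
   condition at 0.05/3; the condition pair within a model at 0.05).

## Frame construction choices

The exact OFM/PiG/DAV frame definitions live in vendor documentation and
the original model papers; this package specifies them operationally,
anchored to the mechanism that matters for the mono- vs multi-segment
contrast:

* **Tibia**: longitudinal axis from the inter-malleolar midpoint (ankle
  joint center) to the knee center, approximated as the lateral femoral
  epicondyle marker shifted half a knee width (default 80 mm) along the
  malleolar line; flexion axis = malleolar line projected orthogonal.
* **Mono-segment foot**: longitudinal axis CA to forefoot marker (PiG: the
  metatarsal marker `MTH`; DAV: the distal `TOE` marker), sagittal plane
  containing that axis and the laboratory vertical. Only CA and the
  forefoot marker enter the sagittal construction, so CA height relative
  to the metatarsal marker is the single geometric factor in sagittal
  estimation.
* **OFM hindfoot**: sagittal plane normal to the medial-lateral calcaneal
  line; longitudinal axis from CA to a *virtual anterior calcaneal point*
  placed 60 mm from CA along the intersection of that plane with the
  horizontal during the static trial, then pinned in calcaneus-local
  coordinates so it moves rigidly with the calcaneus. The hindfoot frame
  depends on the calcaneal triad only - by construction, never on
  forefoot markers.
* **Model conventions**: PiG and OFM subtract the static sagittal offset;
  DAV reports the raw anatomical angle and uses the more distal forefoot
  marker. These two convention differences are what make the two
  mono-segment models disagree systematically (DAV reads more
  plantarflexed), and both are configurable in `foot_model_config()`.
  We deliberately expose a single hindfoot convention rather than
  version switches of the original multi-segment model: the published
  version differences do not affect the sagittal hindfoot-tibia angle
  this package analyzes.

Sign conventions: dorsiflexion (toe-up rotation of the foot relative to
the tibia) is positive; the lab frame is X along progression, Z up,
Y = Z x X. Frames referencing the laboratory vertical make angles
invariant under vertical-preserving rigid motions (rotations about Z plus
translations) - the natural invariance class for gait data - but not
under arbitrary 3D rotations of the whole scene.

## Rocker rules

With criteria `rocker_criteria(-5, 12, 30)`:

* *heel rocker*: angle at foot contact strictly above -5 deg AND a
  down-going pattern over the first 12 % of the cycle. "Down-going" is
  operationalized as net excursion 0 -> 12 % negative AND the running
  minimum over the window strictly below the 0 % value; this captures the
  described pattern without inventing an amplitude cutoff. Both clauses
  and all three thresholds are configurable.
* *premature forefoot rocker*: peak stance dorsiflexion strictly before
  30 % of the gait cycle (a peak at exactly 30 % does not count).

## The synthetic gait generator

No public ITW marker dataset exists, so validation runs on synthesized
cohorts with known ground truth. The generator drives a
lab -> tibia -> hindfoot -> forefoot chain:

* The **ankle waveform** (hindfoot vs tibia, the ground truth) is built
  from clinical landmarks by half-cosine easing between knots - every
  knot has zero slope, so requested peaks are exact extrema - smoothed by
  Fourier truncation (12 harmonics by default). The `toe_walking` profile
  defaults (contact -10 deg, peak DF -2 deg at 20 %, peak PF -18 deg at
  62 %, ROM 16 deg) and the `heel_toe` profile defaults (contact 0 deg,
  loading dip -4 deg, peak DF 10 deg at 45 %, peak PF -15 deg at 65 %,
  ROM 25 deg) were chosen so the barefoot profile matches the
  multi-segment picture of toe walking (small hindfoot ROM, plantarflexed
  contact, early forefoot rocker) and the orthosis profile a corrected
  heel-toe gait; the two sit on opposite sides of both rocker thresholds
  by construction.
* The **midfoot hinge** sits at the Chopart level (about one third of the
  heel-toe span) between hindfoot and forefoot. Its waveform is the
  minimal realization of intrinsic-foot motion in gait: plantarflexion
  rising through stance, peaking at foot off (push-off), decaying to
  neutral in early swing. This is the degree of freedom that realizes the
  misattribution mechanism: a mono-segment axis spanning the hinge reads
  the push-off midfoot plantarflexion as extra ankle plantarflexion,
  enlarging its apparent ROM - the direction observed clinically.
  Amplitude defaults: 15 deg barefoot, 0 deg with the orthosis (which
  promotes heel-toe gait); the amplitude is the experiment's dial.
* **Markers** ride rigidly on their segments with isotropic Gaussian
  noise (default SD 0.5 mm, typical optical-capture noise). Soft-tissue
  artifact is not modelled.
* **GRF** is a stance-gated double bump scaled to 1.2 x body weight at
  4 x the marker rate (250/1000 samples/s); only its threshold crossings
  matter downstream, and they recover the generator's true events to
  within one marker frame.
* **Cohorts** draw per-subject landmarks from normal distributions
  (SDs of 2-3 deg / 3 % GC around the profile defaults), 14 subjects and
  4-10 cycles per subject (mean about 6), all reproducible from one
  master seed.

What passing on synthetic data does and does not show: the generator
proves the pipeline recovers known kinematics through the full marker
pathway and reproduces the *direction* of the model x condition effect
structure. It does not certify numeric agreement with any particular
clinical cohort - real feet have soft-tissue artifact, marker placement
error, multi-axis coupling and between-trial variability that the
generator deliberately omits.

## Numerical choices and degenerate inputs

* Representative-cycle areas use trapezoidal integration on the 101-point
  grid; ties choose the lowest cycle index.
* Parameter extraction takes the earliest instant on ties; peak
  plantarflexion is searched over the full cycle (it can fall in swing),
  peak dorsiflexion over stance only.
* The ANOVA treats roundoff-level sums of squares (below 1e-12 of the
  total) as exact zeros: a null effect reports F = 0, a non-null effect
  over a zero error term is flagged (`note = "zero error SS"`) with p
  pinned at 0. Sphericity is uncorrected by default (3-level factor);
  a Greenhouse-Geisser switch exists.
* The LFM reference curve is the cohort median (configurable to mean),
  consistent with the median-waveform machinery used for representative
  selection; a zero-variance reference raises an error rather than
  returning an undefined R^2.
* Collinear calcaneal triads, coincident CA/forefoot markers and
  malleoli collinear with the knee center raise degenerate-geometry
  errors naming the construction.

## Problem sizes

The validation suite uses 3-cycle noise-free trials for round-trip
checks, 100-seed oracle sweeps for the representative-selection and
ANOVA brute-force comparisons, 1000 null tables for the type-I-error
check, and 50 cohorts of 14 subjects for the effect-structure
replication; the bundled acceptance script repeats the same computations
at 40 cohorts.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
cohort <- generate_cohort(n_subjects = 14, master_seed = 1)
res <- analyze_cohort(cohort)

# mean ROM per model and condition
with(res$tables$rom, tapply(value, list(model, condition), mean))

# factorial analysis of all six parameters
report <- run_factorial_pipeline(res$tables)
print(report)

# rocker prevalence per model in the barefoot condition
aggregate(cbind(heel_rocker, premature_ff) ~ model,
          res$rockers[res$rockers$condition == "BF", ], mean)
```

## Known limitations

* Only the sagittal ankle component is computed; frontal and transverse
  components are out of scope, as are kinetics (moments, power) and the
  kinetic half of severity staging.
* Marker gap-filling and automatic labelling are not provided; cycles
  touching a gap are dropped.
* The frame definitions are operational stand-ins for the full vendor
  conventions (no tibial-torsion or knee-axis corrections); real-data
  users must supply a marker alias map for their lab's dialect.
* The C3D reader supports Intel-byte-order files with integer or float
  data, which covers modern exports but not legacy DEC/MIPS files.
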