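# itwgait

Sagittal ankle kinematics in idiopathic toe walking (ITW), computed under
three foot models and compared factorially across walking conditions.

## The problem

Clinical severity of ITW is commonly staged from two kinematic features of
the sagittal ankle trace: the presence of a **heel (first) rocker** (ankle
angle at foot contact above −5°, with a down-going excursion over the
first 12 % of the gait cycle) and a **premature forefoot (third) rocker**
(peak dorsiflexion before 30 % of the gait cycle). Whether those features
are detected depends on the biomechanical foot model:

* **Mono-segment models** (Plug-in-Gait *PiG*, Davis *DAV*) treat the foot
  as one rigid body whose longitudinal axis runs from the posterior
  calcaneus marker (CA) to a forefoot marker. The two anchors sit on bones
  that are not rigidly connected, so midfoot (intrinsic foot) motion is
  folded into the computed "ankle" angle.
* The **multi-segment Oxford foot model** (*OFM*) computes the ankle as
  hindfoot-relative-to-tibia from calcaneal markers only, and is immune to
  midfoot compliance.

`itwgait` implements the full evaluation pipeline for this comparison:

1. marker IO (C3D and a plain-text fixture format, label aliasing),
2. zero-lag 4th-order Butterworth filtering (fc = 12 Hz) of marker
   coordinates,
3. gait-event detection from vertical ground reaction force
   (threshold-and-hold rule),
4. anatomical frame construction and flexion-first Euler decomposition of
   the tibia-to-foot rotation for OFM, PiG and DAV,
5. time normalization to 101-sample gait cycles, representative-cycle
   selection by median-waveform distance, linear-fit-method (LFM)
   consistency,
6. extraction of the six clinical parameters (angle at foot contact, peak
   dorsi-/plantarflexion with timings, ROM) and rule-based rocker
   classification,
7. a 3 (model) × 2 (condition: barefoot **BF** vs foot-orthosis **FO**)
   fully-within-subject ANOVA with partial η², a Shapiro-routed
   aligned-rank-transform (ART) fallback and Bonferroni post-hocs,
8. a forward-kinematics **synthetic gait generator** with known
   ground-truth hindfoot–tibia and midfoot angle waveforms, so every stage
   is validated end-to-end without access to clinical data.

## Worked example

```r
library(itwgait)

cohort <- generate_cohort(n_subjects = 14, master_seed = 1)
res    <- analyze_cohort(cohort)

with(res$tables$rom, round(tapply(value, list(model, condition), mean), 1))
#>       BF   FO
#> OFM 16.9 24.0
#> PiG 22.3 23.9
#> DAV 23.8 23.8

report <- run_factorial_pipeline(res$tables)
report$blocks$rom$effects[, c("effect", "F", "df1", "df2", "p", "eta2")]
#>        effect           F df1 df2            p      eta2
#> 1       model  711.411459   2  26 2.001956e-23 0.9820544
#> 2   condition    5.887884   1  13 3.053092e-02 0.3117281
#> 3 interaction 1247.453566   2  26 1.494220e-26 0.9896863
```

Reading: in the barefoot condition the mono-segment models report a much
larger ankle ROM than the OFM (midfoot push-off plantarflexion is
misattributed to the ankle), while with the orthosis — which suppresses
midfoot compliance and restores heel-toe gait — the three models agree;
hence the strong model × condition interaction. Rocker classification
shows the same model dependence:

```r
aggregate(cbind(heel_rocker, premature_ff) ~ model + condition,
          res$rockers, function(x) round(100 * mean(x)))
#>   model condition heel_rocker premature_ff
#> 1   DAV        BF           0          100
#> 2   OFM        BF           0          100
#> 3   PiG        BF           0          100
#> 4   DAV        FO          31            0
#> 5   OFM        FO         100            0
#> 6   PiG        FO         100            0
```

Every barefoot toe-walking cycle shows a premature forefoot rocker and no
heel rocker; the orthosis condition restores the heel rocker — except
under DAV, whose raw-angle convention (no static offset) pushes some
contact angles below the −5° threshold, illustrating how the model changes
the classification itself.

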