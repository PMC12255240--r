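---
title: "Estimating medial knee contact force from joint moments and ultrasound geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating medial knee contact force from joint moments and ultrasound geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeload)
```

## The problem

The medial compartment of the tibiofemoral joint carries most of the
compressive load of the knee during locomotion, and high peak medial joint
contact force (MJCF) is a suspected mechanical driver of knee osteoarthritis.
MJCF cannot be measured non-invasively; it is estimated by combining inverse
dynamics (net joint moments and resultant joint forces), a muscle model that
distributes those moments to individual muscle forces, and the knee's frontal
plane geometry -- specifically the distance between the medial and lateral
tibiofemoral contact points, which this package takes from a calibrated
ultrasound measurement of the femoral condyles.

`kneeload` implements this chain end to end for walking, running and
sit-to-stand movements: signal conditioning, event detection and phase
segmentation, a deterministic muscle-force reduction model, the frontal-plane
contact-force balance, peak extraction and scaling, ultrasound panorama
stitching and measurement, and the reliability and group-comparison
statistics that accompany such a study. Because motion-capture exports of the
kind this pipeline consumes are rarely shareable, the package also ships
synthetic-data generators with exact ground truth for every stage; they are
first-class, tested code, not fixtures.

## The contact-force balance

At every sample the medial contact force is obtained by summing moments
about the lateral tibiofemoral contact point in the frontal plane:

$$F_{med} = -\left( \frac{\sum_i r_i F_i}{\hat d} + \frac{F_{RJF}}{2}
  + \frac{\tau_{KAM}}{\hat d} \right)$$

where $r_i$ and $F_i$ are the frontal-plane lever arm and force of the
$i$-th knee-crossing muscle or ligament, $F_{RJF}$ is the resultant
(intersegmental) knee joint force, $\tau_{KAM}$ is the external knee
adduction moment, and $\hat d$ is the midcondylar contact-point distance.

One sign convention governs every term, documented on `mjcf_sample()`:
compression is negative ($F_{RJF} < 0$ during stance), adduction is negative
in the frontal-plane frame, and frontal-plane lever arms of structures that
add medial load are negative. Under physiological loading the leading minus
sign then returns a positive (compressive) medial force. MJCF is reported in
bodyweights (BW, with $g = 9.81\,\mathrm{m/s^2}$); knee adduction and flexion
moments (KAM, KFM) are reported in BW$\cdot$Ht.

The resultant knee joint force is an inverse-dynamics quantity that the
trial tables do not carry; `compute_joint_loads()` defaults to
$F_{RJF} = -F_z$ (the vertical ground reaction force read as joint
compression), and accepts an explicit series whenever a full inverse-dynamics
resultant is available. The synthetic generator uses the same convention, so
recovery tests are exact rather than approximate.

## The reduction model

Net moments are distributed to five muscle groups in a fixed sequence:

1. **Ankle**: gastrocnemius and soleus from the plantarflexion moment.
2. **Hip**: hamstrings and gluteus maximus from the extension moment.
3. **Knee**: the quadriceps force from the knee flexion moment *plus* the
   knee-flexion contributions of the biarticular muscles computed in steps
   1-2 (co-contraction): $F_{quad} = \max\!\big(0, (M + \sum_b r_b F_b) /
   r_{quad}\big)$.

Within a joint, forces are shared in proportion to muscle cross-sectional
area and jointly reproduce the net moment exactly:
$F_m = \mathrm{CSA}_m \cdot M / \sum_j r_j \mathrm{CSA}_j$. Moments in the
antagonist direction produce zero force -- muscles only pull -- and all
outputs are clamped non-negative. Residual tibial shear and frontal-plane
distraction loads, when supplied, resolve to the cruciate and collateral
ligaments mutually exclusively by sign (`ligament_forces()`).

Two modelling points deserve emphasis:

* **Co-contraction set.** The knee step counteracts the knee-flexor moments
  of the *biarticular knee flexors* -- hamstrings and gastrocnemius. One
  also encounters descriptions pairing the hamstrings with the gluteus
  maximus here; the gluteus maximus does not cross the knee, so it cannot
  load the quadriceps, and this package deliberately uses
  hamstrings + gastrocnemius.
* **Coefficients are configuration, not code.** Moment-arm polynomials
  (per joint angle, radians), CSA values, ligament orientations and condylar
  ratios live in a versioned JSON file
  (`system.file("extdata", "model_config.json", package = "kneeload")`). The
  shipped values are documented placeholders of literature-typical magnitude:
  knee arms 2-6 cm with distinct female/male quadratics, hip/ankle arms
  shared across genders but height-scaled by group-mean/grand-mean height
  (e.g. $1.75/1.69$ for men in the reference cohort), CSAs of tens to
  hundreds of cm^2. Every test of the reduction is coefficient-agnostic --
  moment closure and round-trip recovery hold for *any* valid configuration
  -- so users can substitute their preferred regression sources without
  touching code. Angles outside a polynomial's declared validity range are
  clamped to the boundary with a warning; silently extrapolating a quadratic
  can flip an arm's sign.

## Conditioning and segmentation

All channels are filtered with a 4th-order Butterworth filter applied
forward and backward (zero phase): ground reaction forces at 45 Hz;
kinematics, net moments and pelvis velocity at 10 Hz for running and 6 Hz
for other movements. No cutoff correction is applied, so the gain at the
nominal cutoff is 0.5 (the squared single-pass -3 dB point) -- the common
filtfilt convention. R's `signal::filtfilt` does not set initial
conditions, so `filter_dual_pass()` pads both ends by odd reflection, long
enough to outlast the slowest pole's transient, and trims the pad.

Gait trials are segmented at heel strikes: upward crossings of a 20 N
threshold on the filtered vertical force, sustained for 10 ms, resolved to
the first discrete sample satisfying the condition (no sub-sample
interpolation, anywhere). Consecutive heel-strike-to-heel-strike windows
form strides; at most the first five *clean* strides are kept, where clean
means no missing force samples and a duration within 2 SD of the trial
median -- the 2 SD rule is this package's operational definition of "clean".

Sit-to-stand and stand-to-sit phases are defined by force thresholds:

* **Sit-to-stand** starts at the seat-unloading surge, where $dF_z/dt$
  reaches 10% of its trial peak-to-peak value, and ends at quiet standing,
  where $F_z$ stays within $(1 \pm 0.01)\,BW$ for a sustained 200 ms window
  (instantaneous equality is measure-zero, hence the band and the sustain).
* **Stand-to-sit** starts after the quiet-standing period at the first
  sample with $F_z \le 0.98\,BW$ (sustained 50 ms), and ends at the start of
  quiet sitting: the first subsequent sample where either $|dF_y/dt|$ falls
  to 1% of its trial peak-to-peak value or the vertical pelvis velocity
  magnitude falls below 0.02 m/s, whichever happens first (sustained
  100 ms). Absolute derivative values are used; peak-to-peak is computed
  over the whole trial, the only parameter-free choice.

Two numerical choices make these definitions robust on noisy plates, and
both are deliberate implementation decisions worth recording. First,
derivative and band logic runs on an additional 10 Hz smoothed copy of the
force channels, with the derivative taken as a central difference averaged
over a centred 100 ms window (a local-slope estimate) and the first/last
200 ms excluded: differentiating a 45 Hz-bandwidth force amplifies exactly
the noise the threshold comparison must survive. Second, the sit-to-stand
onset is found by locating the global maximum of the smoothed derivative and
walking back to the first sample of its contiguous supra-threshold region --
the robust reading of "the sample where the derivative reaches 10% of
peak-to-peak", immune to isolated noise crossings far from the event.
Kinematic channels sampled at 200 Hz are linearly interpolated onto the
1000 Hz kinetic clock before any joint logic, so a single clock governs all
indices.

## Peaks, scaling and group comparison

Within each stance (walking) the MJCF, KAM and KFM exhibit the classic
two-peak structure; `extract_peaks()` therefore splits the stance portion of
a stride window in half (stance = contiguous loaded samples from the window
start; the midpoint sample belongs to the first half) and reports the
maximum of each half. Running and sit-to-stand movements report a single
maximum. Per-subject values are means over all clean windows; trial counts
are logged so exclusions are auditable.

Group comparisons are gated: Shapiro-Wilk on each group and a
Brown-Forsythe (median-centred) Levene test across groups, both at 0.05,
route the comparison to a Mann-Whitney U test when either rejects and to an
unpaired equal-variance Student's t-test otherwise. Cohen's d (mean
difference over pooled SD) is always reported, and a summary-statistics mode
(`compare_groups_summary()`) reproduces t and d from printed means and SDs.
The family-wise level for a battery of 18 tests (5 movements x 3 load
variables + 3 speed tests) is $0.05/18$, reported as 0.0028. Percent
differences between gender means use the symmetric definition
$|a-b| / \frac{a+b}{2} \times 100$; the relative-to-one-group alternative is
not used, and this choice is flagged on `percent_difference()`.

Power analysis solves the noncentral-t power equation for the effect size at
which a two-sample t-test attains a target power (`uniroot`, tolerance
1e-6); the normal approximation is visibly off at n = 26, where the
one-tailed smallest detectable d at 80% power and alpha 0.05 is 0.70. ICC
reliability uses the Shrout-Fleiss two-way random-effects absolute-agreement
convention, average of k measures -- ICC(2,k) -- from ANOVA mean squares,
with F-distribution confidence bounds stepped up by Spearman-Brown and
$\mathrm{SEM} = \mathrm{SD}\sqrt{1-\mathrm{ICC}}$.

## Ultrasound width measurement

A knee wider than the probe is imaged as a sweep; frames are extracted at
10 frames/s, stitched, and measured. Registration is translation-only
(horizontal-dominant) by normalized cross-correlation of candidate overlaps,
with a minimum 20% overlap and a correlation floor below which stitching
fails loudly, naming the offending tile pair: the probe slides laterally in
skin contact, so perspective distortion is negligible and NCC is
deterministic and testable, unlike feature-homography stitching. Landmarks
(the medial and lateral condyle centres) are supplied as annotations --
raters click them; nothing is auto-segmented. The calibrated distance is the
Euclidean pixel distance divided by the px/cm factor, which is a required
input: calibration provenance (probe field of view vs on-image scale bar)
varies by machine and is not guessed. The measured intercondylar distance is
finally scaled by a gender-specific cadaver-derived midcondylar/intercondylar
ratio to the contact-point distance $\hat d$; when no measurement is
available, per-gender cohort defaults (female 4.86 cm, male 5.53 cm) are
used.

## What the synthetic data emulates -- and what it does not

The generators reproduce the *structure* the pipeline consumes, with exact
ground truth:

* **Gait trials** (`generate_gait_trial()`): 1000 Hz kinetics, 200 Hz
  kinematics, five strides plus the closing heel strike, double-bump
  (walking) or single-bump (running) vertical force crossing 20 N at known
  samples, band-limited angle curves, and planted muscle forces built
  CSA-proportionally from per-group activation bumps. Net moments are
  *constructed from* the planted forces through the same moment-arm model
  the reducer uses, so with zero noise the reduction inverts them exactly
  (relative error below 1e-9 in the tests, at numerical precision in
  practice). All curves live well below the filter cutoffs, so conditioning
  cannot distort the ground truth and parameter-recovery tests stay sharp.
  Noise is i.i.d. Gaussian per channel -- the simplest model that exercises
  the filters.
* **Sit-to-stand traces** (`generate_sts_trace()`): piecewise
  linear-with-plateaus vertical force (seated at 25% BW on the floor plate,
  a 1 s constant-rate rise, quiet standing at BW, a fourfold-faster drop,
  quiet sitting), with matching anterior-posterior force ramps and a pelvis
  velocity trapezoid. Only the floor plate is modelled; no separate seat
  force, which is what the detection equations consume. Returned boundary
  truths are the *analytic crossing times the phase equations define on the
  clean trace*, computed in closed form from the piecewise construction and
  independent of the detection code -- detector tests are genuine recovery
  tests, not self-confirmation. The descent rate is deliberately four times
  the rise rate: the onset threshold (10% of derivative peak-to-peak) then
  sits at exactly half the rise slope, the symmetric point of any zero-phase
  smoothing, which keeps the planted onset well-defined to a few
  milliseconds; and the velocity settle ramp is slow enough that its
  0.02 m/s crossing sits clear of the 6 Hz kinematic filter's corner
  rounding. Under 2% BW channel noise, at least 95% of all four boundary
  types are recovered within +/- 20 ms (in the current suite: 100%).
* **Ultrasound tile sets** (`generate_tile_set()`): exact crops of one
  pseudo-ultrasound master (smoothed speckle plus two bright condyle-like
  arcs) at stated offsets, with the planted landmark distance as truth.
* **Rating tables** (`generate_rating_table()`): two-way random-effects
  draws with planted subject/rater/error variance components and the implied
  theoretical ICC attached.

What passing tests on this data do **not** show: real gait has
stride-to-stride waveform variability, correlated (not white) sensor noise,
soft-tissue artefact, marker gaps, seat-reaction transients and imperfect
probe contact; none of these are modelled, and the trial-to-trial
variability magnitudes (a few percent on amplitudes) are free choices, not
cohort calibrations. The synthetic suite validates the *computations*; it
cannot validate the biomechanical model against instrumented-knee data.

## Problem sizes and determinism

Every generator takes an integer seed and is bit-reproducible; the pipeline
is deterministic given a seed, and derived per-trial seeds stay below
$2^{31}$. The shipped test suite uses the sizes of the reference study where
they matter (52-subject rating tables, 26 per group for power, five strides,
100-seed boundary-recovery batches) and a 3-per-gender demonstration cohort
for the end-to-end pipeline test; `make_demo_cohort()` defaults to 10 per
gender, mirroring a realistic small cohort, and scales linearly.

## Known limitations

* The default $F_{RJF} = -F_z$ is a stance-phase approximation; swing-phase
  MJCF is not meaningful under it (peaks are extracted within
  stance/phase windows only, so reported peaks are unaffected).
* The reduction model is deterministic: no optimization-based load sharing,
  no EMG weighting, and the placeholder moment arms must be replaced for any
  claim about real cohorts.
* Lateral compartment force, contact stress and cartilage-level damage
  metrics are out of scope.
* Video decoding is not implemented: frame extraction consumes directories
  of PNG frames (or in-memory matrices) in timestamp order.
* C3D parsing is not implemented; trials are plain TSV tables in SI units
  with a fixed header.
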