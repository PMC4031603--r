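---
title: "Quantifying foot rollover: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying foot rollover: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footroll)
```

# The problem

During the stance phase of walking, load travels from the heel over the
lateral then medial forefoot to the hallux and toes. Diabetic
polyneuropathy degrades this rollover: anterior regions overload, the toes
disengage, and heel-strike damping worsens — a pattern linked to plantar
ulceration. Trials of foot–ankle exercise therapy therefore track a battery
of rollover variables (regional plantar pressures, centre-of-pressure
progression, sagittal ankle mechanics, clinical foot function) in a two-arm
repeated-measures design. `footroll` implements that entire measurement and
analysis chain, plus synthetic-data generators with closed-form ground
truth so every stage can be validated by parameter recovery.

# Regional plantar-pressure metrics

## Stance detection and step selection

A stance is a maximal run of frames whose total force (pressure × sensor
area, summed) exceeds a fraction of the trial maximum, lasting at least a
minimum duration. Defaults: **threshold 0.05** (5 % of maximum force) and
**minimum duration 0.2 s** — common gait-event practice; both are exposed
as arguments. Step selection mimics the "middle steps" convention: the
first and last step of each walking trial are dropped (gait initiation and
termination), then the requested number of steps (conventionally 25 per
foot) closest to their trial's midpoint is kept.

## Region masks

The loaded footprint is divided along its long axis, heel at 0 %:
heel `[0, 27)` %, midfoot `[27, 55)` %, forefoot `[55, 80)` %, toe band
`[80, 100]` % of foot length. The forefoot band splits across its width
into medial (55 %) and lateral (45 %) strips; the toe band into the hallux
(medial 33 %) and the toes (lateral 67 %). Two readings of these
percentages had to be fixed:

* The published scheme's "final 20 % of foot length" for the hallux/toes
  overlaps its 45 % forefoot block; the only partition consistent with
  27 + 28 + 25 + 20 = 100 is forefoot proper at 55–80 % and the toe band at
  80–100 %, which is what the package uses.
* Vendor automasking software measures widths internally; here each band's
  width is the extent of that band's loaded sensors, and a sensor belongs
  to the band containing its centre (half-open intervals, distal-most
  closed), which makes the partition deterministic.

The long axis is the area-weighted principal axis of the loaded sensor
cloud, so masks are invariant under rigid rotation of the grid. Its
orientation (which end is the heel) comes from loading order — heel sensors
load earliest; if loading carries no temporal signal the grid's declared
posterior→anterior axis is used. The medial side follows the recorded foot
side (left/right), because the hallux is anatomically medial. A point-like
footprint (one sensor) has no length to divide and is labelled heel.

## The metrics

The regional curve is the **per-frame maximum pressure over the region's
sensors** — the convention behind a "peak pressure temporal series". PP is
its maximum; TPP is the instant of the first maximum relative to stance
duration, with denominator N−1 frames so a final-frame peak reads exactly
100 %; PTI is its trapezoidal time integral (kPa·s). The alternative
force–time reading of PTI was rejected as unit-inconsistent with kPa·s.
The COP is the pressure·area-weighted centroid of sensor positions; zero-
load frames are excluded. The total COP path uses all sensors over the
whole stance. A *regional* COP velocity is not defined by the insole
vendor's documentation available to us; the package computes it from the
region-restricted COP over the region's active (non-zero-load) window, and
flags that this is a package convention, not an asserted equivalence.
Velocities are path length divided by the elapsed time of the path's
window. Left and right feet are analysed separately; no left–right
averaging is applied.

# Ankle mechanics

Force-plate signals are filtered at 20 Hz and marker trajectories at 6 Hz
(both adjustable), using a zero-phase Butterworth low-pass. A "4th-order"
filter is realized as a forward–backward pass of a 2nd-order filter — the
dominant biomechanics convention, because the outcomes depend on peak
*timing* and phase lag would bias them. The forward–backward pass is
implemented with odd reflection padding and steady-state initial
conditions, which keeps constants exact to machine precision and removes
boundary transients.

The ankle angle is the signed sagittal angle between the shank axis
(ankle→knee) and foot axis (heel→toe), zeroed at neutral standing (flat
foot, vertical shank), dorsiflexion positive. The zero convention is not
universal; zero-at-neutral was adopted and is stated here.

The net ankle moment comes from a Newton–Euler balance of the foot
segment: ground reaction force applied at the plate COP, foot weight and
inertial terms from the anthropometric model, and the ankle reaction
force. Segment parameters are the standard Dempster-derived table (foot
1.45 %, shank 4.65 %, thigh 10.0 % of body mass; COM at 50 / 43.3 / 43.3 %
from the proximal end; radii of gyration 47.5 / 30.2 / 32.3 % of segment
length), exposed via `dempster_model()` and replaceable. Moments are
normalized to `%BW·h` with g = 9.81 m/s², plantarflexion positive (so the
early-stance extensor peak is negative). The marker protocol is reduced to
the landmarks sufficient for sagittal outcomes — heel, toe, ankle, knee
(hip optional) — rather than a full cluster set, which the four outcomes do
not require.

The "peaks near 20 % and 80 % of stance" are operationalized as windowed
extrema: extensor = minimum over 5–40 % of stance, flexor = maximum over
60–95 %. Windowing is robust to noise away from the expected peak and
equals the global extremum whenever each half of stance is unimodal (a
property the tests check). Frames with vertical force under 5 % of maximum
are excluded from the moment series; stances shorter than 10 frames are
rejected.

# Trial statistics

The intention-to-treat chain mirrors small-clinical-trial practice:

* **Imputation**: a missing cell takes the mean (parametric variables) or
  median (nonparametric) of the observed values of the same variable
  *within the same group and timepoint* — the least biased reading of
  "mean of series" in a groupwise ITT — assuming MCAR. Observed values are
  never changed, so group × timepoint means of parametric variables are
  preserved exactly.
* **Assumptions**: Kolmogorov–Smirnov per cell against a normal with the
  cell's moments, and Levene's test with mean centring.
* **Group × time ANOVA**: the 2 × 2 mixed design is computed in closed
  form (subject means carry the between stratum, difference scores the
  within stratum). With a two-level within factor, sphericity holds
  trivially and no correction is applied. The closed form equals `aov` and
  a GLM model-comparison route to machine precision (tested). Newman–Keuls
  then steps through the ordered cell means with studentized-range
  critical values; the pooled within-cell variance serves as its error
  term with the harmonic mean cell size.
* **Follow-up** (intervention arm, three timepoints): one-way
  repeated-measures ANOVA for parametric variables, Friedman otherwise.
  Fully tied data yield a Friedman statistic of 0 by convention.
* **Rank tests**: Mann–Whitney / Wilcoxon, exact for untied samples up to
  n = 12 per group, otherwise normal approximation with continuity and tie
  correction. Exact p-values equal full enumeration (tested to total
  n ≤ 8).
* **Effect sizes**: `d = |m₁ − m₂| / √((s₁² + s₂²)/2)` — the unweighted
  pooled SD, appropriate for near-equal arms — labelled small < 0.4 ≤
  medium < 0.7 ≤ large. These boundaries follow the usage calibrated in
  this trial literature (0.3 labelled small, 0.4–0.6 medium, 0.7+ large)
  rather than the 0.2/0.5/0.8 textbook convention; they are arguments, not
  constants. Two-sided tests and α = 0.05 throughout.
* **Median differences**: Hodges–Lehmann estimate (median of pairwise
  differences) with the distribution-free CI from the ordered pairwise
  differences.
* **Randomization**: blocks of random size 1–8, balanced up to rounding,
  with the odd unit sent to the smaller arm so the running imbalance at
  block boundaries never exceeds one; fully reproducible from a seed.
* **Sample size**: smallest N reaching target power for a repeated-
  measures F test under a noncentral-F formulation with compound-symmetric
  correlation ρ (default 0.5). The tested effect must be chosen
  (`between`, `within`, `interaction`) because the noncentrality differs:
  `f²Nm/(1+(m−1)ρ)` for between, `f²Nm/(1−ρ)` otherwise. At f = 0.36,
  α = 0.05, power 0.81 in a 2 × 2 between-effect design the package
  returns N = 49; published sample sizes computed with other software
  depend on unstated correlation assumptions, so agreement to the subject
  is not forced. No multiplicity correction is applied across outcome
  variables, matching the analysis convention this package reproduces.

# The synthetic-data generators

The generators *define* the validation conditions; their defaults are
fixed, not tuned per test.

**Rollover recordings.** Each region's sensors carry an asymmetric
raised-cosine pulse: a half-Hann rise from onset to peak and a half-Hann
fall to offset, in % of stance. Onsets may be negative and offsets may
exceed 100: the pulse is truncated at foot strike/lift, emulating the
abrupt heel load at initial contact and the non-zero toe pressure at
lift-off (this also keeps total force above the detection threshold at the
true stance edges, as in real recordings). PP, TPP and PTI have closed
forms (the truncated lobes integrate analytically), so recovery is tested
against exact values: the defaults reproduce the heel → midfoot → lateral
before medial forefoot → hallux/toes progression with heel ≈ 300 kPa
peaking at 18 % of stance, forefoot ≈ 310–350 kPa near 80 %, stance 0.65 s,
cadence 106 steps/min (middle of the 96–116 normal band), noise off by
default. With these defaults the extracted metrics land at the scale
reported for middle-aged DPN cohorts (heel PP ≈ 300 kPa, heel TPP ≈ 18 %,
total COP velocity ≈ 0.26 m/s) — a realism smoke test, not an assertion of
any cohort's numbers.

What the pulses deliberately do *not* model: spatial pressure gradients
within a region (pressures are uniform per region, so regional COP
velocities are near zero), medio-lateral COP excursion, step-to-step
variability of timing, and sensor saturation. Passing recovery tests
therefore shows the *pipeline arithmetic* is right, not that real insole
data are this clean.

**Gait mechanics.** The foot segment's pitch (a late-stance heel rise to
30° starting at 65 % of stance, pivoting about the toe) and the shank and
thigh leans are smooth raised-cosine ramps with hand-derived first and
second derivatives; the vertical GRF is the classic double hump
`BW(1.20 sin πu + 0.30 sin 3πu)`, the shear a braking→propulsion sinusoid,
and the COP lever advances smoothly from 2 cm behind to ~14 cm in front of
the ankle. Because positions, forces and accelerations are analytic, the
net ankle moment follows in closed form from the same Newton–Euler balance
the pipeline discretizes — but the pipeline sees only sampled markers and
forces, filters them and differentiates numerically, so the comparison
(≤ 2 % relative RMS) genuinely exercises the numerical chain. A
quasi-static mode freezes all motion, reducing the truth to the static
lever-arm balance used as an independent oracle. Defaults land the
outcomes at cohort scale: ROM ≈ 22°, end-propulsion angle −8°, extensor
peak ≈ −1.0 %BW·h in early stance, flexor peak ≈ 8.1 %BW·h near 80 %.
Unmodelled: frontal/transverse motion, soft-tissue artefact, force-plate
noise and marker dropout.

**Trial tables.** Outcomes follow a shared-random-intercept model:
`y = μ + b_i + effect + ε`, `b_i ~ N(0, ρσ²)`, `ε ~ N(0, (1−ρ)σ²)`, the
simplest structure with within-subject correlation ρ (default 0.5) and
marginal SD σ. The intervention arm receives `d·σ` at week 12 and, by
default, loses it at week 24 (the return-to-baseline pattern);
follow-up rows exist only for the intervention arm, mirroring a design
whose control arm is not re-assessed at follow-up. MCAR missingness
(default 5 %) is applied per cell. Arm sizes default to 29/26. Under this
null the interaction test's empirical type-I error at 2000 replicates is
≈ 0.05 on complete data; with 5 % missingness plus mean imputation it
rises slightly (≈ 0.07 measured once at 2000 replicates) — a known
mild anti-conservatism of single imputation worth remembering when
interpreting borderline p-values.

# Numerical choices and degenerate inputs

* TPP ties resolve to the first maximum; a single-frame series reads 0 %.
* PTI uses the trapezoidal rule at the recording's sampling rate.
* Sample SD over a single analysis step is 0 by convention.
* All-zero paired differences make the signed-rank test degenerate: the
  package warns and returns `NA` rather than a fabricated p.
* Regions with no sensors yield all-zero series flagged inactive; regional
  COP paths with fewer than two points yield `NA` velocity.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state, so generators are pure functions of
  (scenario, seed).

# Problem sizes used in the validation suite

The shipped tests and the acceptance script validate at deliberately
modest sizes chosen to exercise every code path with comfortable margins:
the default 10 × 30 sensor grid (300 sensors) with single-stance
recordings; 50 randomized rollover scenarios for metric recovery; 5
anthropometrically varied gait trials for the dynamic oracle; 2000 null
replicates at 26/29 arms for the type-I calibration; and full enumeration
of rank tests to total n = 8 (the largest size where enumeration stays
exact and instant).

# Known limitations

* Masks are static over a stance (no per-frame remasking) and
  percentage-based, not landmark-based; arch-type classification is out of
  scope.
* The inverse dynamics is sagittal-plane only and stops at the ankle; no
  joint powers.
* MNSI item-level rubrics are not implemented — totals are stored and
  validated, since instrument internals are defined by the instrument, not
  by this package.
* Proprietary insole formats are not parsed; recordings travel in the
  package's documented self-describing text dialect (fixed units: kPa, m,
  Hz), which round-trips bit-exactly.
* Cohort-level outcome tables from any particular study are not
  reproducible without its subject-level data; what the package reproduces
  is the *method*, validated against synthetic ground truth, plus the
  effect-size arithmetic implied by published group summaries.
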