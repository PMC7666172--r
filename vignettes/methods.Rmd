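---
title: "Models and methods: scoring stress-induced sleep-like inactivity and its behavioral consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresssleep)
```

## Overview

`stresssleep` implements a complete analysis pipeline for a social-defeat
stress paradigm in mice: accelerometer-based scoring of sleep-like
inactivity, its coupling to core body temperature, social-interaction zone
occupancy with susceptible/resilient classification, nose-proximity
sniffing-bout detection from markerless pose tracks, size-filtered c-Fos
cell counting in fluorescence images, and the statistics layer tying these
together. Because raw animal recordings of this kind are rarely released,
the package ships a first-class synthetic-cohort generator that emulates
every input modality with recorded ground truth; all recovery tests and the
acceptance analyses run on generated cohorts.

## Sleep-like inactivity from movement counts

The implanted abdominal sensor records 3-axis acceleration at 25 Hz and
reports movement counts on 12-s epochs: the number of times the synthesized
movement waveform crosses a threshold. We take the waveform to be the
magnitude of the sample-to-sample change of the acceleration-vector norm,
with a default threshold of 0.05 g. This choice is scale-free and immune to
the gravity offset; since the vendor's on-board counter is undocumented
(norm-based, per-axis, or band-passed), the raw-acceleration path
(`count_threshold_crossings()`) is labeled approximate and epoch-count CSV
input is the canonical substrate. One consequence of the norm-change
waveform worth knowing: a perfectly symmetric signed oscillation of constant
magnitude has constant norm and therefore produces no crossings; real
movement is irregular and does not hit this corner.

An epoch is scored *inactive* when its count is zero and it belongs to a run
of at least two consecutive zero epochs, i.e. at least 24 s without
voluntary movement — a behavioral definition of sleep-like inactivity whose
agreement with EEG-defined sleep (about 90%) is established in the
actigraphy literature. Three boundary rules matter:

* isolated single zero epochs are active;
* at the edges of a recording, a missing neighbor is treated as nonzero
  (a run is never started on unknown context);
* runs crossing an hour boundary need no special handling because scoring
  is per-epoch.

Hourly profiles report the percentage of *present* epochs that are active;
bins with less than 90% of their 300 epochs present are flagged invalid and
excluded from window means (sensor-dropout tolerance without imputation).
Window means over Zeitgeber-time (ZT) windows are epoch-weighted; the
conventional "ZT 13–15" window is the three hourly bins starting at ZT 13,
14 and 15, i.e. `window_mean_active(profile, 13, 16)`.

## Temperature coupling and the hypothermia screen

Per-mouse window means of body temperature are regressed on window means of
percent active by ordinary least squares, with the Pearson correlation and
point-wise 95% confidence and prediction bands. The severe-hypothermia
screen (`flag_hypothermia_outlier()`) refits the regression excluding the
candidate and flags it when its temperature lies strictly below the lower
95% *prediction* band at its activity level. The prediction interval — not
the confidence interval — is the statistically correct reference for a
single animal's observation; the confidence band would over-flag. Both bands
are exposed. Temperatures outside a 25–45 °C plausibility range are flagged
but never dropped: genuine severe hypothermia (down to ~31 °C) must survive
screening.

## Zone occupancy and susceptibility classification

The social-interaction arena is 30 × 40 cm with a mesh enclosure holding the
target mouse at one short wall. Zone depths are not standardized, so the
default splits the arena length into thirds: the interaction zone is the
13.33 cm band at the mesh wall, the avoidance zone the band at the opposite
wall — symmetric and conventional for this assay, and fully configurable.
Zone membership is decided per frame from the *centroid* (matching
commercial tracker behavior); pose-likelihood-gated frames (likelihood
< 0.9) are bridged by linear interpolation before zone assignment and
distance summation.

A stressed mouse is classified against the control cohort: its avoidance
time must exceed the control mean by more than one control SD (sample SD,
n − 1) *and* its interaction time must fall below the control mean by more
than one SD to be *susceptible*; meeting neither criterion makes it
*resilient*; exactly one criterion yields *intermediate*, which is retained
as its own label by default (real cohorts happen to partition cleanly; the
package does not force them to). Both thresholds are strict inequalities, so
a mouse exactly at mean + 1 SD is not counted as changed. The
high-social-interest set applies the same two criteria to *every* mouse,
controls included, and reports per-group proportions that feed Fisher exact
tests.

## Sniffing bouts

A sniffing bout is a maximal run of frames in which the nose stays within
2 cm of the mesh front face for at least 500 ms. "Or more" is inclusive:
the frame threshold is `ceiling(0.5 * fps)`, so 15 frames at 30 fps qualify.
The video frame rate is a required input and never assumed. Undefined
(low-likelihood) nose frames break runs; an optional `max_gap_frames`
bridges short gaps, but the default is 0 because the rule is a continuous
stay. Mean bout duration ("sniffing intensity") is the motivation proxy
correlated with interaction-zone time in the valence analysis. Automatic
totals are validated against manually scored intervals by Pearson/OLS.

## c-Fos spot counting

Cells are detected as connected components (8-connectivity) brighter than a
locally determined background: the background is a running median of radius
50 µm, and a pixel is foreground when it exceeds background plus
`k_sigma = 3` times the median absolute deviation of the in-ROI residuals.
Components are retained when their equivalent circular diameter
`2 * sqrt(area / pi)` lies in 9–30 µm, and counts are normalized per mm² of
ROI; hemisphere pairs are averaged per region and mouse. Because the
threshold is background-local, detection is invariant to a constant
intensity offset, and raising `k_sigma` can only reduce counts. Touching
cells are not split (no watershed) — a documented limitation acceptable at
the spot densities involved; the diameter filter is applied to the raw
component, with no pre-smoothing.

## The statistics layer

Standard tests are delegated to base R and emmeans rather than reimplemented:
Pearson (`cor.test`), pooled-variance unpaired t (`t.test`), two-sample
Kolmogorov–Smirnov (`ks.test`, exact for small untied samples), one-way
ANOVA with Tukey HSD (`aov`/`TukeyHSD`, Tukey–Kramer under unequal n),
mixed-design repeated-measures ANOVA (`aov` with a subject error stratum)
with Sidak-adjusted planned contrasts (`emmeans`), and ANCOVA by nested
model comparison (`lm`/`anova`): slope equality is the F test of the
interaction block of `y ~ x * group`, and — only when slope homogeneity is
retained at α = 0.05 — elevation equality is the F test of the group block
in the common-slope model. The two-sided Fisher exact test uses the
probability method (summing hypergeometric probabilities of tables no more
probable than the observed one), which reproduces conventional commercial
output. With a two-level within factor, sphericity holds trivially and no
correction is applied. Multiplicity policy mirrors the study design exactly
— Tukey within ANOVA families, Sidak within the RM-ANOVA family, and no
correction across c-Fos regions — rather than imposing a global FDR;
fidelity was preferred over reform and is stated here so nobody mistakes it
for an oversight.

Degenerate inputs (zero variance, noiseless fits) return flagged degenerate
records with exact coefficient estimates instead of raising, so pipelines
over pathological synthetic data keep running. Numerically empty
within-subject strata are reported as F = 0.

## The synthetic cohort: what it emulates, and what it does not

The generator's defaults are the study conditions: groups of 6 control, 13
stressed, and 9 stressed + sleep-deprived mice.

**Actigraphy.** Activity is a two-state semi-Markov chain on the 12-s epoch
grid. Inactive dwells are `2 + Geometric` epochs (mean 5 epochs = 1 min):
episodes last at least two epochs by construction, so the planted inactive
fraction equals the run-scored fraction exactly, and sub-epoch pauses are
folded into active-state count variation (active epochs emit
`1 + Poisson(3)` counts). Dark-phase active fraction is 0.694, light phase
0.30; the stress preset suppresses the dark-phase fraction to 0.401 from
shortly after the stress (ZT 12.2) until ZT 16.5, so the ZT 13–15 analysis
window is homogeneous; the sleep-deprivation preset forces 0.92 during
ZT 12–18. The reported group dispersions are SEMs of *observed* window
means, so the configured `between_sd = 0.12` is the target SD of observed
values; a single mouse's 3-h window mean carries ≈ 0.04 realization noise
from the dwell structure (measured on the generator), and latent per-mouse
offsets are therefore drawn with SD `sqrt(0.12² − 0.04²)`.

**Temperature.** Body temperature follows
`Tb = β0 + β1 · (30-min rolling active fraction) + mouse offset + AR(1)`,
with `β1 = (37.47 − 36.79)/(0.694 − 0.401) ≈ 2.32 °C` per unit active
fraction and `β0` anchored to the control means, AR(1) with ρ = 0.9 and
stationary SD 0.08 °C per minute sample, and a 0.12 °C between-mouse offset.
One stressed mouse optionally carries the severe-hypothermia trajectory: a
cosine-smooth pull toward a 31.1 °C trough at ZT 17 recovering by late
night. The trough is planted relative to the local activity-implied
baseline, so the minimum temperature equals the configured trough regardless
of the activity realization. The outlier is a *temperature-only*
phenomenon: its activity profile is an ordinary stress draw, because severe
hypothermia is precisely the observation that reduced movement cannot
explain.

**Social sessions.** A session is built from a per-mouse zone-visit
schedule whose totals equal the planted zone-time truth; the centroid
follows steered Ornstein–Uhlenbeck motion through the scheduled zones, so
realized occupancy differs from the plan only by ~1 s of boundary-traversal
jitter. Phenotype zone targets (percent of the 150-s session, interaction /
avoidance) are control 40/20 with 8 pp spread, resilient 52/8 with 1 pp
spread, susceptible 8/52 with 2.4 pp spread — i.e. susceptible mice sit
4 control-SD on the adverse side and resilient mice 1.5 control-SD on the
favorable side. This is an idealized, cleanly separated partition: it is
what makes exact label recovery a meaningful test. Real resilient mice
overlap the control distribution, so perfect recovery on synthetic cohorts
says nothing about borderline animals in real data — only that the
classifier implements its definition correctly.

**Sniffing.** Planted bout counts are Poisson with means 15.33 (control),
12 (resilient), 4.2 (susceptible; the 6 : 7 mixture averages ≈ 8.4) and 8
(sleep-deprived). Durations are shifted-Gamma, `0.55 + Gamma(8, ·)` s, so
every planted bout is detectable by the 500 ms rule by default
(sub-threshold proximity events can be planted by lowering
`min_duration_s`); within-mouse bout-duration distributions are not
published, so this family is a stated assumption. During a bout the nose is
held within 2 cm of the mesh; outside bouts it is kept beyond 2 cm, making
the planted bout list the complete ground truth for the detector. Mean bout
duration is generated with linear coupling to planted interaction time for
high-interest phenotypes (coupling 0.012 s/s, noise 0.08 s), calibrated so
the emergent high-interest correlation centers near r ≈ 0.74 — the
realized value is attenuated by control exclusions trimming the
interaction-time spread. The susceptible phenotype has zero coupling. In
the sleep-deprived group the correlation emerges around 0.85, above its
nominal ≈ 0.77 target, because that group's two-cluster structure
(avoidant/social) dominates the within-cluster noise; we report the
emergent value rather than forcing it.

**Imaging.** Backgrounds are flat base + linear illumination gradient +
Gaussian noise; spots are hard disks of 12–24 µm diameter at 6 × the noise
SD, placed by rejection sampling with a minimum gap and a border margin.
Out-of-range disks (6 and 36 µm by default) exercise the size filter. The
stress preset doubles planted counts in the designated activated regions
(the DMH- and VLPAG-like labels) and leaves the others unchanged.

What the generator does *not* emulate: biomechanically realistic
locomotion, EEG microstructure beneath the behavioral inactivity proxy,
pose-estimator error structure beyond iid likelihood dropouts, optical
point-spread or cell-shape variation, and any correlation between a mouse's
actigraphy and its social phenotype. Passing recovery tests therefore
demonstrates correctness of the analysis code under the stated statistical
structure, not robustness to every artifact of real recordings.

## Numerical choices and degenerate inputs

* ZT convention: ZT 0 = lights-on; hours as floats; a bin is labeled by its
  start; windows are `[from, to)` and may cross ZT 24.
* The bout frame threshold uses `ceiling(min_dur_s * fps)` so non-integer
  products behave inclusively.
* The median-filter radius for spot detection is capped just below half the
  image size so small images remain processable.
* Fisher enumeration follows the conventional `1e-7` relative tolerance
  when comparing table probabilities.
* Zero-variance inputs to t/ANOVA/Pearson return flagged degenerate
  records; noiseless ANCOVA input returns exact estimates with a
  `degenerate` flag instead of unstable p-values.
* Identical seed and configuration reproduce cohorts byte-for-byte; all
  generator randomness flows from the single seed argument.

## Problem sizes

The shipped tests and the acceptance script run at the scale the analyses
are designed for: one simulated day (7,200 epochs) of actigraphy and 1,440
temperature minutes per mouse; 150-s sessions at 30 fps; 288 × 288 px
images at 1 µm/px. Replicate studies use 100 cohorts for the recovery and
classification checks, 200 for the regression-coverage check, and 10,000
Monte-Carlo replicates for the type-I calibration of each core test.

## Known limitations

* The raw-acceleration crossing counter approximates an undocumented
  on-board algorithm; epoch counts are authoritative.
* Exact zone depths and the centroid-vs-nose convention of the original
  tracking software are unpublished; defaults are documented choices.
* Touching c-Fos cells merge into one component.
* The susceptibility thresholds depend on the control sample; with very
  few controls the thresholds themselves are noisy, which is inherent to
  the definition, not to the implementation.
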