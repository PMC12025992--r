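---
title: "Quantifying vocal-fold stiffness asymmetry from high-speed videoendoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vocal-fold stiffness asymmetry from high-speed videoendoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laryngovib)
```

## The problem

Benign vocal-fold lesions (polyps, cysts) are soft and only mildly perturb
the mucosal wave; early glottic carcinoma infiltrates deeper layers and
stiffens the fold, locally abolishing its vibration. High-speed
videoendoscopy (HSV, thousands of frames per second) records the true
oscillation cycle-by-cycle, so stiffness shows up as a *non-vibrating
region* in the image. `laryngovib` turns an HSV frame stack into
quantitative markers of that stiffness — the Stiffness Asymmetry Index
(SAI) from pixel-wise spectral maps, a registry of 38 kymographic
parameters from fold-edge trajectories — and carries them through the
statistics (normality-gated group tests, bootstrap ROC with Youden
cutpoints) and machine learning (SFFS-selected SVM under stratified
cross-validation) needed to ask whether they separate normophonic,
benign-lesion and malignant-lesion larynges.

No public HSV corpus of this kind exists, so the package ships a
first-class synthetic-recording generator with exact ground truth; every
claim the package makes is validated against it.

## Laryngotopography and the SAI

Each pixel over the glottis has a brightness time-series that oscillates as
the fold edges alternately cover and expose the dark glottal gap. After
removing the temporal mean and (by default) applying a Hann window — the
625 ms clinical segments contain a non-integer number of cycles, so leakage
control matters — the per-pixel DFT gives amplitude and phase maps at any
frequency. The fundamental is found per pixel as the in-band
(default 70–500 Hz, the physiological phonation range) amplitude argmax;
the global F0 is the amplitude-weighted mode over pixels whose peak clears
a robust noise floor. A pixel is classified *vibrating* when its amplitude
at F0 reaches `median + k·MAD` of the out-of-band amplitudes (`k = 4` by
default — conservative rejection of sensor noise; raising `k` can only
shrink the mask).

The glottis is split into left and right sides between the user-supplied
(or, for synthetic data, automatically detected) anterior and posterior
poles. Two modes exist:

* **straight** — the segment joining the poles;
* **adaptive** — a per-row boundary at the estimated *contact line* between
  the folds, so a lesion bulging across the straight axis is still
  assigned to its own side. Per image row the boundary is the midpoint of
  the inner envelope of the sub-pixel gap edges over time, with the two
  envelope endpoints weighted by the inverse of each edge's excursion
  range. The weighting matters: the mobile edge's envelope is truncated by
  the ~2 px gap width needed to resolve both edges near closure, whereas a
  rigid edge pins the contact line exactly; the weighted estimate is exact
  in both the symmetric and the one-sided-rigid limit.

With `RVA_s` the vibrating fraction of side *s*'s fold region (the region
is the boundary ± 25 % of the glottal length, a configurable margin — the
fold extent itself is not part of any standard definition), the index is

$$\mathrm{SAI} = 1 - \frac{\min(\mathrm{RVA}_L, \mathrm{RVA}_R)}
                          {\max(\mathrm{RVA}_L, \mathrm{RVA}_R)}.$$

No closed form for the SAI is printed in the clinical literature this
package follows — only its defining properties: a ratio of the two
relative vibrating areas, 0 for symmetric vibration, values toward 1 for a
stiff fold, and invariance when moderate perspective distortion scales one
side's vibrating *and* total areas proportionally. The `1 − min/max` form
satisfies all of them (the ratio invariance exactly, which the tests
assert at machine precision) and reproduces the reported group medians'
scale (≈ 0.06 / 0.3 / 0.6). This choice is a package decision and is
flagged as such.

## Kymographic parameterization

At `M = 33` axis positions (percent of fold length, posterior → anterior;
`M` must divide into thirds) the gap is segmented per frame by an
intensity threshold (Otsu over the fold region by default) and the two
edges are localized sub-pixel from the linear brightness ramp of the
anti-aliased edge. Cycle boundaries sit at minima of the lightly smoothed
glottal area waveform, separated by at least half the spectrally estimated
period. Per-position, per-cycle quantities (half peak-to-peak amplitudes,
open fractions, gap extrema) are averaged over cycles first — robustness
to cycle-to-cycle jitter — and then aggregated into 38 named parameters.

Definitions worth calling out, because only descriptive names are
standardized in the field:

* *amplitude asymmetry* is `100·|A_L − A_R| / max(A_L, A_R)`, giving the
  documented 0–100 % range (a sum denominator would cap at 100 only for
  one-sided vibration);
* *phase difference* is the cross-spectrum phase of the two edge
  trajectories at F0, in (−180°, 180°], averaged plain, by thirds, weighted
  by `A_L + A_R`, and as absolute values (so `AbsPhaseDiffAvg ≥
  |PhaseDiffAvg|`, an exact Jensen inequality the tests check);
* *phase asymmetry* is `100·|Δt|/T₀` with Δt the circular
  cross-correlation lag, quantized to whole frames;
* the *Center* parameters sample the position nearest 50 %FL;
* `Nonclosing` / `Nonopening` count positions whose cycle-averaged minimal
  gap stays above / maximal gap stays below the closure threshold
  `θ_c = 1 px`;
* the *open quotient* locates open runs with the same `θ_c` but refines
  the opening/closing instants by extrapolating the measured gap slope to
  zero gap. Plain frame counting above a 1 px threshold loses
  `≈ 2·θ_c/slope` per cycle (a 3–4 % negative bias at desk-scale
  amplitudes); the extrapolation removes the bias without touching the
  threshold semantics used by the closure parameters.

Positions where both folds are rigid have no defined asymmetry; they are
excluded from the asymmetry/phase aggregates and their count is reported.
Each formula lives in a single registry function so an alternative
convention can be swapped without touching the extraction chain.

## Statistics

Per parameter: Shapiro–Wilk in every group at α = 0.05 gates one-way ANOVA
(all groups normal) versus Kruskal–Wallis; a significant global test is
followed by the three pairwise Mann–Whitney tests with Bonferroni
correction (`min(1, 3p)`; the U statistic is oriented to the smaller
group).

ROC analyses are bootstrapped: 1000 resamples with replacement at the
original n, each resample's empirical ROC interpolated onto a fixed
101-point false-positive-rate grid (stepwise-conservative: the maximal TPR
at or below each grid FPR), then averaged. Degenerate resamples that lose
a class are redrawn so B stays fixed. The summary reports the mean AUC
with 2.5/97.5-percentile bounds, and the Youden optimum two ways: `youden`
is `max(TPR − FPR)` of the *mean* curve with the mean curve's
sensitivity/specificity at that point (so the identity
`J = sens + spec − 1` holds exactly in every exported table), while the
percentile CIs come from each iteration's own optimum. A concrete cutoff
value is only meaningful on the full unresampled data; `full_data_cutoff()`
scans the midpoints between distinct scores and breaks Youden ties toward
higher specificity. Scores are auto-oriented (larger = more pathological)
with a recorded flag.

## Classification

Features are z-scored with the *training* fold's mean and SD (sample
convention); held-out folds never see their own statistics, and the tests
assert this leak-freedom directly. The classifier is an RBF-kernel SVM
(e1071; `C = 1`, `γ = 1/p` on standardized features — conventional
defaults, recorded in every report since the study this follows does not
state them), with sigmoid-calibrated class probabilities; the three-class
task uses one-vs-rest models and assigns by the highest renormalized
probability.

Feature selection is classic SFFS: start from the best single feature,
then alternate an inclusion step with conditional exclusions that are
accepted only when they beat the best subset previously seen at that size.
The criterion is the mean balanced accuracy (chosen over raw error because
of the 21/39/42 class imbalance) of the SVM under an internal stratified
5-fold CV whose folds are drawn once from the seed, making the whole
search deterministic. The search stops at a subset-size cap
(`min(p, 10)`) or after two consecutive non-improving inclusion passes,
returning the best subset seen overall; accepted steps therefore carry a
non-decreasing criterion by construction.

`evaluate_cv()` runs stratified k-fold (k = 5; stratification is a package
choice — unstratified folds are fragile at these class sizes) with either
a fixed feature arm (e.g. the six univariately significant parameters,
`mct_features()`) or SFFS repeated inside every training fold. The
acceptance experiments use the fixed arm: it keeps the 20-seed ordering
experiment at seconds per seed while measuring the same qualitative
contrast.

## The synthetic generator

`simulate_recording()` renders two opposed fold edges about a vertical
midline: bright tissue (0.8), dark gap (0.1), linear anti-aliased edges,
additive Gaussian sensor noise — brightness modulation at the fold edge is
exactly what laryngotopography measures, so nothing more photometric is
needed. Kinematics are a half-rectified sinusoid with a rectification
level set so each fold is abducted for exactly the `open_quotient`
fraction of the cycle; an axial amplitude profile
`floor + (1 − floor)·sin(πu)` keeps the poles quieter than the midfold
without creating degenerate always-closed positions. A unilateral lesion
attenuates amplitude over a fractional extent (`stiffness` ∈ [0, 1]) and
may protrude medially (`bulge`); colliding folds are clamped to a shared
contact so the gap is never negative. Defaults reproduce the clinical
acquisition: 3200 fps, 625 ms (2000 frames), F0 150 Hz; the default desk
scale is 64 × 256 px with 400–2000 frames and the full 416 × 416 px
resolution is available through the same parameters. Ground truth carries
the analytic edges, the swept-band vibrating mask, and the expected SAI
(swept-area ratio), so recovery can be scored exactly.

What the generator does **not** emulate: tissue biomechanics (no
mass–spring or finite-element model — the mucosal wave is reduced to its
edge kinematics), endoscope optics and motion, Bayer color sensors,
aperiodic phonation, and bilateral lesions. Passing tests therefore show
that the measurement chain recovers known kinematics from realistic
image structure, not that it is robust to every clinical artifact.

`simulate_cohort_params()` draws tabular cohorts (default 21 normophonic /
39 benign / 42 malignant, the published cohort structure) directly in
parameter space, which keeps the 1000-iteration bootstrap and the 20-seed
selection/CV experiments at desk scale; videos are rendered only for the
imaging-chain tests. Group distributions are truncated normals. Only the
SAI group medians (≈ 0.06 / 0.3 / 0.6) and the qualitative ordering
malignant > benign > norm are published, so the remaining calibration is
the package's own: the spreads of the six discriminative parameters are
sized through the binormal identity `AUC = Φ(Δμ/√(σ₁²+σ₀²))` to reproduce
the published univariate AUCs (≈ 0.91 organic-lesion detection, ≈ 0.80
malignancy for SAI), and those six parameters share a latent "severity"
factor (loadings 0.75–0.85) because they are different summaries of the
same physical asymmetry — with independent draws a multivariate classifier
would separate the groups almost perfectly, which the published
cross-validated AUCs (0.93 / 0.83) rule out. These values were fixed once
from the printed statistics and are not tuned further.

## Numerical choices and degenerate inputs

* Frequency resolution is `frame_rate / n_frames`; all F0 recovery claims
  are stated relative to it.
* The vibration threshold uses median/MAD (not mean/SD) so a minority of
  strongly vibrating pixels cannot inflate the noise floor.
* A constant stack yields all-zero spectra (valid), an empty vibration
  mask, and "no oscillation detected" from the F0 search rather than an
  error; a constant glottal area waveform and sub-3-cycle segments are
  rejected in cycle segmentation.
* If both sides have zero vibrating area the SAI is defined as 1 with a
  "no vibration" status; an empty side region (bad poles) is an error.
* Adaptive partition with no detectable gap falls back to straight mode
  with a warning status.
* Bootstrap ties: tied scores are merged into single ROC operating
  points; the Mann–Whitney AUC applies the usual tie correction.
* All coordinates are 0-based row-major with the origin top-left in the
  exported formats; axis positions are percent of fold length in (0, 100].

## Problem sizes used in the shipped experiments

The test-suite and acceptance-script experiments run at desk scale chosen
by the package: 64–72 px wide, 96–192 px fold length, 400–2000 frames
per render; B = 1000 bootstrap iterations; 1000-replicate null
simulations; 20-seed selection and cross-validation experiments on
102-row cohorts. At these sizes the complete suite runs in a few minutes
on one CPU while every tolerance stated above is met; all sizes scale up
through the same configuration objects.

## Known limitations

* The SAI closed form and the fold-region definition are package choices
  consistent with, but not dictated by, the clinical literature; both are
  isolated behind configuration so alternates can be evaluated.
* Phase asymmetry is quantized to whole-frame lags (≈ 1.7 % of a cycle at
  150 Hz / 3200 fps).
* The adaptive boundary assumes the folds actually make contact somewhere
  in the cycle at most rows; a permanently wide-open glottis reverts to
  (interpolated) midline behaviour.
* Real endoscopic artifacts — motion, specular highlights, mucus,
  perspective tilt beyond a proportional scaling — are outside the
  generator and therefore outside what the tests demonstrate.
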