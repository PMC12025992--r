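# laryngovib

Quantitative analysis of vocal-fold vibration from high-speed laryngeal
video, for voice clinicians and biomedical-imaging researchers studying
benign and malignant glottic lesions.

Early glottic carcinoma stiffens the vocal fold and locally abolishes its
mucosal wave, while benign lesions (polyps, cysts) leave it largely
pliable. High-speed videoendoscopy (HSV, ~3200 frames/s) records the true
oscillation, so stiffness appears as a non-vibrating region in the image.
`laryngovib` implements the full measurement-to-classification chain:

* **Laryngotopography (LTG)** — per-pixel Fourier analysis of the
  brightness time-series over the glottis: F0, amplitude and phase maps,
  a robust vibration mask, and left/right partitioning of the glottis by a
  straight pole-to-pole axis or a locally adaptive contact-line boundary.
* **Stiffness Asymmetry Index (SAI)** — with `RVA_s` the vibrating
  fraction of side *s*'s fold region,

  `SAI = 1 − min(RVA_L, RVA_R) / max(RVA_L, RVA_R)  ∈ [0, 1]`,

  0 for symmetric vibration, →1 for a stiff fold, and exactly invariant
  when perspective scales one side's vibrating and total areas
  proportionally.
* **Kymography** — sub-pixel fold-edge trajectories at 33 axis positions,
  cycle segmentation of the glottal area waveform, and the registry of 38
  named vibratory parameters (amplitudes, open quotients, amplitude and
  phase asymmetries, phase differences).
* **Statistics** — Shapiro–Wilk-gated ANOVA / Kruskal–Wallis,
  Bonferroni-corrected pairwise Mann–Whitney tests, bootstrap ROC
  (B = 1000, percentile CIs), Youden index `J = sens + spec − 1` and
  full-data cutoffs.
* **Classification** — RBF-kernel SVM with leak-free fold-wise
  standardization, sequential floating forward selection (SFFS), and
  stratified 5-fold cross-validation for three tasks: Norm/Benign/Malignant,
  lesion-vs-norm, malignant-vs-benign.
* **Synthetic data** — a ground-truth-annotated generator of oscillating
  glottis recordings (class-dependent amplitude/phase asymmetry, lesion
  stiffness and bulge, sensor noise) and tabular 21/39/42 cohorts, so the
  whole chain is testable without any clinical download.

## Worked example

Render a recording with a stiff right-fold lesion and measure it:

```r
library(laryngovib)

rec <- simulate_recording(oscillation_params(
  n_frames = 400, width = 64, height = 128, glottal_length = 96,
  lesion_side = "right", lesion_extent = c(0.25, 0.75),
  lesion_stiffness = 0.8, noise_sd = 0.01, seed = 1))

analyze_stiffness(rec$stack)
#>   rva_left rva_right   sai    f0 mode
#> 1    0.194     0.133 0.312   152 adaptive
```

The right fold's relative vibrating area is depressed by the lesion, so
SAI rises to 0.31 (ground truth for this render: 0.49 — partial stiffness
attenuates rather than abolishes the local sweep, and the index grows
monotonically to ~0.97 for a fully rigid fold). The recovered F0 (152 Hz)
is the 150 Hz simulation truth at this render's 8 Hz spectral resolution.
Kymographic parameters from the same stack:

```r
part <- attr(analyze_stiffness(rec$stack), "objects")$partition
traj <- extract_edge_trajectories(rec$stack, part, m = 33)
pars <- compute_kymo_parameters(traj, segment_cycles(traj))
round(unlist(pars[c("AmplAsymAvg", "AbsPhaseDiffAvg", "OQAvg", "RGGA")]), 1)
#>     AmplAsymAvg AbsPhaseDiffAvg           OQAvg            RGGA
#>            34.0             0.1            59.6             0.0
```

34 % mean amplitude asymmetry (the lesioned positions vibrate at a
fraction of the healthy side), no phase lag (none was simulated), and the
simulated 60 % open quotient recovered to 0.4 points.

Cohort-level statistics and classification on a synthetic 102-subject
cohort calibrated to the published group structure:

```r
co <- simulate_cohort_params(cohort_spec(seed = 1))
roc <- bootstrap_roc(co$SAI, task_labels(co$label, "lesion_vs_norm"),
                     positive = "Lesion", b = 1000, seed = 1)
glance(roc)[, c("auc", "auc_lo", "auc_hi", "youden")]
#>     auc auc_lo auc_hi youden
#> 1 0.906  0.841  0.957  0.870

evaluate_cv(co, mct_features(), "malignant_vs_benign", seed = 1)
#> <classifier_report> task malignant_vs_benign, 5-fold CV (seed 1, none features)
#>            predicted
#> truth       Benign Malignant
#>   Benign        33         6
#>   Malignant      8        34
#> balanced accuracy 0.828, mean fold AUC 0.905
```

SAI alone detects organic lesions with a bootstrap AUC of 0.91 on this
cohort, and the six-parameter SVM grades malignancy at 0.83 balanced
accuracy — the generator is calibrated so these match the published
operating characteristics of the clinical cohort it emulates.

Every result object has `tidy()`/`glance()` methods and an `autoplot()`
(LTG maps, mean ROC curves with percentile bands, confusion matrices);
`run_pipeline(run_config(...))` drives simulator → LTG/SAI → kymography →
statistics → classification end to end with a provenance manifest, and
`inst/cli/laryngovib.R` exposes the same stages as shell subcommands.

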