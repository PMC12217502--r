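# earfluid

MRI-based inner-ear fluid volumetry and its link to hearing instability.

Hearing-instability disorders (Meniere's disease, sudden sensorineural
hearing loss, autoimmune inner ear disease) are associated with
endolymphatic hydrops — expansion of the endolymphatic fluid space. On MRI
the compartments can be separated: a STIR-like channel shows **all**
labyrinthine fluid as hyperintense, while a contrast-enhanced delayed
FLAIR-like channel shows **perilymph only**, because gadolinium never
enters the endolymph. For a structure (cochlea or vestibule) with
total-fluid mask S and perilymph mask F on a voxel grid of edge v (mm):

    TV = |S|·v³     PV = |F ∩ S|·v³     EV = TV − PV     E/P = EV / PV

with volumes in µL (1 mm³ = 1 µL). The E/P ratio is the size-normalized
hydrops index; the package quantifies it longitudinally, scores per-visit
hearing stability from audiograms, and runs the statistics that relate the
two.

The package is aimed at researchers prototyping or validating inner-ear
volumetry pipelines: every stage runs on synthetic data with known ground
truth, so there is nothing to download and every claim is testable.

## What is inside

* **Phantoms** — `phantom_spec()` / `generate_phantom()`: voxel phantoms of
  the vestibule (ellipsoid) and cochlea (2.5-turn spiral tube) with
  exact-count compartment calibration, rendered as co-registered STIR-like /
  FLAIR-like pairs with Gaussian blur and Rician noise; NIfTI I/O via
  `write_image_pair()` / `read_image_pair()`.
* **Volumetry** — `segment_fluid()` (seeded region growing,
  26-connectivity, fraction-of-robust-max / fixed / Otsu thresholds),
  `quantify_volumes()` (containment rule, so EV ≥ 0 and TV = PV + EV
  exactly), `classify_hydrops()`, `tv_deviations()`,
  `dose_delay_association()`.
* **Audiometry** — `compute_pta()` (4-frequency, LF, HF),
  `classify_snhl()`, `classify_stability()` (≥ 20 dB at one frequency or
  ≥ 15 dB at two consecutive frequencies vs the prior audiogram),
  `cumulative_shift()` (signed sum of shifts > 10 dB),
  `check_hi_inclusion()`.
* **Cohorts** — `cohort_params()` / `simulate_cohort()`: longitudinal
  ear-visit instances with AR(1) E/P dynamics, group calibrations
  (healthy-volunteer vestibular E/P 0.35 ± 0.086, cochlear TV
  93.18 ± 10.47 µL, ...), and audiograms whose shifts are sign-consistent
  with the latent endolymph change; `perturb_ratings()` for two-operator
  reliability studies.
* **Statistics** — `fisher_exact()` (sample OR + exact p),
  `or_confidence_interval()` (Woolf), `icc_agreement()` (ICC(A,1)),
  `kruskal_wallis()` + `mann_whitney_posthoc()` (Bonferroni),
  `per_ear_variance()` + `variance_group_compare()`, `pearson_cor()`, and
  `fit_gamma_glmm()` — a Gamma log-link GLMM with patient and
  ear-within-patient random intercepts (glmmTMB backend) with Nakagawa
  marginal/conditional R² (`nakagawa_r2()`).
* **Pipeline** — `validate_config()` / `run_pipeline()`: simulate →
  segment → score → analyse → report, deterministic per seed, with a thin
  command-line wrapper in `inst/cli/earfluid.R`.

## Worked example

```r
library(earfluid)

# a vestibular phantom at the healthy-volunteer calibration
ph <- generate_phantom(phantom_spec("vestibule", seed = 1))
ph
#> Ear phantom (vestibule): 23 x 19 x 17 voxels at 0.50 mm
#>   ground truth: TV 59.62 uL, EV 15.50 uL, E/P 0.351

measure_phantom(ph)   # segment both channels, quantify
#> vestibule fluid volumes: TV 59.38 uL, PV 44.12 uL, EV 15.25 uL, E/P 0.346
```

The ground-truth label map holds 59.62 µL of fluid at E/P 0.351; the
seeded region-growing segmentation of the noisy, blurred channels recovers
59.38 µL and E/P 0.346 — a 0.4 % volume error and an E/P error of 0.005.

```r
rep <- run_pipeline(list(seed = 1))
rep
#> Inner-ear fluid pipeline report
#> seed: 1
#> affected instances: 146 (104 stable, 14 unstable, 28 baseline-unknown)
#> hydrops-positive affected instances: 38
#> HV instances: 30
#> contingency (EH x instability): OR = 9.32, 95% CI [2.7, 32.6], p = 0.00029
#> GLMM: AIC 1181.2, R2 marginal 0.720 conditional 0.858
```

One simulated cohort (14 affected patients, 12 healthy volunteers): every
affected ear's first visit has no stability designation (28 baselines),
unstable hearing concentrates in hydropic instances (odds ratio 9.3), and
the Gamma log-link mixed model attributes most explained variance in the
4-frequency pure tone average to the fixed effects led by vestibular E/P.
Counts and statistics vary with the seed; the structure does not.

## Documentation

The methods vignette (`vignettes/earfluid-methods.Rmd`) describes the
phantom geometry and its deliberate simplifications, the audiometric rules
and their boundary conventions, the cohort generator's dynamics and
calibration, the statistical variants chosen (Woolf interval, ICC(A,1),
trigamma observation-level variance), and known limitations — in
particular the systematic underestimation of cochlear E/P at clinical
voxel sizes.
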