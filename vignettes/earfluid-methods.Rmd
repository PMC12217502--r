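---
title: "Methods: inner-ear fluid volumetry and hearing-stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inner-ear fluid volumetry and hearing-stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Endolymphatic hydrops (EH) — expansion of the endolymphatic fluid space of
the inner ear — accompanies hearing-instability disorders such as Meniere's
disease, sudden sensorineural hearing loss, and autoimmune inner ear
disease. Two co-registered MRI channels make the fluid compartments
separable *in vivo*: a STIR-like sequence in which **all** labyrinthine
fluid is hyperintense, and a contrast-enhanced delayed FLAIR-like sequence
in which **only perilymph** is hyperintense, because gadolinium accumulates
in perilymph but cannot cross into endolymph. Subtracting the perilymph
volume (PV) from the total fluid volume (TV) yields the endolymph volume
(EV), and the ratio E/P = EV/PV is a size-normalized index of hydrops for a
structure (cochlea or vestibule).

`earfluid` implements this volumetry, the audiometric scoring rules that
define hearing stability, and the longitudinal statistics that connect the
two — and, because no imaging data ship with the package, a synthetic
phantom and cohort generator that makes every stage testable end to end.

## Phantoms

`generate_phantom()` rasterizes a parametric structure into a voxel label
map (background / perilymph / endolymph) and renders the two channels.

* **Geometry.** The vestibule is an ellipsoid (axis ratios 1.25 : 1 : 0.8)
  with a single connected endolymph sub-region grown around an interior
  locus; the cochlea is a tapering spiral tube of 2.5 turns (outer radius
  2.8 mm tapering to 0.9 mm over a 2.4 mm rise) with the endolymph as an
  axial core. These shapes are deliberately schematic: they reproduce the
  *measurement* behaviour that matters — partial-volume loss at 0.5–0.8 mm
  voxels, a thin perilymph sheath around the cochlear endolymph, and
  (optionally) endolymph fragments near the voxel scale — not anatomy.
* **Exact-count calibration.** The fluid compartment is the
  `round(TV/voxel³)` voxels nearest the structure interior and the
  endolymph the `round(n·EP/(1+EP))` of those nearest the endolymph locus,
  so ground-truth volumes match their targets to within half a voxel. The
  only calibration error is integer rounding, which is why very small
  targets (under ~50 voxels) cannot meet a 1 % volume tolerance at coarse
  voxel sizes.
* **Rendering.** Foreground/background intensities (default 100/0), an
  isotropic Gaussian blur (default FWHM 0.6 mm) standing in for the scanner
  point-spread function, and Rician magnitude noise (default SD 10, i.e.
  10 % of contrast) — the standard magnitude-MRI noise model. The
  generator is bit-deterministic given its seed.
* **Fragmentation option.** `fragment_endolymph = TRUE` confines cochlear
  endolymph to ~0.5 mm beads separated by ~1 mm gaps along the spiral.
  This reproduces the discontinuous endolymph signal seen at the
  resolution limit of 3T imaging; the test suite documents that E/P
  recovery degrades under fragmentation while the connected default stays
  closer to truth. We chose the bead scale empirically: fragments much
  longer than a voxel concentrate the endolymph and *improve* detection,
  which is not the phenomenon of interest.

## Volumetry

`segment_fluid()` thresholds a channel (default: half of the 99th-percentile
"robust max"; fixed and Otsu policies available) and keeps the
26-connected supra-threshold component(s) reachable from operator-supplied
seed voxels. Seed placement is the semi-automated boundary: seeds and ROI
boxes are inputs, everything downstream is automatic. A seed below
threshold is an explicit error ("seed outside fluid").

`quantify_volumes()` applies the containment rule — the perilymph mask is
intersected with the total-fluid mask before subtraction — so `EV = TV −
PV ≥ 0` holds by construction and `TV = PV + EV` is exact in voxel units;
clipped perilymph voxels are counted and surfaced as a warning. Volumes are
reported in µL (1 mm³ = 1 µL). Whether the original acquisition pipeline
enforced containment is unknown; here it is a declared design choice that
guarantees the conservation invariant under imperfect segmentation.

At the default noise and blur the vestibule segmentation achieves Dice
above 0.97 against ground truth and TV errors of ~1–2 %; the cochlear E/P
is systematically underestimated (sheath thinner than a voxel in places),
which mirrors the known difficulty of cochlear endolymph quantification and
is why only cochlear TV — not cochlear E/P — is treated as a calibration
quantity.

## Audiometric rules

All rules operate on air-conduction thresholds at 0.25–8 kHz quantized to
the clinical 5 dB lattice.

* PTA variants: 4-frequency (0.5/1/2/4 kHz), low-frequency (0.25/0.5), and
  high-frequency (4/8) arithmetic means.
* SNHL: air-conduction PTA > 25 dB HL **and** air–bone gap ≤ 10 dB.
* Per-visit stability (vs the most recent prior audiogram): unstable if
  |Δ| ≥ 20 dB at ≥ 1 frequency or |Δ| ≥ 15 dB at ≥ 2 *consecutive*
  frequencies; magnitudes are used so both worsening and improvement
  trigger. Unstable visits split into improved/worsened by the sign of the
  cumulative shift; a triggered visit whose large shifts cancel exactly is
  flagged "indeterminate" rather than forced to a side. Baseline visits
  are "unknown".
* Cumulative shift: the signed sum of per-frequency differences strictly
  larger than 10 dB in magnitude.
* Inclusion screen over serial audiometry: fluctuating hearing (≥ 20 dB at
  one frequency or ≥ 15 dB at ≥ 2 frequencies — no adjacency requirement,
  unlike the per-visit rule; both are implemented as stated rather than
  harmonized) or sudden loss (≥ 30 dB at 3 consecutive frequencies), with
  sudden taking precedence.

The suite verifies the implementation against an independent brute-force
enumeration of these sentences over lattice shift vectors.

## Cohort simulation

`simulate_cohort()` generates the longitudinal instance table the
statistics consume. Group calibrations are the healthy-volunteer and
affected-ear values the volumetry is benchmarked against: vestibular E/P
0.35 ± 0.086 (HV) and 0.43 ± 0.15 (affected); cochlear E/P 0.24 ± 0.05 and
0.23 ± 0.07; TV 59.57 ± 8.67 / 57.39 ± 9.32 µL (vestibule) and
93.18 ± 10.47 / 91.42 ± 11.86 µL (cochlea). Fourteen affected patients
contribute two ears with 3–7 visits over 15 months; twelve healthy
volunteers contribute two ears with 1–2 visits.

Each ear's vestibular E/P follows a stationary AR(1) process (φ = 0.6)
around its baseline. Ears whose baseline exceeds 0.45 are "hydrops-prone"
and carry a larger innovation SD (0.09 vs 0.015; healthy-volunteer ears
0.008). These values were derived, once, from the marginal structure the
simulation is meant to emulate: with the default shift gain, a
hydrops-prone ear crosses the instability trigger on roughly 40 % of
transitions and ~45 % of affected ears are prone, giving on the order of
one in five post-baseline instances unstable and about a third of affected
instances hydropic (E/P > 0.50, strict). The larger innovation SD in
prone ears is also what produces the higher per-ear E/P variance in ears
with EH or unstable hearing that the variance comparisons detect.

Hearing is linked to endolymph through a Gamma log-link model: the latent
level is `exp(β₀ + β_EP·E/P + diagnosis and age effects + patient RE + ear
RE)`; baseline audiograms scatter a frequency profile around that level,
and later visits shift each frequency by `shift_gain × λ_f × ΔE/P` (rounded
to 5 dB), so per-frequency shifts are *sign-consistent* with the latent
endolymph change by construction. Setting `shift_noise_sd > 0` decouples
shifts from endolymph dynamics for null simulations. The hydrops flag,
instability designations, and E/P–PTA correlations therefore emerge from
the generative mechanism rather than being stamped on.

What the simulator does **not** emulate: real anatomy and registration
error, radiologist hydrops reads (the flag is a numeric threshold, default
E/P > 0.50, configurable), missing visits, conductive overlays, and
measurement error structure beyond independent Gaussian noise. Passing
tests show the pipeline's statistics behave correctly under the assumed
mechanism, not that the mechanism is true of patients.

## Statistics

* **Contingency**: sample odds ratio `ad/bc` with the two-sided Fisher
  exact p (probability-mass rule, via `stats::fisher.test`) and a Woolf
  log-OR interval, `exp(ln OR ± z·√(1/a+1/b+1/c+1/d))`. The Woolf interval
  was chosen because it reproduces the benchmark interval on the
  reconstructed hydrops-by-instability table; zero cells yield an infinite
  OR with a flag, and the interval refuses zero cells rather than silently
  correcting.
* **Reliability**: ICC(A,1) — two-way random effects, absolute agreement,
  single rater — from the mean-squares decomposition; the variant matches
  the interchangeable-operator design of inter-rater volumetry.
* **Group comparisons**: tie-corrected Kruskal–Wallis H with post-hoc
  two-sided Mann–Whitney U and Bonferroni adjustment `min(1, p·family)`;
  the family is the number of pairwise comparisons in a panel.
* **Variance comparisons**: per-ear sample variance across visits
  (single-visit ears are excluded with a warning — variance is undefined
  at n = 1), compared between ear groups by Mann–Whitney.
* **GLMM**: Gamma log-link with nested random intercepts (patient,
  ear-within-patient), fitted by Laplace maximum likelihood via `glmmTMB`.
  We verified on known-parameter simulations that `lme4::glmer`'s Gamma
  implementation underestimates random-intercept variances by ~40 % at
  realistic sizes while `glmmTMB` recovers them; `glmer` remains in the
  suite as an independent cross-check of the fixed effects. Coefficients
  are reported raw and with continuous predictors z-scored (for
  coefficient plots); diagnosis indicators are non-exclusive columns since
  ears may carry more than one diagnosis.
* **R²**: Nakagawa decomposition on the link scale with observation-level
  variance `trigamma(shape)` for log-link Gamma (`log(1 + 1/shape)`
  exposed as an option); marginal = fixed / total, conditional adds the
  random-intercept variances, so zero random variance forces marginal =
  conditional.

## Pipeline

`validate_config()` reads a YAML run configuration, fills defaults, and
rejects unknown keys; `run_pipeline()` executes simulate → phantom
volumetry check → stability scoring → statistics → report, writing
`cohort.csv`, `designations.csv`, `volumes.csv`, `report.json`, and a
human-readable summary, all deterministic per seed. Stage failures abort
with a stage-labelled message; a contingency table with an empty marginal
(possible in very small cohorts with no unstable visit) is reported as
degenerate rather than treated as a failure. Hydrops status can come from
the simulator's latent truth or from the measured E/P (config switch), to
separate labelling error from measurement error.

## Problem sizes and numerical choices

The test suite runs at desk scale, chosen to give stable checks at
interactive runtimes: 100 random phantom specs for the calibration
property, 24 phantoms per structure for the healthy-volunteer round trip,
100 replicate GLMM fits at 100 patients × 2 ears × 5 visits for coverage,
500 replicates for type-I error checks, and 200 replicates for the
variance-comparison power analysis (14 ears per group, 5× innovation-SD
contrast, observed power well above 0.8). Exact oracles (Fisher
enumeration over all 2×2 tables with total ≤ 12, stability-rule
enumeration over 5 dB lattices) are exhaustive or densely sampled.

Numerical conventions: strict inequality at the hydrops threshold and in
the >10 dB cumulative-shift filter; weak inequalities in the audiometric
triggers exactly as the rules state them; thresholds quantized to 5 dB
within [−10, 120] dB HL (generator floors at 0 dB HL); region growing uses
26-connectivity; the segmentation threshold defaults to half the
99th-percentile intensity, which is exact on noise-free binary phantoms
and robust to the Rician background floor at the default noise level.

## Known limitations

Cochlear E/P is biased low at clinical voxel sizes here as in practice;
the phantom geometry is schematic; the AR(1) dynamic is a modelling
convenience (the benchmark study reports only per-ear variances, not a
dynamical model); the hydrops flag is a numeric stand-in for a
radiologist's read; and the simulated audiogram mechanism, while
sign-consistent with endolymph change, is far simpler than real
fluctuating hearing loss.
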