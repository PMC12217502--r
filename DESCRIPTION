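Package: earfluid
Title: Inner Ear Fluid Volumetry, Hearing Stability Scoring, and Longitudinal Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for MRI-based quantification of inner ear fluid compartments
    and their relationship to fluctuating hearing loss. Generates synthetic
    voxel phantoms of the cochlea and vestibule rendered as co-registered
    total-fluid (STIR-like) and perilymph-only (FLAIR-like) image pairs with
    known compartment volumes, and simulates longitudinal ear-visit cohorts
    with group-dependent endolymph/perilymph (E/P) ratio dynamics and linked
    audiograms. Provides seeded region-growing segmentation and voxel-count
    volumetry (total, perilymph, and endolymph volumes and E/P ratios),
    rule-based audiometric scoring (pure tone averages, sensorineural hearing
    loss criterion, per-visit hearing stability designation, cumulative
    threshold shift), and the accompanying statistics: Fisher exact
    contingency analysis with Woolf odds-ratio intervals, two-way
    absolute-agreement intraclass correlation, Kruskal-Wallis and
    Mann-Whitney group comparisons with Bonferroni correction, per-ear
    variance comparisons, Pearson correlation, and Gamma log-link generalized
    linear mixed models with Nakagawa marginal and conditional R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
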