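Package: callosalMRI
Title: Multiparametric MRI Analysis of the Corpus Callosum in
    Parkinsonian Syndromes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a multiparametric magnetic resonance imaging
    analysis of the corpus callosum (CC) aimed at neurodegenerative
    parkinsonism. Implements midsagittal CC segmentation and the
    Hofer-Frahm subdivision into areas I-V, planimetry, gray-level
    co-occurrence texture features (entropy and inhomogeneity),
    diffusion tensor fitting with fractional anisotropy mapping,
    deterministic streamline tractography seeded from the callosal
    areas, tractwise fractional anisotropy statistics (TFAS), a
    control-referenced combined z-score, Bonferroni-corrected group
    comparisons, and ROC-based group discrimination. A synthetic
    phantom cohort generator provides T1-weighted slices and diffusion
    tensor volumes with configurable group-level effects so the whole
    cascade can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
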