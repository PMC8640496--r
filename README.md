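# callosalMRI

Multiparametric MRI analysis of the corpus callosum (CC) for
neurodegenerative parkinsonism. The package implements, as a tested and
reusable pipeline, the full analysis cascade used to ask whether — and
where — the CC of patients with progressive supranuclear palsy (PSP,
subtypes PSP-RS and PSP-P) and Parkinson's disease (PD) differs from
healthy controls:

1. **Morphometry** — AC/PC alignment, midsagittal slice extraction,
   intensity-threshold (Otsu) CC segmentation, subdivision into the five
   Hofer–Frahm areas (cuts at 1/6, 1/2, 2/3, 3/4 of the
   anterior–posterior extent), and planimetry (area ratios).
2. **Texture** — per-area gray-level co-occurrence features on the
   midsagittal T1w slice: entropy (−Σ p log₂ p) and inhomogeneity
   (Σ p (i−j)², the contrast form that *rises* with neighbor
   differences).
3. **Microstructure** — log-linear diffusion tensor fitting, fractional
   anisotropy (FA) maps, 8 mm FWHM Gaussian smoothing, age correction
   against controls, deterministic streamline tractography on the
   averaged control dataset (FA threshold 0.2, curvature/dot-product
   threshold 0.9), and tractwise FA statistics (TFAS: per-subject mean
   FA over each area's tract voxels, excluding FA < 0.2).
4. **Scoring** — control-referenced z-scores and the combined score

   C = (z_FA + 0.5 z_entropy + 0.5 z_homogeneity) / 2,

   pooled-variance t-tests with Bonferroni correction over the
   3 contrasts × 5 areas family, and ROC/AUC (midrank ties, identical to
   Mann–Whitney U/(n₁n₀)) for the area-II combined score.

Because patient MRI of this kind is not shareable, the package includes
a **synthetic phantom cohort generator**: an arch-shaped CC template
with per-area texture, five U-shaped callosal fiber bundles as prolate
tensor fields with controllable FA, optional DWI synthesis (48
directions at b = 1000 s/mm² + 4 b = 0, Rician noise), and group-level
effects confined to areas I–III (PSP > PD), so the entire cascade is
testable end to end. See the methods vignette
(`vignettes/callosal-mri-methods.Rmd`) for models, parameter choices and
limitations.

## Worked example

```r
library(callosalMRI)

cfg <- pipelineConfig(cohort = cohortConfig(n_psp_rs = 10, n_psp_p = 6,
                                            n_pd = 14, n_control = 12,
                                            seed = 42))
res <- runPipeline(cfg)
print(res)
#> ccAnalysis of 42 subjects
#> combined score: corrected p < 0.05 in:
#>  area       contrast  p_corrected
#>     I PSP vs control 1.847488e-03
#>    II PSP vs control 3.862234e-06
#>   III PSP vs control 3.729000e-10
#>   III  PD vs control 2.459270e-02
#>    II      PSP vs PD 3.683167e-04
#>   III      PSP vs PD 1.083032e-06
#> AUC [PSP vs control, area II] = 0.964
#> AUC [PD vs control, area II] = 0.762
#> AUC [PSP vs PD, area II] = 0.902
```

The simulated PSP group shows corrected significance of the combined
score in callosal areas I–III and nowhere in IV–V, PD differs most in
area III, and the area-II score separates PSP from controls better than
PD from controls — the qualitative pattern the phantom's default
effects encode. Per-subject tables (`res$planimetry`, `res$texture`,
`res$tfasMeans`, `res$panel`), the test tables (`res$tests`, one per
marker family including planimetry) and the ROC objects (`res$roc`)
are all returned; `writePipelineResults(res, dir)` writes them as TSV
and JSON. A configuration can also be read from JSON or YAML with
`readPipelineConfig()`, and reruns with the same configuration are
bit-identical.

Individual stages are ordinary functions operating on S4 containers
(`CCLabelMap`, `TensorVolume`, `FAMap`, `TractSet`, `ROCResult`), e.g.:

```r
tpl   <- makeCCTemplate(phantomGeometry())
slice <- synthesizeT1wSlice(tpl, amplitude = 3, noiseSd = 2, seed = 1,
                            smoothAmplitude = 6)
mask  <- segmentCC(slice)
lm    <- subdivideHoferFrahm(mask, pixdim = c(2, 2))
planimetry(lm)
areaTexture(slice, lm, levels = 32)
```

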