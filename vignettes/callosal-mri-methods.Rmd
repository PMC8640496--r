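---
title: "Methods: multiparametric MRI analysis of the corpus callosum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric MRI analysis of the corpus callosum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callosalMRI)
```

## The problem

Progressive supranuclear palsy (PSP) involves the frontal white matter
early, and the corpus callosum (CC) — the main interhemispheric
commissure — is a natural window on that involvement: its midsagittal
cross-section can be parcellated into five areas (the Hofer–Frahm
scheme: I prefrontal, II premotor/supplementary motor, III primary
motor, IV primary sensory, V parietal/occipital/temporal), and each
area can be probed with three complementary measurements:

* **planimetry** — the area's size relative to the whole CC (atrophy);
* **texture** — gray-level co-occurrence statistics of the T1w
  midsagittal slice (microstructural disorganization not visible as
  atrophy);
* **tract FA** — the mean fractional anisotropy over the fiber tract
  that originates in the area, from diffusion tensor imaging.

The package implements this cascade end to end, z-normalizes the
markers against a control group, combines them into a single score per
area, and evaluates group discrimination (PSP, its subtypes PSP-RS and
PSP-P, Parkinson's disease as a disease control, healthy controls) with
Bonferroni-corrected t-tests and ROC analysis. Because clinical MRI of
this kind is not freely shareable, the package carries a synthetic
phantom cohort generator that reproduces the statistical structure the
analysis assumes, so that every stage is testable.

## Pipeline stages and their models

### Alignment and midsagittal extraction

`alignACPC()` applies a rigid + isotropic-scale transform built from
the anterior/posterior commissure landmarks and the interhemispheric
normal, resampling trilinearly. Landmarks are inputs, not detected.
`extractMidsagittal()` takes the central sagittal slice; when the slice
count is even, the two central slices are averaged (a fixed tie rule so
the operation is deterministic). Synthetic cohorts are generated in a
common space, so the pipeline itself runs with identity alignment; the
transform machinery is exercised by its own tests.

### CC segmentation

`segmentCC()` estimates Otsu's threshold inside a region of interest
(default: the central 50 percent of each image dimension — enough to
cover both the CC and surrounding background, which is what Otsu
needs), binarizes the whole slice, keeps the largest 8-connected
component and fills enclosed holes of up to 3 voxels. 8-connectivity is
required because the thin callosal arch can run diagonally;
the component labeling is implemented in the package because the
available image library only labels 4-connected components. A
`border_contact` flag marks masks touching the image border. A fixed
threshold can override Otsu for reproduction of operator-chosen
thresholds.

### Hofer–Frahm subdivision and planimetry

`subdivideHoferFrahm()` cuts the mask bounding box orthogonally to the
anterior-posterior axis at fractions 1/6, 1/2, 2/3 and 3/4 of its
extent (anterior = 0). These fractions are the normative convention of
the parcellation scheme. A voxel belongs to the stripe containing its
column center; a center exactly on a cut goes to the anterior stripe
(0-based columns, half-open stripe intervals). Note that the fractions
are not symmetric about 1/2, so mirroring a mask front-to-back
corresponds to subdividing with the complementary fractions
(1/4, 1/3, 1/2, 5/6); the test suite checks exactly that equivariance.
`planimetry()` reports per-area voxel counts, mm² and ratios to the
total CC count; ratios sum to one by construction.

Whether "area size" should be measured on one slice or averaged over
several central slices is left open by the source material;
single-slice measurement is used and the choice is configurable through
which slice(s) the caller passes.

### Texture

Within each area independently, intensities are min–max quantized into
L = 32 levels (`quantizeGrayLevels()`), co-occurrences are accumulated
over the four distance-1 offsets (0,1), (1,0), (1,1), (1,−1), pooled,
symmetrized and normalized (`computeGLCM()`), and two features are
computed:

* `glcmEntropy()`: −Σ p log₂ p, zero iff the area is constant;
* `glcmInhomogeneity()`: Σ p (i−j)², the contrast form.

Per-area quantization makes the features invariant to global intensity
shifts and scanner scaling, so they are comparable across subjects.
The second feature is deliberately named *inhomogeneity*: the standard
GLCM feature called "homogeneity" (Σ p/(1+(i−j)²)) *falls* when
neighboring gray levels differ more, which is the opposite of the
behavior the clinical literature describes under that name. The
contrast form is the standard feature that rises with neighbor
differences, and the alias "homogeneity" is accepted in outputs. L and
the offsets are configurable; L = 32 assumes reasonably populated
areas — at phantom scale (tens to hundreds of voxels per area) the
co-occurrence table is sparse and entropy saturates near its
upper bound, a known limitation discussed below.

### Diffusion: tensor fit, FA, smoothing, age correction

`fitTensor()` solves the log-linear least-squares system
ln S = ln S₀ − b gᵀDg per voxel (requires ≥ 6 diffusion-weighted and
≥ 1 b = 0 volume; voxels with non-positive signals are excluded).
`computeFA()` derives eigenvalues in closed form (Cardano), clamps
negative eigenvalues to zero (counting them), and evaluates
FA = √(3/2)·‖λ−λ̄‖/‖λ‖, with FA(0-tensor) ≡ 0. `smoothFA()` applies a
separable Gaussian with σ = FWHM/(2√(2 ln 2)) per axis (default FWHM
8 mm, converted to voxels through the stored spacing; reflective
boundary). `ageCorrect()` fits the voxelwise FA–age slope in controls
only and subtracts β(v)·(ageᵢ − mean age) from every subject, i.e.
residual plus prediction at the cohort mean age.

### Tractography and TFAS

Tracking runs once, on the component-wise average of the control
tensors (`averageControlDataset()`), seeded with one seed per CC-area
voxel on the midsagittal plane. `trackStreamlines()` integrates
bidirectionally along the principal eigenvector with nearest-neighbor
tensor lookup and 1 mm steps, flipping the eigenvector sign to continue
the previous direction, and stops on: FA < 0.2; dot product of
consecutive unit step directions < 0.9 (a per-step curvature limit of
arccos 0.9 ≈ 25.8°); the volume boundary; or 300 steps per direction.
The "vector product" threshold is interpreted as this scalar-product
bound: a cross-product-magnitude bound of 0.9 would forbid straight
continuation and allow near-orthogonal turns, which contradicts
conventional streamline tracking. Streamlines shorter than two steps
are discarded. Nearest-neighbor tensor lookup is the simplest
convention consistent with conventional tracking; seeding density,
step size and the thresholds are configurable.

The visited-voxel set of each area's tract is then fixed and applied to
every subject's smoothed, age-corrected FA map:
`tfasSubjectMeans()` computes the per-subject mean FA over those
voxels, *not considering values below 0.2* (cortical gray matter
reaches FA ≈ 0.2, so lower values are treated as non-white-matter).

### Combined score and statistics

Per area, the three markers are z-normalized against the controls
(sample SD, n−1) and combined as

C = (z_FA + 0.5·z_entropy + 0.5·z_homogeneity) / 2,

an equal weighting of microstructure (FA) and texture (the two texture
features sharing one unit of weight). Computed verbatim, the score
partially cancels in affected subjects, because their FA z-scores fall
while their texture z-scores rise. `combinedScore()` therefore exposes
`flipTexture`: with the texture z-scores negated, affected subjects get
uniformly *reduced* scores, which matches the reported direction of
group differences and is the only variant with discriminative power.
The pipeline defaults to `flip_texture = TRUE` and records the choice
in its configuration; the verbatim variant remains available.

`groupCompare()` runs pooled-variance Student's t-tests (Welch
optional) for PSP vs controls, PD vs controls and PSP vs PD per area,
Bonferroni-corrected with family size m = 15 (3 contrasts × 5 areas —
the conservative reading of correcting "all the results"; m is
configurable and recorded in the output). Stars mark corrected
p < 0.01 and p < 0.001. Groups that are exactly constant and equal give
t = 0, p = 1 (relevant for phantom planimetry, which is identical
across subjects by construction). `rocCurve()` builds the ROC curve of
the area-II combined score over all unique thresholds with midrank tie
handling, so the trapezoidal AUC equals the Mann–Whitney statistic
U/(n₁n₀); point estimates only, no confidence intervals.

## The synthetic cohort generator

`cohortConfig()` + `generateCohort()` emulate:

* a midsagittal CC as a half elliptical annulus (arch) on a 56 × 36
  grid at 2 mm spacing, AP extent 44 voxels, shared by all subjects
  (so planimetry carries no group signal, by design);
* a T1w slice: background at 50 percent of the CC base intensity 120,
  a fixed smooth low-frequency intensity component (SD 6, correlation
  length 3 voxels), a per-area rough (voxelwise) texture component with
  amplitude 3 in controls, global Gaussian noise SD 2;
* five U-shaped fiber bundles, one per area, sweeping left–right
  through the 15-voxel x extent with a gentle downward arc, rasterized
  as elliptical tubes whose anterior–posterior half-width stays inside
  their own area's column range; tensors are prolate with principal
  axis along the local tangent and eigenvalues chosen in closed form
  (δ = FA/√(3−2FA²)) to hit the target FA at mean diffusivity
  7·10⁻⁴ mm²/s; background tensors are near-isotropic at FA 0.05;
* group effects confined to areas I–III: additive FA reductions
  (PSP-RS 0.06/0.11/0.10, PSP-P 0.05/0.08/0.08, PD only area III 0.05)
  and texture amplitude increases (PSP-RS 3.5/5.0/4.0, PSP-P
  2.5/3.5/3.0, PD 2.0/2.5/2.5), zero in areas IV–V; control bundle FA
  0.7;
* between-subject variability: a per-subject, per-area Gaussian FA
  offset (SD 0.03), voxelwise tensor component noise (SD 2·10⁻⁵
  mm²/s), and fresh texture fields per subject;
* demographics: group sizes 46/20/66/44 (PSP-RS/PSP-P/PD/controls) and
  ages drawn from N(71, 9²), matching the study population the
  analysis is designed for; age has no true effect by default, and
  `age_slope` injects a linear FA–age trend to make the age correction
  testable.

No per-group effect *magnitudes* are available as published numbers —
only the qualitative pattern (alterations confined to areas I–III,
larger in PSP than PD, FA loss in PD only in area III, no area-size
differences). The default effect sizes above were chosen once so that
a study-sized cohort reproduces that qualitative pattern with the
area-II AUC ordering PSP vs controls > PD vs controls > 0.5, and are
not re-tuned thereafter.

`synthesizeDWI()` adds the acquisition layer when needed: 48
unit gradient directions at b = 1000 s/mm² (a deterministic spherical
Fibonacci lattice) plus four b = 0 volumes, monoexponential signals and
Rician noise at a stated SNR (the magnitude-MRI standard; noiseless
when SNR is unset). The default cohort works directly with tensor
volumes for speed; the DWI → tensor-fit round trip is validated
separately (noiseless recovery is exact to numerical precision).

### A note on texture amplitudes and min–max quantization

Under per-area min–max quantization, any texture model that is purely
*linear* in its amplitude (e.g. i.i.d. noise scaled by A) produces
amplitude-invariant co-occurrence features — min–max normalization
removes scale. The generator therefore superimposes the rough
(amplitude-scaled) component on a *fixed-amplitude* smooth component:
the rough/smooth variance ratio then grows with the amplitude, and
inhomogeneity responds strictly monotonically. With the smooth
component disabled (its default in `synthesizeT1wSlice()` is 0), an
amplitude-0, noise-0 slice is exactly constant and its entropy is 0.

### What the phantom does not emulate

Realistic anatomy outside the CC; partial-volume edges (segmentation
Dice on phantoms is near 1 and says little about segmentation of real
T1w data); scanner artifacts, bias fields, motion; nonlinear
inter-subject warping (generation in a common space replaces MNI
normalization, and a hook accepts precomputed affines for real data);
crossing fibers (one bundle per voxel, so tracking is easier than in
vivo); realistic entropy dynamics (areas have tens to hundreds of
voxels, so entropy is nearly saturated and the group signal is carried
mainly by tract FA and inhomogeneity). Passing tests on phantoms
validate the computational contracts, not clinical performance.

## Numerical choices

* Voxel indices are 0-based in the subdivision arithmetic; stripe
  intervals are half-open with anterior winning exact ties.
* Otsu's threshold is computed on a 256-bin histogram of the ROI after
  min–max normalization.
* Cardano eigenvalues clamp the acos argument into [−1, 1]; tensors
  with p² ≈ 0 are treated as isotropic. FA is clamped into [0, 1].
* Smoothing uses a dense banded convolution matrix per axis
  (kernel radius 3σ, reflective boundary) — exact and fast at these
  volume sizes.
* The tracking step is 1 mm on a 2 mm grid; positions map to voxels by
  half-open nearest-neighbor binning; a candidate point in a
  sub-threshold voxel is *not* added to the streamline, so visited
  voxels are supra-threshold by construction.
* Degenerate group tests (zero pooled variance) are defined as t = 0,
  p = 1 when the means agree and |t| = ∞, p = 0 otherwise.
* Reproducibility: every cohort is generated from one master seed via
  per-subject derived seeds; re-running a pipeline configuration gives
  bit-identical tables.

## Validation problem sizes

The shipped test suite validates: the GLCM features against a naive
pair-enumeration oracle on 100 random 16×16 masked images (tolerance
1e−12); the subdivision against hand-derived rectangle fixtures and a
voxelwise oracle; segmentation recovery (Dice ≥ 0.98) on 20 phantom
slices at the default contrast and noise; the noiseless DWI→tensor→FA
round trip on a ≈ 40³ volume (max FA error < 1e−6); the tracking
termination contract and threshold monotonicity on a 3×3 parameter
grid; the TFAS exclusion rule against brute-force voxel loops (100
random instances); the combined-score arithmetic and AUC–Mann–Whitney
equivalence (random instances up to 50 per class); Bonferroni
familywise-error control on 200 reduced-size null cohorts
(15/15/15 subjects on a 40 × 26 grid); and the qualitative
group-difference pattern on 20 study-sized default cohorts. These
sizes keep the whole suite at desk scale while leaving each check
statistically meaningful.

## Limitations

The texture features operate in a sparse co-occurrence regime at
phantom resolution; the package reports them faithfully, but entropy
in particular has limited discriminative power there. The combined
score's sign convention is resolved pragmatically (see above) and both
variants are computable. Verbal AUC quality labels are not
implemented. Atlas-based volumetry, which the original workflow used
only as an external cross-validation of planimetry, is out of scope.
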