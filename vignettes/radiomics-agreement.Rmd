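---
title: "Radiomic feature agreement on synthetic CT/MRI phantoms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic feature agreement on synthetic CT/MRI phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Radiomics derives quantitative imaging biomarkers from segmented tumor
volumes, but the numbers depend on implementation choices that are rarely
visible to the end user: how voxels are resampled, how intensities are
discretized, how texture matrices are aggregated over directions, how a
surface is triangulated. Two radiomics programs configured "identically"
can disagree, and the same feature computed from CT and from MRI of the
same tumor may or may not carry the same information.

`radagree` implements the full measurement chain needed to study both
questions on data with known ground truth: NIfTI-1 volume/mask I/O, the
three standard voxel-resampling strategies, MRI histogram-matching
normalization, fixed-bin-number discretization, 66 IBSI-style features in
six families (4 shape, 16 histogram, 18 GLCM, 11 GLRLM, 12 GLZLM,
5 NGTDM), and an agreement analysis based on the two-way mixed-effects,
absolute-agreement, single-measurement intraclass correlation coefficient

$$\mathrm{ICC} = \frac{MS_R - MS_E}
{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with $MS_R$, $MS_C$, $MS_E$ the row (subject), column (rater) and residual
mean squares of the two-way ANOVA without replication, $n$ subjects and
$k = 2$ raters. ICC values are banded poor ($<0.5$), moderate
($0.5$–$0.75$), good ($0.75$–$0.9$) and excellent ($\ge 0.9$); negative
estimates are reported as computed and banded poor. An F statistic
$MS_R/MS_E$ with $(n-1)$, $(n-1)(k-1)$ degrees of freedom is reported
alongside each ICC as a descriptive subject-separation test; it never
enters the banding.

Because real paired CT/MRI cohorts with tumor segmentations are rarely
shareable, the package ships a synthetic paired-phantom generator whose
cross-modality coupling is an explicit dial, so the agreement analysis can
be validated against a known truth — something no private clinical dataset
permits.

## Extraction dialects

The two "raters" in the software comparison are *extraction dialects*:
named bundles of implementation choices on which real programs have
historically differed.

| axis | dialect A | dialect B |
|---|---|---|
| GLCM aggregation | merge counts over 13 directions | per-direction, average features |
| GLRLM aggregation | merge | average |
| surface algorithm | mesh (marching tetrahedra) | exposed voxel faces |
| internal-resampling grid anchor | corner | center |
| NGTDM edge rule | any in-ROI neighbour | full 26-neighbourhood required |

Dialects are surrogates, not reproductions of any specific program: the
exact internal settings of the programs the design mimics are not public
at this granularity. The axes were chosen because each is a documented
divergence between implementations and a plausible driver of imperfect
ICC.

"Internal" resampling applies the dialect's own grid anchoring inside the
extraction call, so dialects genuinely disagree on the resampled grid —
the mechanism by which distinct resampling algorithms degrade software
agreement. "External" resampling is a shared prior stage (always
corner-anchored), so both dialects consume identical inputs; "original"
skips resampling.

## Preprocessing

Order: resample → normalize (MRI only) → discretize. Working spacings
default to 1 mm isotropic for CT and 1.4 mm for MRI.

* **Resampling**: output size per axis is
  `ceiling(in_size * in_spacing / target)`; images are sampled at output
  voxel centers with an interpolating cubic B-spline (IIR prefilter, poles
  per the standard recursive algorithm, mirror boundaries), masks with
  nearest neighbour; out-of-grid samples clamp to the nearest edge value.
  B-spline prefiltering makes resampling to the native spacing reproduce
  in-grid values to ~1e-9, which the tests assert.
* **Normalization**: MRI intensities are histogram-matched to a
  healthy-subject reference by pairing 64 quantile knots (computed above
  the volume-mean background threshold) and interpolating linearly between
  knots. The mapping is monotone, hence rank-preserving. The reference is
  itself resampled to the MRI working spacing before matching under the
  resampling arms — the upstream description is silent on this point and
  the choice is recorded as a guess. CT is never normalized (HU are
  already standardized).
* **Discretization**: fixed bin *number* (default 64) over the in-ROI
  range: `bin(x) = min(floor(n (x - min)/(max - min)) + 1, n)`; a constant
  ROI maps to bin 1 and is flagged degenerate. Fixed bin number is the
  appropriate choice when intensity units are arbitrary, as for MRI.

## Texture matrices and features

All four matrix families use 3-D neighbourhoods: GLCM/GLRLM the 13 unique
Chebyshev-distance-1 offsets, GLSZM 26-connected zones, NGTDM the
26-neighbourhood mean. Masked voxels always break adjacency: pairs, runs
and zones never cross the ROI boundary. Formulas follow the IBSI
reference definitions; entropies are log base 2; Kurtosis is excess;
Variance/MAD use the population (1/N) convention; percentiles use linear
interpolation (R type 7). Degenerate inputs (constant ROI, single voxel,
zero variance) produce NaN plus a degeneracy flag rather than an error, so
cohort tables stay rectangular; NGTDM caps Coarseness at 1e6 and sets
Busyness to 0 when its denominator vanishes.

Two subtleties found while testing, now asserted as the correct behavior:

* Merge and average aggregation agree for GLCM features on a constant ROI
  (every direction collapses to $p(1,1)=1$) but *not* for GLRLM features,
  because chord lengths through any non-degenerate shape differ across the
  13 directions. The dialect contrast is therefore real even on constant
  phantoms.
* NGTDM features are not all invariant under duplicating voxels:
  Busyness, Complexity and Contrast are (they are $p$-normalized), while
  Coarseness and Strength scale inversely through their $\sum_i s_i$
  terms, $s_i$ being a per-level *sum* in the IBSI convention.

The mesh surface uses marching tetrahedra (six Kuhn tetrahedra per cell,
midpoint crossings on the binary mask) rather than marching cubes: the
same 0.5-isosurface triangulation idea without a 256-case table. On a
digitized ball it overshoots the analytic sphere area by roughly 20–25%
at 1 mm resolution while the voxel-face area tends to 3/2 of it; the test
suite asserts this ordering rather than a closeness no binary isosurface
mesher achieves. What matters for the package's purpose is that the two
surface algorithms are *different in a realistic way*, and that each is
exact where it should be (voxel-face area of a cube is exactly 600 mm² at
1 mm spacing).

## The synthetic cohort

Each patient owns one continuous tumor shape — an ellipsoid with
lognormal semi-axis ratios under a random rotation, perturbed by smooth
directional noise, bounded by construction — sampled on each modality's
grid, so CT and MRI masks describe the same geometry up to voxelization.
Intratumoral texture is a Gaussian random field (white noise smoothed to a
correlation length, default 6 mm, standardized) evaluated at voxel
centers; the MRI field is
$T_{MRI} = \rho\,T_{shared} + \sqrt{1-\rho^2}\,T_{indep}$ with
$T_{shared}$ the CT field evaluated on the MRI grid, so
`texture_correlation` $\rho$ is an explicit, recoverable ground truth.

Intensity models: CT = lung (−800 HU) / mediastinal slab (40 HU) / tumor
(60 HU) + texture + Gaussian noise (SD 5 HU); MRI = affine rescale of the
tissue map (arbitrary units) × a smooth multiplicative bias field
(amplitude 0.2) + texture + heavier Gaussian noise (SD 20). MRI noise is
Gaussian, not Rician: magnitude bias modelling is irrelevant to the
agreement mechanics under study. Defaults state the emulated acquisition:
CT 0.7×0.7×2 mm, MRI 1.4×1.4×2.5 mm, 35 patients.

Two generator choices deserve justification because they shape every
downstream ICC:

* **Per-patient heterogeneity multiplier** (lognormal, SD(log) 0.35,
  shared between modalities) scaling the texture amplitude, plus a milder
  length-scale jitter. Without it every phantom has identical texture
  statistics, between-subject variance of texture features collapses, and
  ICC — a variance ratio — measures nothing. Real cohorts vary in tumor
  heterogeneity; the multiplier is that variation.
* **Desk-scale grids**: the default CT grid is 64³ (44.8 mm in-plane field
  of view), which caps the default tumor diameter range at 20–32 mm; the
  stated clinical range (20–150 mm) is available with `full_size = TRUE`.
  This keeps the full 3-arm × 2-dialect × 2-modality grid at desk scale.

Child seeds are derived as
`(seed*1000003 + patient*10007 + stream*101) mod (2^31 - 19)`, one stream
per role (shape, CT texture, MRI texture, noises, nuisance draws), so
cohorts are bit-reproducible, including NIfTI bytes on disk.

### What a green test does and does not establish

The generator emulates the *statistical structure* the agreement analysis
assumes — shared geometry, modality-specific intensity scales and noise,
tunable texture coupling. It does not emulate anatomy, respiratory
motion, contrast kinetics, scanner-specific reconstruction kernels, or
Rician noise. A green cross-modality test therefore validates the
*pipeline and statistics*, not any clinical claim about which features are
stable in patients.

Three validation worlds are used, each chosen for what it isolates:

1. **Default world, ρ = 0**: geometry shared, texture uncoupled, full
   noise/bias/grid differences. Expected and observed: shape Volume and
   Surface Area good/excellent, the large majority of texture features
   poor — the qualitative fingerprint of the cross-modality analysis.
2. **Null-difference world, ρ = 1**: identical acquisition grids, equal
   noise, no bias, identity intensity map. The modalities are then
   statistically exchangeable and ≥ 90% of features reach good/excellent.
   The stragglers are the low-gray-level-emphasis family (LGRE, SRLGE,
   LRLGE, LGZE, SZLGE): they weight the extreme lower tail of the
   discretization range, which is set by independent noise minima in each
   modality, so their true cross-modality ICC is genuinely low even here.
   This is a real property of tail-sensitive features, not a pipeline
   defect.
3. **Controlled ρ sweep**: the null-difference world with the
   heterogeneity multiplier disabled. With the multiplier active, shared
   amplitude correlates amplitude-dependent texture features across
   modalities even at ρ = 0 (a deliberate, realistic confounder); with the
   full default world, MRI noise and bias pin texture ICC near zero at
   every ρ. Only the controlled configuration makes the ρ-mixture the
   sole coupling, and there the median texture ICC rises monotonically
   over ρ ∈ {0, 0.5, 1}.

## Agreement analysis details

Per feature, the ratings matrix is patients × two raters (two dialects at
fixed modality, or CT/MRI at fixed dialect — raw feature values in the
latter case, so absolute agreement penalizes scale differences, which is
intended). Patients in which the feature is degenerate for either rater
are dropped for that feature; a feature with fewer than 3 usable patients,
or an undefined ICC (zero denominator), is flagged and excluded from the
band percentages, whose denominator is the count of defined ICCs (all 66
in regular runs) so they always sum to 100. Reports print percentages
with one decimal, list good/excellent features explicitly ("none" when
empty), and carry a provenance block (package version, config hash, seed).

## Numerical choices

* B-spline prefilter tolerance 1e-14; mirror boundaries; constant volumes
  are reproduced to machine precision (partition of unity).
* ICC denominator guarded at 1e-14 relative to the squared data scale;
  below it the ICC is declared undefined rather than returned as noise.
* Quantile knots with heavy ties are collapsed by averaging reference
  quantiles per unique source knot, preserving monotonicity.
* All entropies treat 0·log 0 as 0.
* NIfTI is written as float64 (volumes) / uint8 (masks) with an
  axis-aligned sform; oblique orientations are rejected on read rather
  than silently reoriented.

## Known limitations

* Only axis-aligned NIfTI-1; no DICOM, no 4-D, no oblique geometry.
* Dialects A/B span four implementation axes; real programs differ on
  more (gray-level rebinning inside matrices, distance weighting, 2-D
  fallbacks).
* The F test accompanies ICC descriptively; no multiple-testing
  correction is applied anywhere.
* Desk-scale defaults trade anatomical scale for runtime; `full_size`
  restores clinical extents but not anatomical realism.
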