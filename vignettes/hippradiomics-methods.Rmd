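---
title: "Hippocampal subregion radiomics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hippocampal subregion radiomics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippradiomics)
```

## The analysis in one paragraph

The package quantifies texture in four hippocampal subregions (left/right
× caudal/head) of spatially normalized T1-weighted MRI and asks three
questions: which radiomic features differ between Alzheimer's disease
(AD), amnestic mild cognitive impairment (aMCI) and normal controls (NC);
which of those features track cognition (MMSE, AVLT); and how well the
features classify subject pairs (AD–NC, aMCI–NC, AD–aMCI) under a nested
leave-one-out RBF-SVM. Each subregion contributes 423 features — 47 base
features on the original patch and on each of 8 wavelet sub-bands — for
1692 per subject. Because no clinical cohort ships with the package, a
synthetic cohort generator with a controllable disease effect stands in
for the MRI data; it is first-class, tested code, and everything the
statistics and classification stages consume is generated through it.

## ROI handling

Volumes and masks are accepted as NIfTI-1 pairs on a common grid; the
package deliberately performs no registration or atlas reslicing — it
validates shape agreement and otherwise trusts the upstream
normalization. A subregion patch is the tight bounding box of the mask's
foreground with the binary mask carried alongside: every downstream
statistic is computed over foreground voxels only, never over the
zero-filled background. Masks with fewer than 27 foreground voxels are
rejected outright; below roughly a 3×3×3 neighbourhood, co-occurrence
and run-length matrices degenerate to near-empty counts and the
resulting features are noise. Voxel indexing is 0-based with half-open
bounding boxes internally, which keeps the cropping arithmetic free of
off-by-one ambiguity.

## Feature definitions and conventions

**Quantization.** GLCM and GLRLM require discrete gray levels. Intensities
are binned into `ng = 64` equal-width levels spanning the foreground
min–max range (top bin closed), a common default that balances matrix
sparsity against gray-level resolution; `ng` is exposed in
`radiomics_config()`. Because binning depends only on the position of a
voxel within the min–max span, all 33 texture features are exactly
invariant under positive affine intensity transforms `x → a·x + b`
(`a > 0`); the test suite asserts this invariance, and the corresponding
equivariance of first-order location/scale features. Invariance under
general monotone transforms does *not* hold (equal-width bins are not
rank-based), and is not claimed.

**First-order (14).** Energy, entropy, kurtosis, maximum, mean, mean
absolute deviation, median, minimum, range, root mean square, skewness,
standard deviation, uniformity, variance — over foreground voxels, with
entropy/uniformity computed on the same `ng`-bin histogram as the
texture quantization. Kurtosis is non-excess (Gaussian → 3) by default —
under this convention "positive kurtosis" reads as a histogram more
peaked than the Gaussian only relative to 3; an excess-kurtosis flag is
provided. On zero-variance patches skewness and kurtosis are defined as
0 so feature vectors stay finite; the degenerate case is also what the
constant-patch tests pin down.

**GLCM (22).** Distance-1 co-occurrence over the 13 unique 3-D offsets
(26-connectivity modulo point symmetry), pairs accumulated symmetrically
and normalized per direction; features are computed per direction and
averaged over non-empty directions (count pooling is a config
alternative). Entropy-type features use log base 2 with 0·log 0 ≡ 0.
Where the literature splits on denominators the registry fixes one
reading per feature rather than guessing intent: `homogeneity1` divides
by `1 + |i−j|`, `homogeneity2` by `1 + (i−j)²`; `idn`/`idmn` use the
`Ng`- and `Ng²`-normalized versions of the same forms; `sum_variance` is
the second moment of `p_{i+j}` about the *sum average* (some texts
center on sum entropy); GLCM `variance` is `Σ (i − μ)² p(i,j)` with `μ`
the mean gray level under `p` (equal to the marginal mean for a
symmetric matrix); `correlation` on a zero-variance matrix is defined as
0 (0/0 form). Each choice is a documented convention, applied uniformly.

**GLRLM (11).** Maximal same-level runs along raster lines in the same 13
directions, broken by background voxels and patch boundaries; the
standard run-emphasis family (SRE, LRE, GLN, RLN, run percentage,
LGLRE, HGLRE, SRLGLE, SRHGLE, LRLGLE, LRHGLE), averaged across
directions. The conservation identity Σ R(g,l)·l = foreground voxel
count per direction is asserted property-style in the tests.

Shape and volume descriptors are deliberately absent: with atlas-derived
masks shared across subjects they are constant within subregion and
carry no subject-level information.

## Wavelet sub-bands

Each patch (background zero-filled) is decomposed once with the 8-tap
Symlet-4 filter pair, separably along the three axes with decimation by
2, yielding the 8 sub-bands LLL…HHH in fixed order. Boundary handling is
periodization: the per-axis transform is then an orthogonal map for
every even length (odd lengths repeat the last sample), which is what
makes the two exactness tests possible — perfect reconstruction through
the synthesis bank to 1e−8 relative error, and energy conservation to
1e−6 relative on full-mask patches. A decimated rather than stationary
transform is implemented; the 8-band naming is consistent with either,
so this is a documented implementation choice, not a claim about any
particular prior pipeline. Each band carries a 2×2×2 max-pooled
companion mask (foreground if *any* source voxel is foreground), which
bounds background leakage to the filter-width halo while keeping every
genuinely informative coefficient; sub-band quantization is re-derived
per band from that band's own (signed) coefficient range, since a global
intensity range is meaningless across bands.

## Screening model

Features are adjusted for age and gender by per-feature OLS on
`[1, age, gender]` fit over **all** subjects jointly — fitting per group
would absorb exactly the group differences the screen is meant to find —
and the adjusted value is the residual plus the grand mean. The omnibus
test is the classical one-way fixed-effects F across NC/aMCI/AD,
Bonferroni-controlled at `0.01 / 1692` (the family is the full feature
count). Post hoc pairwise tests are Welch t by default, chosen for
consistency with the Welch form of the classifier's ranking statistic
(pooled-variance t is a flag). Spearman correlations with MMSE use
midrank ties and the t approximation for P, over the pooled AD + aMCI
subjects by default (per-group subsets are available; the pooled reading
treats cognition–texture coupling as a property of the patient spectrum);
AVLT maps use the same machinery at P < 0.05. "Significant in a
subregion" is bookkept per base feature identity (`band__family__feature`)
so multi-subregion counts aggregate the four subregions' flags, and
−log10 P values are floored at 1e−300 for finite heat-map output.

## Classifier protocol

Min-max normalization (train rows only, test rows not clipped; constant
training features map to 0), Welch-t ranking with at most 200 features
kept, RBF-SVM via LIBSVM (e1071), and two nested LOOCV loops: each inner
fold re-normalizes and re-ranks on its own training rows and scores every
(cost, gamma) on the powers-of-two grid `c ∈ 2^{−5..15}`,
`g ∈ 2^{−15..3}` (the canonical LIBSVM coarse grid; overridable); the
inner winner (ties → smaller cost, then smaller gamma) is refit on the
full outer training set and evaluated on the held-out subject. SEN/SPE
take the patient group as positive; AUC uses the rank (Mann–Whitney)
formulation with midranks. The feature *count* is tuned outside the
outer loop (`select_feature_count()`), matching the protocol of tuning a
single k and reporting its LOOCV accuracy; this carries an optimistic
selection bias, which is why the per-count curve is returned alongside
the winner and a fully nested treatment of k is left to the caller's
loop. Train-only min-max (rather than whole-sample) is the defensible
reading where the protocol is silent, and it is what the no-leakage
invariant requires: everything entering a fold's model is a function of
that fold's training rows, verified behaviourally by the permutation-null
test (chance-band accuracy on permuted labels), which is the decisive
integrity check for nested CV. `repeated_leave_k_out()` repeats the same
train-side pipeline on random stratified (round-robin) 4-subject
hold-outs.

## The synthetic cohort generator

Each subject's volume is a white-noise Gaussian field smoothed with a
per-group kernel sd and rescaled to a common intensity sd: the smoothing
length is the texture knob (longer correlation → visibly coarser
texture → lower GLCM entropy/contrast), and a per-group mean shift is
the intensity knob. Defaults encode the modeled cohort structure: group
sizes 45/33/38 (NC/aMCI/AD), age ≈ 68–72 ± 7–8 years and near-balanced
gender in all groups, MMSE 28.6/26.6/17.6 ± 1.4/2.6/5.6 truncated to
[0, 30], and four AVLT scores falling monotonically with severity — so a
default cohort reproduces the demographic table of a typical memory-clinic
discovery sample. The single `effect` multiplier scales every deviation
from NC: `effect = 0` gives an exchangeable imaging null (used for
type-I-error and permutation calibration), `effect ≈ 5` a cohort
separable in a handful of features. Masks are four fixed ellipsoids
(semi-axes 8×6×5 voxels ≈ 1000 voxels, the scale of a 1 mm isotropic
hippocampal subregion) shared by all subjects, as atlas masks would be.
The generator emulates group-dependent texture/intensity and covariate
structure only — not hippocampal anatomy, scanner noise spectra,
partial-volume effects or site effects — so green tests demonstrate the
*pipeline's* correctness and calibration, not clinical performance on
real MRI; the headline clinical accuracies of any real study are outside
what synthetic data can certify.

## Numerical choices and degenerate inputs

- Constant patches: quantization maps everything to level 1 with a
  warning; GLCM concentrates at (1,1); skewness/kurtosis/correlation
  use their 0 conventions.
- Directions with no valid voxel pair (possible for thin ROIs) are
  flagged empty and excluded from feature averaging; all-empty is an
  error, precluded by the 27-voxel floor.
- Welch ranking sentinels: zero variance with zero mean difference → T
  = 0; zero variance with nonzero difference → signed infinity, ranked
  first.
- P-value floor 1e−300 before −log10.
- CSV round trips hold to 1e−12 relative; full precision is written.

## Problem sizes in the shipped runs

The test suite and acceptance script run everything end to end at desk
scale, chosen once as representative rather than exhaustive: cohorts of
2–10 subjects per group for imaging-level checks (a subject extracts in
about 2 s), 50 replicates of 1692-feature null tables for screening
calibration, 10–20 label permutations at n = 40 × 200 features for the
leakage null, and reduced powers-of-two grids (4 grid points) with 10–20
ranked features for the CV integrity checks — the protocol under test is
identical at every scale, only the grid density and replicate counts
grow in a full run. The analysis drivers under `analysis/` run the same
stages on a full-size default cohort (45/33/38 subjects) and write their
tables under `results/`.

## Known limitations

Equal-width quantization is not rank-invariant; the stationary-transform
variant of the sub-band decomposition is not implemented; Bonferroni is
the only multiplicity control (by design, matching the screening
protocol the package implements); the 3-group problem is only attacked
pairwise; and `select_feature_count()`'s outside-the-loop tuning of k is
optimistically biased, as discussed above.
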