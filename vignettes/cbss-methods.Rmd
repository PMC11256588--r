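---
title: "CSF-based spatial statistics: models, conventions and design choices"
author: "cbss package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSF-based spatial statistics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbss)
```

## The problem

Cerebrospinal fluid (CSF) in the ventricles, cisterns and sulcal spaces is
not static: bulk, incoherent motion of CSF water attenuates the diffusion
MRI signal at low diffusion weighting (b ≤ 200 s/mm²), before thermal
diffusion dominates. The apparent diffusivity fitted in that low-b regime —
the IVIM *pseudodiffusivity* D\* — is a candidate marker of CSF dynamics,
of interest in aging and memory-clinic populations where impaired CSF
circulation and glymphatic clearance are suspected.

`cbss` implements the analysis chain needed to turn a low-b diffusion
acquisition into regional CSF statistics:

1. **fractions** — tissue fraction maps, a pseudo-T2 contrast, and the CSF
   voxel mask;
2. **parcellation** — assignment of every subarachnoid CSF voxel to a named
   sulcus or cistern via its nearest gray-matter landmark;
3. **pdiff** — per-voxel log-linear fitting of
   $S(b) = S(0)\,e^{-b D^*}$ and regional median pseudodiffusivity (MPD);
4. **finemap** — distance zones along the lateral and third ventricles,
   anchored at the start of the third ventricle;
5. **stats** — reproducibility, inter-regional correlation with
   multiplicity control and bootstrap aggregation, covariate-adjusted
   associations with cognition and imaging markers;
6. **phantom** — a synthetic digital head that exercises every stage with
   known ground truth.

## The signal model and its estimator

Within the CSF mask each voxel's decay over all volumes with
b ≤ 200 s/mm² is modelled as single-compartment isotropic
pseudo-diffusion. The fit is ordinary least squares of $\log S$ on $b$;
D\* is minus the slope, S(0) the exponentiated intercept. The default
acquisition (16 b-values 0–1500 s/mm², three gradient directions per
non-zero b, five b = 0 volumes, 2 × 2 × 4 mm voxels) contributes 38 points
to each fit: CSF is isotropic, so the three directions are treated as
replicate samples and enter as independent unweighted points, as do the
five b = 0 volumes. Whether replicate directions should instead be averaged
before fitting is configurable in principle but immaterial for an OLS fit
with balanced replicates: the slope is identical either way.

Non-positive signals (possible under noise after background suppression)
are dropped pointwise; a voxel is marked missing when fewer than two
distinct b-values survive. The log-linear estimator was chosen over
nonlinear least squares because it is closed-form, deterministic, and at
CSF-like SNR agrees with a nonlinear fit to a fraction of a percent (the
test suite compares medians of both estimators on identical Rician draws
and requires agreement within 2%). The nonlinear fit is retained in the
tests only, as an independent oracle.

MPD is the *median* of voxel D\* in a region — robust to the outlier
voxels that partial-volume and pulsation artifacts produce. Bilateral
regions are summarized as the average of the left and right medians
weighted by the corresponding volumes; midline regions pass through.

## CSF masking and the 0.8 threshold

A voxel is CSF when its free-water fraction passes 0.8 *and* its
anatomical label is ventricular or subarachnoid. The two natural readings
of the threshold ("larger than 0.8" vs "0.8 or larger") differ only at
exact equality; `cbss` uses one configurable comparator applied both to the
mask and to fit eligibility, defaulting to `>=`, with `>` available via
`fw_comparator = "gt"`. The choice is documented rather than silently
fixed because no principled tie-breaker exists at a measured value of
exactly 0.8.

The pseudo-T2 contrast mixes GM and CSF fractions 1:2; the package
normalizes by 3 so the image stays in [0, 1] — the ratio is what matters,
the scale is a convention. The white-matter fraction, when not supplied,
comes from a deterministic two-class segmentation of corrected FA: 2-means
with fixed initialization at the 10th and 90th percentiles and a soft
assignment by relative distance to the class centers. This is a
deliberately simple, fully reproducible segmenter: it has no random
restarts, converges to the same split on the same input, and degrades
explicitly (constant input returns an all-zero WM fraction with a
warning). GM closes the sum to one, clipped to [0, 1] with the clip count
reported; inputs whose CSF + WM exceeds one at more than 1% of voxels are
rejected as inconsistent.

## Parcellation by nearest gray-matter landmark

Each subarachnoid voxel receives the label of the gray-matter atlas voxel
nearest in *physical millimetres*; with 2 × 2 × 4 mm voxels the anisotropy
matters (three in-plane steps, 6 mm, lose to one slice step of 4 mm — and
win at 1 mm in-plane spacing). Ventricular voxels keep their anatomical
segmentation labels and are never propagated into. Exact distance ties are
resolved to the lowest label code, which makes the output deterministic
and permutation-accountable.

The implementation contract is equality with an exhaustive all-pairs
scan. Internally the candidate ranking uses a BLAS cross-product
factorization of the squared distance, which is applied only when the mm
coordinates are integers — every term is then an exact integer in double
precision, so ties resolve identically to the brute-force scan; other
spacings use a direct per-axis difference path with the same arithmetic as
the oracle. The property suite checks voxel-for-voxel equality against an
independent brute-force implementation over randomized volumes.

Regions too small to summarize are governed by one cohort-wide rule: a
region with fewer than 10 voxels in at least 50% of subjects is dropped
from all analyses; if fewer subjects are affected the region is kept and
only those subjects' MPD is marked missing. Both parameters are
configurable; missingness is always counted, never silently dropped.

## Ventricular fine mapping

The "start of the third ventricle" — the anchor for distance zones — is
the overlap between the lateral-ventricle masks dilated by 3 voxels and
the third-ventricle mask. The dilation uses the face-connected
(6-neighbour) structuring element iterated three times; full 26-neighbour
connectivity is available, since the anatomical definition does not fix
the element. Each ventricular voxel is then binned by its minimum
Euclidean mm distance to the seed into half-open bins [0,5), [5,10),
[10,15), [15,20); a voxel at exactly 5.0 mm falls in the second bin, and
voxels at 20 mm or more are not analysed. Third-ventricle zones count
outward (zone 1 nearest the seed); lateral-ventricle zones count inward
(zone 1 is the 15–20 mm shell). Distances are straight-line, not geodesic
within the CSF; for the short ranges involved this is the standard
convention and the geodesic refinement is out of scope.

## The statistics battery

All variables except sex are z-transformed (mean 0, SD 1 over non-missing
entries). Sex is coded 0 = male, 1 = female and enters models untouched.

* **Reproducibility.** Per region and subject, the MPD is recomputed on
  100 random 95% subsamples of the region's voxels (without replacement,
  seeded); the coefficient of variation sd/mean of the replicates is
  reported. Bilateral regions re-apply the volume-weighted side-median
  convention inside every replicate.
* **Inter-regional correlation.** Pearson correlation over
  pairwise-complete subjects for every region pair, BH-adjusted across all
  unique pairs as one family. A robustness companion redraws 95% of the
  cohort ten times, averages the correlation per pair, and combines the
  ten Pearson p-values with the aggregated Cauchy association test
  (ACAT): $T = \tfrac1k \sum_i \tan\{(0.5 - p_i)\pi\}$,
  $p = 0.5 - \arctan(T)/\pi$, equal weights. ACAT is robust to the strong
  dependence among bootstrap draws, reduces to the identity at $k = 1$,
  and is clamped at exact 0/1 inputs (ε = 1e-15, with a warning). Equal
  weights are used; no weighting scheme is implied by the test's
  definition and none is assumed.
* **Associations.** For each region (or zone) and outcome, OLS of the
  z-scored outcome on the z-scored MPD plus covariates — age, sex, years
  of education for cognitive outcomes; none for age itself — with listwise
  deletion and BH adjustment across regions per outcome. The reported
  correlation R alongside the adjusted slope is the *marginal* Pearson
  correlation, a deliberate and flagged choice; the partial correlation is
  recoverable from the fitted models, which are retained in the returned
  object. Sensitivity analyses additionally adjust for intraparenchymal
  volume (FreeSurfer-convention codes 2, 3, 41, 42) or its fraction of
  intracranial volume. Sex differences use the two-sided Wilcoxon rank-sum
  test, with the exact null when both groups have ≤ 25 untied
  observations and the tie-corrected normal approximation otherwise.
* **MPD–CBF coupling.** Per subject, the Pearson correlation between the
  regional MPD profile and the matched regional CBF profile (at least 3
  complete regions), then an unadjusted association of that per-subject
  correlation with age.

Missing data are handled listwise per analysis and counted; no imputation
is performed.

## The digital phantom

The phantom emulates every input the pipeline consumes: a procedural
ellipsoidal head with a white-matter core, a two-voxel cortical gray
ribbon carrying a toy atlas of four bilateral landmark regions (two sulci,
two cisterns), a subarachnoid shell, long paraventricular lateral
ventricles joined through a narrow midline third-ventricle channel (so the
junction-seed and all eight distance zones are populated), and a small
fourth ventricle — the smallest geometry that exercises every stage,
including the exclusion rule (the fourth ventricle deliberately sits below
the 10-voxel threshold at the default 24 × 24 × 16 grid). Default true
pseudodiffusivities place ventricles and cisterns (2.4–3.0 × 10⁻³ mm²/s)
above sulci (1.2–1.4 × 10⁻³ mm²/s), with tissue decaying at
0.7 × 10⁻³ mm²/s.

Noise is Rician by default — magnitude MRI — with σ expressed as a
fraction of S(0) and defaulting to 2%, a choice made by the package (the
low-b SNR of the reference acquisition is not published); Gaussian and
noiseless modes exist for analytic checks. Noise is applied to the head
voxels; background air is left at zero signal, which no analysis stage
reads. Between-subject biology is a 10% relative SD on each region's D\*;
geometry jitters by ±1 mm per subject. Covariates (age, sex, education,
five continuous cognitive scores) are generated with mild, realistic
age–cognition coupling, and *planted effects* mix a covariate's cohort
z-score into a region's (or ventricular zone's) D\* draw so that the
standardized slope recoverable by the association layer equals the planted
value. A planted MPD–CBF coupling grows with age to exercise the
profile-correlation analysis.

What the phantom does *not* emulate: cortical folding, EPI distortion,
motion, partial-volume mixing beyond linear fractions, or registration
error (all inputs are generated co-registered; a rigid nearest-neighbour
resampling hook is provided for external data). Passing tests on the
phantom therefore validate the computational chain and its conventions,
not robustness to real-world registration and artifact burden.

## Determinism and problem sizes

One master seed fans out to per-stage and per-subject sub-seeds (all kept
within 32-bit integer range); identical configurations yield byte-identical
tabular outputs, which the suite asserts. The test and acceptance runs use
desk-scale sizes chosen as the package's own defaults: 24 × 24 × 16 voxel
phantoms, cohorts of up to 60 subjects, 50 replicate cohorts for the
Monte-Carlo recovery checks, and ≤ 20³ volumes for the brute-force
parcellation oracle.

## Known limitations

* The pseudodiffusivity model is mono-exponential within b ≤ 200; no
  bi-exponential IVIM perfusion fraction is estimated.
* Free-water and corrected-FA maps are inputs; the single-shell free-water
  elimination that produces them is out of scope, as are skull-stripping
  and anatomical segmentation.
* Distances are Euclidean in mm; whether a reference implementation used
  index units is unknowable from the anatomical definitions alone, so the
  unit is configurable via the spacing argument.
* The marginal-vs-partial ambiguity of the reported R is resolved as
  marginal and flagged in the documentation.
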