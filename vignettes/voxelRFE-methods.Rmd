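---
title: "Locating discriminative brain regions with SVM-RFE consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating discriminative brain regions with SVM-RFE consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelRFE)
```

## The problem

Voxel-based morphometry pipelines segment each subject's T1-weighted MRI
into tissue-probability maps: one scalar per voxel per tissue class (gray
matter, white matter) giving the probability that the voxel belongs to
that tissue. In a two-group design — for instance elderly controls versus
Alzheimer's disease patients — the scientific question is *which voxels
carry the group difference*, without committing in advance to an
anatomical atlas or a predefined parcellation.

voxelRFE treats every voxel as one feature of a linear classifier
(voxel-as-feature), ranks features with SVM recursive feature elimination,
and stabilizes the ranking by repeating selection over many overlapping
subject subsets. The regions of interest are the voxels that many subsets
agree on.

## The model

A linear soft-margin SVM separates the two labeled groups with the
maximal-margin hyperplane

$$ g(\mathbf{x}) = \mathbf{w}^{\top}\mathbf{x} + b = 0, $$

where $\mathbf{x}$ is a subject's vector of tissue probabilities over the
$M$ in-mask voxels. The weight vector is recovered from the dual solution
as $\mathbf{w} = \sum_i y_i \lambda_i \mathbf{x}_i$ over the support
vectors, with $0 \le \lambda_i \le C$ and $\sum_i y_i \lambda_i = 0$. The
penalty $C$ trades margin width against training misclassifications.

**SVM-RFE.** If $|w_n| \simeq 0$ the $n$-th voxel contributes nothing to
$g(\mathbf{x})$. Each elimination loop trains the SVM on all samples of
the current feature set, sorts surviving voxels by $|w_n|$, discards the
$\tau$ lowest, and optionally re-scores the surviving set with an
independent cross-validated SVM. Repeating to exhaustion yields a complete
elimination ranking; the "top $p$" selection keeps the
$\lceil p \cdot M \rceil$ voxels eliminated last.

**Consensus.** Subjects of each class are shuffled once, and a sliding
window of `window` subjects per class advances in steps of
`window − overlap`, producing
$\lfloor (N - W)/(W - O) \rfloor + 1$ overlapping subsets (32 subsets for
185 subjects per class with $W=30$, $O=25$). SVM-RFE runs per subset; the
consensus map counts, per voxel, how many subsets placed it in their top
20%. If selection were independent and uniform, counts would follow
$\mathrm{Binomial}(n_{\text{sets}}, p{=}0.2)$; the package reports that
curve as a descriptive reference, and real signal shows up as right-tail
excess. Thresholding the counts (at 44%, 56%, 75% or 100% of the sets)
yields ROI masks of increasing stringency.

**Baseline.** The comparison selector is the voxelwise two-sample
pooled-variance Student's t-test at p = 0.05 without multiple-comparison
correction, evaluated by the same cross-validation.

**Evaluation.** Accuracy uses the leave-10-out scheme: the samples are
shuffled once (seeded), dealt into $S = \lfloor N/10 \rfloor$ disjoint
class-stratified groups of exactly 10, and each group is tested against an
SVM trained on the rest. Note this holds 10 *subjects* out per fold
regardless of $N$ — for $N = 60$ it is 6 folds — which differs from the
conventional tenth-of-the-data "10-fold".

## The phantom generator

Real segmented cohorts require an imaging study; validation here runs on
synthetic cohorts whose ground truth is known.

* **Template.** A deterministic, brain-like base map: a centered
  ellipsoid with a flat high-probability core (0.9 for GM) and a smooth
  cosine falloff to exactly zero at the boundary. The WM template is a
  smaller ellipsoid.
* **Planted effect.** Spheres (`roiSpec`: center and radius in voxels)
  inside which AD-labeled subjects lose `effectSize` of tissue
  probability. The default plants two bilateral spheres of radius ~4.5
  voxels in a 32³ grid, emulating the symmetric medial-temporal atrophy
  pattern; with `effectSize = 0.4` against noise sd 0.1 the planted
  contrast is strong, comparable to the hippocampal GM deficits that
  full-scale studies report as near-saturating differences.
* **Noise.** Per subject, an i.i.d. Gaussian field convolved with a
  Gaussian kernel (FWHM in voxels; 0 = i.i.d.), then divided voxelwise by
  the exact local standard deviation of the convolution so the marginal
  sd equals `noiseSd` everywhere, edges included. Noise is confined to
  the template's tissue support: segmentation emits exact zeros outside
  tissue for every subject, and it is precisely this property that makes
  the voxel-as-feature universe a strict subset of the grid (about 27% of
  the full 121×145×121 grid for gray matter; about 31% of the 32³
  phantom).
* **Clipping.** Values are clipped to [0, 1] after the effect and noise
  are applied, as probabilities require. Clipping biases the realized
  class difference slightly toward zero wherever template ± 3·sd crosses
  the bounds; the planted spheres sit in the 0.9 core where a 0.4–0.5
  deficit never clips, so the noiseless difference image equals
  `effectSize · truthMask` exactly.

What the phantom deliberately does **not** model: anatomy, registration
and normalization error, partial-volume structure, scanner and site
effects, and any calibration of the noise level to a real cohort — the
inter-subject variance of real segment maps is not characterized by the
source material, so `noiseSd` is a free parameter. Passing phantom tests
therefore demonstrates correctness of the algorithmic machinery and
sensible behavior under controlled signal/noise, not clinical performance.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `C` | soft-margin penalty | 1.0 | the method's source never states its value; 1.0 is the standard neutral choice, exposed everywhere |
| `tau` | voxels eliminated per RFE loop | 0.04 (4% of M) | mirrors the full-scale step of 20,000 ≈ 3.5–4% of features |
| `fraction` | top share kept as ROIs | 0.2 | the "top 20% most relevant" operating point |
| `window` / `overlap` | subset size / sharing per class | 15 / 10 (desk) | scales the heavily-overlapping 30/25 design to a 30-per-class cohort, giving 4 subsets |
| consensus thresholds | fraction of sets required | 0.44, 0.56, 0.75, 1.0 | reporting operating points; 0.75 is the "robust ROI" mask |
| `noiseSd`, `smoothFwhm` | noise sd and correlation | 0.1, 3 vox | smooth, moderate inter-subject variation; FWHM = 0 gives i.i.d. noise for calibration studies |

## Numerical choices

* **Solver.** Training delegates to libsvm (via e1071) with tolerance
  1e-6 and no feature scaling (inputs are already probabilities on a
  common scale). Because the dual depends on the data only through the
  Gram matrix $K = XX^{\top}$, wide problems ($M > n$) are factored as
  $K = ZZ^{\top}$ by symmetric eigendecomposition and solved in the
  $n$-dimensional span; duals, objective and threshold are identical, and
  $\mathbf{w}$ is recomputed exactly from the duals. This makes each RFE
  loop on tens of thousands of voxels cost milliseconds rather than
  seconds. Orientation is normalized so positive decisions mean AD (+1).
* **Ties in $|w_n|$** are broken by eliminating the lower voxel linear
  index first; every run is bit-reproducible given the seeds (cohort,
  subject order, folds — no other randomness exists).
* **Rank bookkeeping.** Eliminated chunks are ranked by $|w_n|$ at the
  loop of their elimination; the last survivor takes rank $M$. When fewer
  than $\tau$ features remain, all but one are eliminated so the trace
  reaches a minimal set, and callers choose their cut by rank.
* **Ranking bias, by design.** The ranking SVM is trained on *all*
  samples of each subset (not within CV folds), and the pooled
  consensus-mask accuracies evaluate features selected using the complete
  sample. Both choices reproduce the published scheme; the pooled rows of
  the comparison table carry an explicit "not a strict CV" note rather
  than silently presenting optimistic numbers.
* **Degenerate t-tests.** Zero pooled variance flags the voxel as
  degenerate; a zero mean difference is then non-significant (p = 1),
  a nonzero one is infinite separation (p = 0). This keeps the noiseless
  phantom — where planted voxels separate perfectly with zero variance —
  selectable by the baseline.
* **Stratified folds.** Class members are dealt round-robin into the
  $S$ groups of 10; a training fold that loses a class entirely raises an
  error rather than returning a meaningless accuracy.

## Problem sizes used in the tests

The bundled validation runs at desk scale, chosen so the full suite
re-runs in minutes: 32³ phantoms with 30 subjects per class and ~10,000
in-mask voxels for recovery and calibration studies, 12³–16³ grids for
unit tests, and the full 121×145×121 geometry exercised only where it is
cheap (feature counting, header round-trips). The full-resolution
configuration is available through `phantomParams(dims = c(121L, 145L,
121L), ...)` and the same code paths.

## Known limitations

* The binomial reference curve ignores the dependence induced by
  overlapping subsets; it is a visual null, not a test. Observed counts
  on effect-free phantoms still sit above it in the right tail because
  shared subjects correlate the subsets' selections.
* Leave-10-out accuracy on subsets requires at least 20 subjects; smaller
  windows fall back to an error, not a silent degraded scheme.
* `effectSize` is a mean shift only; the generator does not model
  class-dependent covariance or lesion texture.
* With heavy clipping (template near 0 or 1 and large `noiseSd`), the
  realized noise is sub-Gaussian and the nominal t-test calibration
  degrades at the support edge; calibration tests use configurations
  where clipping is rare.
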