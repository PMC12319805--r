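---
title: "Mapping muscle projectomes in the lumbosacral cord: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping muscle projectomes in the lumbosacral cord: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumbomap)
```

## The problem this package addresses

Lower-limb muscles are innervated by motor neuron pools distributed
segmentally along the lumbosacral spinal cord (levels L1 to S2), with
somatosensory afferents projecting onto those pools. The rostrocaudal
distribution of a muscle's innervation — its *projectome* — varies
substantially between individuals, which matters for targeted
neuromodulation and neurosurgical planning. Task fMRI of the lumbosacral
cord offers a non-invasive window on this organization: block-design tasks
(active movement, passive stretch, tendon vibration of a specific muscle)
evoke BOLD responses whose spatial distribution across hemicords and spinal
levels can be quantified per participant.

`lumbomap` implements that analysis chain as tested, reusable code: run
quality control, a simplified multi-level GLM, spinal-level geometry,
laterality and segmental metrics, and a decision-tree construction of
personalized projectomes. Because no public lumbosacral task-fMRI dataset
accompanies this work, the package also ships a first-class synthetic-data
module that generates cord geometry, paradigms and 4D BOLD runs with known
ground truth, so every downstream stage is validated against planted truth.

## Coordinate conventions and spinal levels

All volumes are handled in RAS+ orientation: x increases to the right, y
anteriorly (ventral), z rostrally. Slice indices are 1-based in R. The
seven lumbosacral levels L1, L2, L3, L4, L5, S1, S2 are ordered rostral to
caudal, so L1 occupies the largest z. Level delimitation from anatomy
follows the root-entry-zone (REZ) midpoint rule: with the nine roots T12
through S3 annotated, the boundary between consecutive levels is the
rostrocaudal midpoint of the flanking REZs, and level `Lk` spans the
half-open interval `(mid(REZ_k, REZ_caudal), mid(REZ_rostral, REZ_k)]`.
Nine roots give exactly seven interior levels; `levels_from_rez()` refuses
incomplete or non-monotone annotations. Annotations may be given in mm or
slice units (with a declared slice thickness); computation is in mm, and
the construction is invariant to uniform translation of all coordinates.

## Quality control

*Framewise displacement.* Realignment in reduced-FOV cord imaging is
two-stage (volume rigid-body, then slice-wise in-plane), so the FD
definition must accommodate per-slice traces. We use the sum of absolute
backward differences of the translations, averaged over slices and then
over time; when 3D rotations are present they are converted to arc length
at a 50 mm radius (a conventional head-size radius, kept configurable and
documented because the trace geometry differs in the cord). Runs are kept
only when mean FD is *strictly* below 0.5 mm — a run at exactly the
threshold is excluded.

*DVARS scrubbing.* DVARS is the RMS of voxelwise intensity differences
between consecutive volumes inside the cord mask, computed on unsmoothed
motion-corrected data. Outlier frames exceed Q3 + 1.5 IQR of the run's
DVARS series, with quartiles by linear interpolation between order
statistics (R's type-7 quantiles); on short series the flag set depends on
the quantile method, which is why it is pinned here. Flagged transitions
map to one-hot nuisance regressors for the later of the two volumes.

*tSNR.* Temporal mean over temporal standard deviation per voxel, with the
sample (n − 1) standard deviation; zero-variance voxels are reported as
`Inf` and excluded from mask averages.

## The general linear model

The task boxcar is convolved with a three-function haemodynamic basis: the
canonical double-gamma response (peak 6 s, undershoot 16 s, ratio 1:6) plus
its temporal and dispersion derivatives, with the second and third columns
orthogonalized against the first so that the canonical coefficient carries
the effect of interest. The canonical column is peak-normalized, which
makes the fitted coefficient read directly in percent-signal-change times
baseline/100 units; the simulator uses the same convolution, so amplitude
recovery is unbiased by construction (HRF-mismatch experiments can vary the
simulated peak delay via `hrf_delay`).

Nuisance regressors comprise polynomial drift (order 2 by default), the
first five principal components of the CSF signal (`acompcor()`, computed
on unsmoothed data; components are variance-ranked, unit-norm,
mean-centered time courses), motion parameters when configured (intended
for the tendon-vibration condition, where the task correlates least with
residual motion), and the outlier one-hots. All columns except the
intercept are mean-centered, and rank deficiency is an error naming the
collinear columns.

Estimation is ordinary least squares per voxel. Prewhitening is
deliberately omitted: the synthetic noise model is white, and an
autocorrelation model fitted to white noise only adds variance. The t
statistic for the canonical contrast converts to a Z score by matched
cumulative probabilities, computed on the log scale in the tails so large
|t| does not saturate.

Fixed-effects combination across runs (second level) and across conditions
(third level) sums effects and their variances: `cope = Σ cope_i`,
`varcope = Σ varcope_i`, `z = cope / √varcope`. This equal-weight
summation convention is appropriate when all runs share one acquisition;
it makes combination associative and gives the exact √k scaling of Z for k
identical runs that the test suite checks.

*Thresholding.* Voxels are active at Z > 2.3 (strict). Cluster-level
correction forms 26-connected clusters at that threshold and compares
their sizes against a max-cluster-size null obtained by sign-flipping the
run-level effect maps — a permutation substitute for random-field cluster
inference, chosen because it is assumption-light and exactly reproducible
under a seed. When the number of runs k satisfies 2^k ≤ `n_perm`, all sign
patterns are enumerated and the p-values are exact. Two caveats are
documented rather than hidden: with few runs the smallest achievable
p-value is 1/2^k (four runs can never reach p < 0.05), and sign-flip nulls
assume mean-zero exchangeability, so they are conservative when each
individual run already carries strong signal. Clusters with p ≥ 0.05 are
removed.

*Smoothing.* The anisotropic 2 × 2 × 6 mm FWHM kernel is applied in
cord-aligned coordinates: separable in-plane smoothing per axial slice,
then a longitudinal pass in which each output voxel averages neighbouring
slices displaced by the integer centerline offset between slices, with
kernel weights renormalized over in-grid samples. For a straight or gently
meandering cord this realizes a kernel oriented along the cord; it is not
a full curved-coordinate resampling, which would require the non-rigid
straightening transforms that are out of scope here.

## Hemicords and laterality

`hemicord_partition()` splits each slice at the centerline: left/right by
the x coordinate, dorsal/ventral by the y coordinate. A voxel exactly on
the dividing line goes to the right and to the ventral hemicord; the tie
rule is arbitrary but fixed so all counts are reproducible. The laterality
indices are

$$LR = \frac{n_{left} - n_{right}}{n_{left} + n_{right}}, \qquad
  DV = \frac{n_{dorsal} - n_{ventral}}{n_{dorsal} + n_{ventral}},$$

so +1 means all active voxels left (respectively dorsal) and −1 all right
(ventral). Empty regions yield missing indices, never zero: a zero is a
statement of balance, not of absence. Reflecting an activation about the
centerline negates the corresponding index exactly when the centerline
lies on a half-integer coordinate (the lattice maps onto itself and the
tie column is empty) — a property the suite tests.

## Segmental distributions

For the rostrocaudal profile, active voxels are counted per level. A level
is labeled *active* when it holds strictly more than 30% of all active
voxels; the fraction is of the significant voxels, not of the level's
volume, and it is evaluated on raw counts *before* size correction —
labelling first, then correcting, then summing, then normalizing. The size
correction divides each level's count by its relative volume (level voxel
count over the mean level volume); the normalizing constant cancels after
the final normalization, which is why an activation covering the whole
cord uniformly yields an exactly flat profile regardless of unequal level
volumes (a testable neutrality property). Group profiles sum the
size-corrected counts of active levels across participants and normalize
to 1. `compare_to_expected()` reports the normalized mass falling inside a
muscle's expected innervation range.

## Probabilistic-to-binary level maps

Across-subject probabilistic level maps (the across-subject frequency of
each label, the estimator the synthetic module also uses) are adapted into
non-overlapping contiguous binary maps: binarize at 0.6, keep the largest
26-connected component, fill holes in 3D, dilate in-plane to the cord's
full cross-section, then resolve the resulting slice sets pairwise between
adjacent levels — z-overlaps are divided equally along z, z-gaps are
filled and divided equally, and an odd slice goes to the more rostral
level (a deterministic tie rule recorded in the output). Non-adjacent
levels overlapping in z violates rostrocaudal order and is an error; a
level entirely below threshold either errors or is dropped with a warning,
per configuration. The output invariants — pairwise disjoint, z-contiguous,
filling the in-plane cord extent, rostrocaudal order preserved — are
validated on every call, and binarization of an already-binary map is the
identity.

## The projectome decision tree

Each muscle contributes a ladder of stat maps: third-level before
second-level, corrected before uncorrected, then stricter voxelwise Z and
stricter cluster-defining p first (stable for ties). Maps are iterated in
that priority order; 26-connected components of the first map containing a
candidate decide the muscle. A component is a candidate when its center of
gravity falls within the muscle's expected innervation range — the
unweighted voxel centroid by default (Z-weighting is available behind a
flag for sensitivity analyses), looked up in the level map at the nearest
voxel. Within a map the largest kept component wins; equal sizes resolve
to the more caudal centroid. The component's DV index classifies it as a
motor pool (DV < −0.2), sensory pool (DV > +0.2) or mixed; the ±0.2 margin
encodes that a nearly balanced component should not be over-interpreted,
and the side follows the LR index with ties to the right. Confidence is
*high* only when the selected map is third-level corrected. A muscle with
no kept candidate anywhere is *not estimable* — a result, not an error.

The default expected ranges (TA L4–S1, Gas L4–S2, Qd L1–L4, Il L1–L4, BF
L5–S2, GMax L5–S2) summarize intraoperative nerve-root stimulation
literature and ship as editable JSON; users with their own reference
tables should substitute them.

## The synthetic-data module

The simulator emulates a reduced-FOV axial acquisition: a 48 × 48 × 32
voxel grid at 1.1 × 1.1 × 3 mm, TR 2.5 s, a roughly cylindrical cord of
4 mm radius with a CSF ring, and an optionally meandering centerline with
bounded curvature. Paradigms follow the two task designs: 12 task blocks
of 15 s alternating with 13 rest periods of 15 s (375 s; the
paradigm-derived volume count is 150 at TR 2.5 s, and a `pad_volumes`
parameter exists for acquisitions that record a few extra trailing
volumes), and 18 alternating agonist/antagonist vibration blocks of 10 s
with rests jittered uniformly on 10–15 s under a seed.

The signal model is deliberately plain: baseline × (1 + amplitude ×
convolved boxcar) at planted voxels, a global polynomial drift, white
Gaussian noise, an optional low-rank CSF time course (to exercise
aCompCor), and a 6-column motion trace with requested spikes. Every
generator is a pure function of its arguments including the seed. The
model omits k-space physics, susceptibility artifacts, and structured
cardiac/respiratory noise; passing tests therefore demonstrate the
correctness of the analysis logic and its statistical calibration under
the stated noise model, not robustness to all physiological artifacts of
real cord data.

## Numerical choices and degenerate inputs

- Connected components: 26-connectivity in 3D, with background
  6-connectivity for hole filling; labels are size-ordered.
- Quantiles: type 7 (linear interpolation) everywhere.
- t → Z: matched cumulative probabilities with log-scale tails.
- Empty activation maps: indices and distributions are missing (`NA`), not
  zero. Empty region masks are errors.
- Ties: partition ties to right/ventral; odd overlap/gap slices to the
  rostral level; equal-size candidate components to the more caudal
  centroid; side ties to the right.
- Zero-variance voxels: `Inf` tSNR sentinel, excluded from means.

## Validation problem sizes

The test suite validates the statistical calibration at sizes chosen to
keep Monte-Carlo error meaningful while the whole suite runs in well under
a minute of compute per criterion: the false-positive rate of the
first-level GLM is checked on 11,520 pure-noise voxels against the normal
tail at Z > 2.3 (±0.003); fixed-effects √k scaling is checked to 1e-10 for
k = 1..5; and the end-to-end recovery study simulates 20 participants ×
6 muscles × 2 runs with planted right-sided clusters at an amplitude
(0.65% signal change at noise SD 1% of baseline) calibrated so the
combined planted-voxel Z averages ≈ 5, requiring ≥ 90% of assignments to
match the planted level and side and 100% rejection of decoy clusters
planted outside each muscle's expected range.

## Known limitations

- Motion correction, coregistration and template normalization are
  upstream of this package: motion parameters, masks and (optionally)
  warps are inputs.
- The three-function basis is a documented simplification of
  optimal-basis-set approaches, and OLS omits autocorrelation modelling;
  equivalence with any specific neuroimaging toolbox's numerics is not
  claimed.
- Sign-flip cluster correction is conservative at high per-run SNR and
  cannot reach p < 0.05 with fewer than five runs.
- The expected-range table is a coarse literature summary; projectome
  conclusions inherit its granularity (one level per muscle boundary).
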