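---
title: "Linking striatal dopamine-transporter availability to motor sequence learning"
author: "datmotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking striatal dopamine-transporter availability to motor sequence learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(datmotor)
```

## The scientific question

Striatal dopamine shapes both the *execution* of movements (bradykinesia and
rigidity in Parkinsonian syndromes follow nigro-striatal degeneration) and,
animal work suggests, the *acquisition* of new motor skills through
plasticity in the sensorimotor striatum. Disentangling the two in humans
requires asking **where** in the striatum dopamine-transporter (DaT)
availability relates to motor-symptom severity, and where it relates to the
ability to improve with practice. `datmotor` implements an analysis chain
for exactly this question:

1. **Behaviour.** A sequential finger-tapping task (template 4-1-3-2-4) is
   scored from raw keystroke logs. Each practice block ends after 60
   presses, so at most 12 correct sequences fit in a block.
2. **Imaging.** MNI-space DaT-SPECT volumes are rescaled to voxelwise
   specific binding ratios ("local SBR") against an occipital reference;
   a striatal volume of interest (*DaTStriatum*) is thresholded from the
   cohort mean.
3. **Inference.** Mass-univariate regression of local SBR on behavioural
   covariates, with cluster-extent family-wise-error control by covariate
   permutation.
4. **Connectivity.** Peaks of significant clusters seed a normative
   resting-state functional-connectivity analysis.

## Behavioural model

Speed is summarised per block as the **correct-sequence duration** (CSD):
the mean time from the first to the last press of each exactly-matched
template occurrence (four inter-press intervals; the gap *preceding* a
sequence is not counted). Accuracy (ACC) is the number of correct sequences
over the block maximum of 12. Both are combined in the performance index

$$\mathrm{PI} = 100\; e^{-\mathrm{CSD}}\; e^{\mathrm{ACC}-1},$$

which is 100 for an instantaneous, error-free block, strictly decreasing in
CSD and strictly increasing in ACC. The source formula for this index is
typographically ambiguous between $e^{\mathrm{ACC}-1}$ and
$e^{\mathrm{ACC}}-1$; the first parse is the package default because it
yields a natural 0-100 scale consistent with reported group means in the
low tens, while the second is available as `compute_pi(..., variant =
"exp_minus_one")`. Neither parse is asserted as ground truth anywhere in
the tests.

Sequence counting is greedy, non-overlapping, left to right; an erroneous
press simply never anchors a match. For the canonical template this is
provably maximal (the template cannot overlap itself), and the test suite
checks the greedy count against an independent dynamic-programming
enumeration on random keystreams.

Learning is summarised by three baselines — BoT (mean PI of training blocks
1-2), EoT (blocks 15-18), BoR (retest blocks 1-2) — and their differences:
**online learning** = EoT − BoT, **offline consolidation** = BoR − EoT. A
block with no correct sequence has *undefined* PI (never zero); undefined
values propagate, with one exception taken from the study protocol: if
exactly one of the two initial retest blocks is undefined, BoR is imputed
from the other block and flagged.

```{r behaviour}
log <- gen_keystroke_log(seed = 42, subject = "demo")
training <- score_session(log, "training")
retest <- score_session(log, "retest")
learning_metrics(training, retest)
```

## Local SBR and the DaTStriatum mask

Each volume is divided by its mean intensity over an occipital
(BA 17/18/19) reference mask, making the occipital mean exactly 1 and
striatal voxels interpretable as voxelwise binding ratios. The operation is
scale-invariant and idempotent. The cohort-mean local-SBR image is
thresholded at 2.0 — values *strictly below* 2.0 are excluded, so the
boundary is inclusive, a convention chosen for determinism — to yield the
DaTStriatum mask. Right-to-left mirroring for left-hand trainers is a pure
voxel-axis flip (no interpolation), legal only on grids symmetric about
x = 0 within half a voxel; group analysis is then restricted to the
task-contralateral left hemisphere. Summary metrics per subject are the
mean and maximum local SBR, the MNI coordinate of the maximum-intensity
voxel (ties broken by the smallest (i,j,k) index — relevant only for
noise-free phantoms) and the intensity-weighted centre of gravity
(non-positive intensities are excluded from the weights).

## Voxelwise inference

Per masked voxel, ordinary least squares on `[intercept, covariate]` gives
a slope and a t statistic with n − 2 degrees of freedom. Tests are
one-sided per contrast, mirroring the sign structure of the hypotheses
(negative for motor-symptom severity, positive for online learning).
Noise-free voxels would have infinite t; they are clamped to a documented
sentinel of ±1e6. Candidate clusters are connected components of
supra-threshold voxels (one-sided p < 0.001) under 18-connectivity (faces +
edges), a common neuroimaging convention the source analysis does not
specify.

Family-wise control is by **permutation of the covariate**: for each of
`n_perm` shuffles the maximum cluster extent is recorded, and an observed
cluster of extent $k$ receives
$p_{\mathrm{FWE}} = (1 + \#\{\text{perm max} \ge k\})/(n_{\mathrm{perm}}+1)$.
This replaces parametric random-field theory deliberately: it is exact at
small n, needs no smoothness estimate, and is fully testable. Seeds are
explicit function arguments, never global state; identical seeds give
bit-identical cluster sets.

Two properties of this procedure matter in practice:

* On *unsmoothed* white noise the max-extent null is nearly degenerate
  (almost all permutation maxima are 0 or 1 voxel), so cluster inference is
  radically conservative there. This is expected — cluster-extent inference
  presupposes spatially smooth statistics.
* On smooth fields matching the effective resolution of reconstructed
  FP-CIT SPECT (FWHM ≈ 12 mm), `simulate_cluster_fwer()` measures a
  family-wise rate of about 0.03-0.06 at nominal 0.05 over 500 null
  cohorts (12 subjects, 12³ grid of 4 mm voxels, 399 permutations). The
  residual conservatism comes from integer ties in the max-extent null and
  cannot be removed without changing the cluster statistic.

## Normative connectivity

Preprocessing per run follows a fixed order: frames with Power-style
framewise displacement above 0.5 mm are censored (FD sums absolute backward
differences of the six motion parameters, rotations converted on a 50 mm
sphere; the formula itself is a package choice since only the threshold is
prescribed); nuisance regression on kept frames removes intercept, six
motion parameters, mean white-matter, CSF and global signal; residuals are
band-pass filtered 0.01-0.08 Hz with a zero-phase 4th-order Butterworth
(applied forward-backward, after demeaning to avoid step transients);
censored series are treated as contiguous — interpolation variants are out
of scope. The seed time series is extracted from *unsmoothed* residuals,
target series are smoothed with a 5 mm-FWHM separable Gaussian
(σ = FWHM/(2√(2 ln 2)) per axis), and the map holds Fisher-transformed
correlations with |r| clamped at 1 − 1e−12. Two runs per subject are
averaged at the z level. Group inference is a one-sample t per voxel with
sign-flipping permutations as the null (valid under the symmetric null),
and the same cluster machinery as the SPECT arm; the binary intersection of
two thresholded networks gives the overlap map.

## Cohort statistics

`mixed_rmanova()` implements the two-factor mixed design (between-subject
group × within-subject block) with Type III sums of squares computed from
orthonormal within-subject contrasts and unweighted group means, which
matches standard commercial implementations under unequal group sizes.
Sphericity is quantified by the Greenhouse-Geisser epsilon from the pooled
within-group covariance; the Huynh-Feldt correction of that estimate
(capped at 1, floored at 1/(J−1)) rescales the degrees of freedom whenever
ε_GG < 1 — "correct only if necessary". Two-level within factors satisfy
sphericity trivially (ε ≡ 1). The test suite cross-checks the full table
against an independent multivariate-model implementation and against
hand-computed textbook sums of squares. The Mann-Whitney U uses midranks
and a tie-corrected normal approximation without continuity correction;
t-tests are pooled-variance by default with Welch as an option.

The packaged 38-participant cohort table drives the reproducible cohort
statistics:

```{r table1}
rt <- reproduce_table1()
rt$r_ues_putamen$r
rt$dichotomization
```

## The synthetic study

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes. All are pure functions of
their seed.

**DaT-SPECT phantom.** A 4 mm MNI-like grid (24×30×20) carries two
striatal ellipsoids and an occipital slab. Striatal intensity is
$1 + (\mathrm{base}-1)(1-\mathrm{loss})$ with base SBR 3.5 (a healthy
striatal-to-occipital FP-CIT ratio) and a loss combining (a) a global
deficit graded toward the posterior lateral putamen (so the surviving
maximum-intensity voxel migrates medially/anteriorly as depletion rises,
the canonical depletion pattern) and (b) an independent posterior-specific
component confined to the posterior putamen. Voxel noise is Gaussian
(SD 0.1).

**Cohort coupling.** The cohort mimics a DaT-SPECT referral population:
every subject draws a global deficit uniform on [0,1]; about half are
parkinsonian-type with a posterior-specific deficit uniform on [0.4, 1],
the tremor-type rest have none. UES (0-16) derives from a 0.7/0.3 mixture
of global and posterior deficit (bradykinesia-rigidity tracks posterior
putaminal depletion) with unit Gaussian noise, rounded and clipped. The
online-learning target is linear in the noise-free posterior-putaminal
local SBR (4 PI units per SBR unit, SD-1.5 noise) and is *realised* through
the keystroke simulator: per-block CSD follows an exponential approach to
an asymptote chosen to hit the target PI, with Gamma-jittered inter-press
intervals and random wrong keys at ~4%. This mixture design is what makes
the two behavioural domains spatially dissociable — the global component
loads on the whole striatum, the posterior component only posteriorly — and
it is the regime in which the default cohort (n = 40) recovers the planted
posterior learning cluster (Dice against the planted support typically
≥ 0.55 across seeds) inside a broader motor-symptom cluster, while keeping
r(UES, putamen SBR) near −0.8.

**Resting state.** A small centred grid holds a seed blob (6 mm) and a
network-scale target blob (10 mm) sharing a band-limited latent signal at
run-level amplitude 0.6 (log-normally jittered across runs, emulating
inter-individual connectivity differences), white-matter/CSF slabs for
nuisance extraction, drifting motion parameters and optional planted
FD spikes.

What the phantoms deliberately do **not** emulate: SPECT point-spread and
reconstruction artefacts, partial-volume effects, BOLD haemodynamics and
physiological noise spectra, anatomical variability, or registration
error (volumes are consumed already in MNI space, as in the delegated
upstream pipeline). Passing recovery tests therefore demonstrates the
correctness and calibration of the *analysis*, not robustness to every
property of real data.

## Problem sizes and numerical choices

Simulation sizes are chosen for desk-scale reproducibility: 500 null
cohorts of 12 subjects for the FWE calibration, one 40-subject cohort for
recovery, 20 resting-state runs of 400 frames (TR 0.72 s) for network
recovery. Degenerate inputs are handled explicitly: empty masks,
zero-variance seeds and covariates, rank-deficient confound matrices and
non-mirror-symmetric grids are rejected with diagnostics; zero-correct
blocks propagate as missing; argmax ties break lexicographically. Voxel
indices are 0-based internally and all reported coordinates are MNI mm.

## Limitations

The permutation FWE is mildly conservative on discrete extents (above).
The pipeline consumes spatially normalised volumes and performs no
registration or anatomical segmentation of caudate vs putamen; striatal
sub-region claims rest on the voxelwise maps, not on region labels. The
rmANOVA requires complete within-subject data (no missing cells). The
connectivity stage models neither run concatenation nor scrubbing-aware
filtering; censored series are filtered as contiguous.
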