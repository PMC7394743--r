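---
title: "Methods: MST functional-connectivity analysis of delirium risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MST functional-connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstfc)
```

# Scope and model

`mstfc` analyses resting-state functional brain networks in relation to
predisposing delirium risk factors. The unit of analysis is a subject's
region-of-interest BOLD matrix (Power 264-region parcellation, one mean time
series per region) together with six rigid-body realignment parameters per
volume. The pipeline produces five per-subject outcomes — global MST
strength, MST diameter, MST leaf fraction, and PCC–DLPFC left/right
connectivity — and regresses them on risk-factor covariates at the group
level.

The statistical model is deliberately simple: ordinary least squares per
outcome and determinant with a fixed adjustment set (center, age when it is
not the determinant, gender, IQ), standardized coefficients
β = b·SD(x)/SD(y) (binary predictors on the same convention, matching the
convention of classical statistics packages), and Benjamini–Hochberg FDR
within each determinant's family of five outcomes. The family choice matters:
with a single family of five, a raw p of 0.007 survives at the 0.05 level
(0.007 ≤ 0.05/5 for the smallest p), whereas pooling all determinants into
one family would not preserve that; the family is configurable in
`riskFactorModels()`.

# Denoising chain and its fixed order

`denoiseSubject()` applies, in a fixed and logged order:

1. deletion of the first 15 volumes (magnetization equilibration);
2. framewise displacement, FD(t) = Σ|Δtranslations| + 50 mm·Σ|Δrotations|
   with FD(1) = 0 — the sum-of-absolute-backward-differences convention of
   the motion-scrubbing literature, since small-angle rotations sweep an arc
   of radius ≈ 50 mm on the cortical surface;
3. subject-level motion gate: excluded when mean relative displacement
   exceeds 0.2 mm, strictly. The realignment tool's "mean relative
   displacement" cannot be recomputed from parameter tables alone, so when
   absent the mean FD serves as a proxy and the QC record says so;
4. 36-parameter nuisance regression on the full series. The design is the
   standard 36-component model: 9 base signals (6 motion, WM, CSF, global),
   their backward-difference derivatives (first element 0, keeping the design
   the same length as the data), and the squares of all 18. This is the only
   reading of "quadrates, temporal derivatives and quadrates of the
   derivatives" that yields 36 columns;
5. zero-phase band-pass 0.01–0.08 Hz on the full series;
6. censoring of volumes with FD > 0.2 mm (strictly greater — a volume at
   exactly the threshold is retained, following the wording "exceeded");
7. duration gate: excluded when retained volumes × TR fall below 240 s
   (strictly below; exactly 240 s passes).

Regression and filtering run on the *full* series and censoring afterwards,
because band-pass filtering an irregularly sampled (censored) series is
ill-defined. Whether the original analyses censored before or after
filtering is not decidable from the description; `censorFirst = TRUE`
provides the other order for sensitivity analyses (it regresses and filters
the retained subsequence, which treats the censored gaps as contiguous).
Censoring never alters retained values — only the retention mask — so the
two orders share all other code paths.

The band-pass is a Butterworth filter of order 2 applied forward and
backward (`signal::filtfilt`), i.e. an effective fourth-order zero-phase
response. At TR = 2 s this retains ≥ 90 % of a 0.04 Hz sinusoid's amplitude
and attenuates a 0.2 Hz sinusoid by ≥ 90 % (verified against sinusoidal
probes in the tests). Rank-deficient nuisance designs (e.g. all-zero tissue
signals) are projected through the pivoted QR with a warning, which is
equivalent to the pseudoinverse solution for the residuals.

# Connectivity and the spanning-tree backbone

Connectivity is the Pearson correlation over retained volumes (censored
volumes are dropped and the remainder concatenated; regions with zero
variance over retained volumes are an error rather than silently NA).
Regional PCC–DLPFC connectivity averages member time series within each node
set first and then correlates the two averages; the mean-of-pairwise
correlations variant exists behind a flag for sensitivity analysis only.

The backbone is a *maximum*-weight spanning tree over the strictly positive
correlations, constructed by Kruskal's algorithm with union–find: edges
ranked by descending weight, each added unless it closes a loop, until n−1
edges connect all regions. Implementation choices:

- **Ties** between equal weights break deterministically by lexicographic
  (i, j) order. For continuous data ties have probability zero; the rule
  exists purely for reproducibility.
- **Zero correlations count as absent edges** (only strictly positive edges
  are candidates). If the positive graph is disconnected the subject is not
  analyzable under this rule, and the error lists the components rather than
  silently returning a forest.
- Metrics are reported unnormalized: strength is the mean edge weight,
  diameter the edge count of the longest shortest path (double
  breadth-first traversal), leaf fraction the share of degree-1 nodes.
  Normalized variants can be derived trivially by the caller; they are not
  defaults.

The construction is validated against exhaustive enumeration of all labeled
spanning trees (via Prüfer sequences) on small graphs, against an
independent Prim-style implementation, and against `igraph::mst`; path and
star topologies pin the closed-form extremes (diameter, leaf fraction) =
(n−1, 2/n) and (2, (n−1)/n).

# The synthetic cohort

`simulationConfig()` defaults encode the study conditions the package is
designed around: 264 regions, 238 volumes at TR = 2 s, and covariate
marginals matching the included sample's demographics (age 71.2 ± 4.9 years
truncated at the 65-year inclusion minimum, IQ 105 ± 12.2, MMSE 28.7 ± 1.4
with the ≥ 24 cognitive screen, Barthel 98.4 ± 4.8 clamped to [0, 100], 63 %
male, 30 % Berlin, 5 % alcohol misuse, 5 % depression, 24 % TIA/stroke,
86 % ASA-unhealthy). Continuous scores use truncated-normal rejection
sampling; a zero SD collapses to the mean provided it respects the bounds.

The base correlation is block-structured: 12 modules (roughly the number of
canonical resting-state networks) with within-block r = 0.5 and
between-block r = 0.1 — mid-range values for network-averaged resting-state
correlations. The matrix is checked for positive semidefiniteness and, if
numerically indefinite, repaired by eigenvalue clipping at zero followed by
rescaling to unit diagonal; the repair is deterministic and refuses matrices
whose smallest eigenvalue is materially negative.

**Planted effect.** The generator must satisfy two constraints at once: the
effect acts multiplicatively on off-diagonal connectivity (so it directly
moves the measured outcome, mean MST edge weight), and the downstream
standardized β̂ should recover the configured γ. A pure (1 + γz) scaling
fails the second constraint — with no other between-subject connectivity
variability, z would explain nearly all of the outcome variance and β̂
would approach 1 regardless of γ. Each subject's off-diagonals are therefore
scaled by 1 + c·x with a *unit-variance* modulator

x = γ·z + √(1 − γ²)·η,  η ~ N(0, 1),

where z is the subject's standardized planted covariate and c (default 0.1)
is the amplitude of inter-individual connectivity variability (~10 %
coupling differences between subjects, a realistic scale). The standardized
slope of the connectivity scaling on z is then exactly γ, between-subject
variance is realistic, and β̂ recovers γ up to the small attenuation from
sampling noise in the empirical correlations. Scalings that would push any
|r| ≥ 1 are an error. Subject matrices are sampled as multivariate normal
draws through the Cholesky factor (with the same clipping repair as a
fallback for semidefinite targets).

Motion traces are a bounded random-walk drift (per-volume FD ≤ 0.105 mm by
construction) plus persistent 0.4–0.8 mm translation jumps at spike volumes,
so spike volumes have FD > 0.2 mm and non-spike volumes FD ≤ 0.2 mm exactly
— scrubbing can be verified volume-for-volume. Tissue confounds are shared
low-frequency sinusoids (0.01–0.05 Hz) added to every region with a
per-subject gain, giving the 36-parameter regression genuine shared variance
to remove.

What the generator does *not* emulate: hemodynamic response convolution,
scanner drift and spike physics, spatial structure within regions,
non-Gaussian BOLD marginals, and any coupling between motion and signal
(spikes corrupt the motion record, not the BOLD draw). Passing tests
therefore demonstrate the correctness and calibration of the analysis chain,
not robustness to every artefact of real acquisitions.

# Calibration studies

`plantedEffectStudy()` and `recoveryStudy()` run replicate studies of the
full inferential chain — covariate generation, per-subject connectivity
targets, multivariate-normal sampling, Pearson matrix, Kruskal MST, global
strength, adjusted regression — at n = 222 subjects and 60 regions (12
modules of 5). The reduced region count keeps a 1000-replicate null
calibration to minutes while leaving the tree statistics' behaviour intact;
238 volumes per subject match the acquisition. These replicates skip the
temporal-denoising stage: the clean generation path used for calibration
contains no motion spikes or tissue confounds for it to remove (those code
paths are validated separately, down to exact spike recovery), and including
it would only add the cost of filtering ~13 million samples per calibration
without changing what is being estimated.

The acceptance suite asserts, at the study's conditions: mean β̂ within
±0.08 of the planted γ = 0.18 with a ≥ 95 % positive-sign rate over 100
replicates, and a null (γ = 0) rejection rate at α = 0.05 inside the
binomial 95 % band around 5 % over 1000 replicates. The γ default of 0.18 is
an anchor of convenience — the only published effect-size anchor among the
risk factors is a standardized β of 0.178 for age — not a claim about any
other determinant.

# Numerical and procedural conventions

- Thresholds are strict exactly where the source wording is strict:
  FD censoring ("exceeded" 0.2 mm), motion gate ("larger than" 0.2 mm),
  duration gate ("less than" 240 s), FDR significance (corrected p "below"
  0.05).
- Quintile cuts use R's default linear-interpolation percentile (type 7) at
  the 20th/80th percentiles, with boundary values assigned inclusively to
  the extreme groups; with n ≥ 10 both extreme groups are guaranteed at
  least two members.
- Summary-statistic t-tests default to Welch's unequal-variance form, which
  reproduces the published age contrast (t = 2.30) where the pooled form
  gives 2.28; the pooled flag exists because the published Barthel contrast
  (−0.51) is reproduced only under pooled variance — a documented
  sensitivity, not a default.
- Log transformation of non-normal variables is configuration-driven with an
  empty default; `normalityScreen()` (Shapiro–Wilk at α = 0.05) only
  recommends, never transforms.
- Seeds: every stochastic function takes or derives an explicit seed;
  per-subject and per-replicate seeds derive from the master seed through a
  fixed 32-bit Lehmer step, so whole-cohort runs are bit-reproducible and
  byte-identical on disk.

# Known limitations

- Inputs are region-level series; voxel-level spatial preprocessing
  (realignment, segmentation, registration, smoothing) is out of scope, as
  is NIfTI-native end-to-end processing.
- The positive-graph disconnection rule treats such subjects as errors;
  alternative conventions (largest component, absolute weights) are not
  offered because they change the estimand.
- Complete-case analysis only; no imputation, interaction, or mediation
  modelling.
- The Fisher-z convergence guarantees for generated series are elementwise
  sampling statements; at 264 regions the ~35k simultaneous elements make
  occasional 3-SE exceedances expected, which is why the tests use a
  simultaneous (Bonferroni-matched) band.
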