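---
title: "Models and methods: age-dependent seed-network resting-state connectivity"
author: "agefc maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: age-dependent seed-network resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agefc)
```

# Scope and model

`agefc` implements a two-stage analysis of age-dependent resting-state
functional connectivity (RS-FC) in a nine-node network spanning the
visual-attention system (bilateral superior parietal area 7A, bilateral
dorsal premotor cortex), the sensorimotor system (bilateral parietal
opercular area OP4), and three task-general nodes (rostral SMA and
bilateral anterior insula). The six system-specific peaks and the
task-general peaks are packaged in `defaultSeeds()`.

**Stage one — task-general seed definition by co-activation
meta-analysis.** For a given seed peak, the experiments in a coordinate
database that report activation closest to the seed are selected
(`selectNearestExperiments()`; an experiment's distance is the minimum
Euclidean distance over its reported foci, and the distance of the k-th
selected experiment reproduces the seed table's "maximum distance"
semantics on any database). Convergence over the selected experiments'
foci is quantified with activation likelihood estimation: each experiment
contributes a modeled-activation (MA) volume — the voxelwise *maximum*
over its foci of an isotropic Gaussian, the non-additive rule under which
repeated foci within one experiment are no extra evidence — and the ALE
statistic is the probabilistic union `1 - prod(1 - MA_e)`. Voxelwise
significance is assessed against the random-spatial-association null (the
ALE value obtained when each experiment contributes the MA value of one
uniformly random in-mask voxel), clusters formed at voxel p < 0.001 are
tested for family-wise error by a foci-relocation permutation null of the
maximum cluster size, and the per-seed co-activation maps are intersected
with the conservative minimum-statistic conjunction (voxelwise
intersection of the FWE-surviving masks).

**Stage two — RS-FC and age effects.** Each subject's BOLD volume is
cleaned with a 31-column nuisance design: six motion parameters, their
backward-difference temporal derivatives (first frame 0), and the mean
GM/WM/CSF signals, each mean-centred, plus the squares of the centred
terms (re-centred), plus an intercept. Confound regression precedes an
ideal (boxcar) band-pass to 0.01–0.08 Hz realized in the discrete Fourier
domain: inclusive band edges, DC always removed. Each 5-mm seed sphere
(gray-matter voxels whose centre lies within the radius, inclusive) is
summarised by its first eigenvariate — the first right singular vector of
the centred voxel-by-time matrix, scaled by its singular value over the
square root of the voxel count, sign-fixed so the mean spatial loading is
non-negative. Seed time courses are correlated pairwise (Pearson), Fisher-Z
transformed, and analysed at the group level: one-sample t-tests for the
existence of FC, Spearman rank correlation with age for age effects (p by
the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`), each family of 36
tests corrected separately by Benjamini–Hochberg FDR at q = 0.05 (the two
analyses are distinct hypotheses families; correcting their union would
mix them), a contrast of the 100 youngest versus 100 oldest subjects
(Welch's unequal-variance t on Fisher-Z; group means reported as the
inverse Fisher transform of the group-mean Z; age ties broken by subject
id so membership is deterministic), and a deterministic change-pattern
classification (inversion, loss of anti-correlation, loss of positive FC,
gain) in which "absent FC" means the group's one-sample test does not
reject at 0.05 uncorrected — the criterion is otherwise unspecified in
the source analysis and had to be fixed somewhere.

# The synthetic cohort generator

Real multi-site scans are not redistributable, so validation rests on a
generator whose ground truth is known exactly.

**Age–coupling law.** Population coupling is linear in Fisher-Z:
`z_ij(age) = base_ij + slope_ij (age - referenceAge)`, with the
correlation matrix at any age the inverse Fisher transform, repaired to
the nearest positive-semidefinite correlation matrix by eigenvalue
clipping at a small floor followed by rescaling to unit diagonal (the
simplest projection preserving symmetry and the unit diagonal; iterated
until the minimum eigenvalue clears -1e-10). Linearity is a modelling
choice — the reference analysis only reports monotone rank correlations —
but it makes endpoint calibration exact: `calibrateTruth()` places the
line through `atanh(mean_r_young)` and `atanh(mean_r_old)` at the
expected mean ages of the 100 youngest and oldest of 399 uniform ages
(26.4 y and 76.6 y for ages uniform on 18–85), so the generative group
means equal the reference values by construction.

**Between-subject variability.** Each subject receives a Fisher-Z offset
with per-connection standard deviation chosen so the population
correlation between subject Z and age matches the reference `rho_s`
exactly: `sigma_total = |slope| sd(age) sqrt(1/rho^2 - 1)`, from which
the estimation noise implied by the scan length (below) is subtracted in
quadrature. With the packaged reference table this places the planted
`|rho_s|` at 0.14–0.24.

**Signals.** Latent region signals are white multivariate normal draws
band-limited to 0.01–0.08 Hz with the package's own boxcar filter:
resting-state fluctuations of interest are slow, and generating the
signal inside the pass band means the pipeline's own filter is exactly
transparent to it, making the noiseless round trip exact rather than
limited by out-of-band sampling noise. The per-subject "realized
coupling" returned by `simulateSubject()` is the empirical correlation of
these latent series. A band-limited correlation estimate has roughly `2B`
effective degrees of freedom, where B is the number of retained
positive-frequency bins; the package uses `sd(z) = 1/sqrt(2B - 3)`
(verified by simulation to within 1%) when sizing calibration noise.

**Confounds.** Every brain voxel carries a slow drift sinusoid (default
0.005 Hz, below the pass band) and a cardiac/respiratory-like sinusoid
(default 0.15 Hz, above the band but below every site's Nyquist); seed
voxels add independent noise and a scaled leak of a motion regressor
built from six random-walk motion parameters (default step 0.02
mm/degree per frame, a realistic slow drift that the nuisance model must
remove). Tissue labels come from a concentric phantom (WM core, GM
shell sized to contain every seed sphere, thin CSF rind) with seed
spheres stamped GM.

**Geometry.** The default grid is 32x32x32 voxels at 3 mm, RAS+, centred
on the origin. MNI seed coordinates reach |x| = 50 and z = 60 mm and fall
outside this desk-scale box, so seed peaks are compressed by a documented
uniform scale (`compressSeeds()`, default 0.5; the demonstration pipeline
uses 0.35 on a 24-voxel grid). Radii stay in true mm. Meta-analysis runs
on a separate 16-voxel grid at 4 mm.

**Foci databases.** `generateFociDatabase()` assigns every experiment a
home seed (round-robin) and plants one Gaussian-scattered focus at the
home seed and at each planted convergence zone, plus Poisson background
foci uniform over the mask — so the planted zones are shared convergence
zones with known locations, the synthetic analogue of task-general
co-activation. `nullFociDatabase()` places all foci at uniformly random
in-mask voxel centres: the no-convergence condition for familywise-error
calibration.

What the generator does **not** emulate: scanner physics (no T1
equilibration, susceptibility, or spatial autocorrelation beyond the ROI
structure), site-specific noise spectra (the sources do not characterise
them; defaults are stated, not fitted), realistic age distributions
(uniform ages maximise slope-recovery power; the site profiles carry the
TR and duration heterogeneity), and nonlinear or non-monotone age
trajectories. Passing tests therefore demonstrate the pipeline's
statistical and numerical correctness under a faithful generative law,
not robustness to artefacts the generator does not contain.

# Numerical choices

- **Filter.** A DFT boxcar rather than an IIR design: bit-reproducible,
  exactly idempotent, trivially testable. Off-bin spectral leakage of
  non-commensurate sinusoids is accepted and visible in tests only
  through on-bin probes.
- **Eigenvariate scaling and sign.** Scaling (singular value over sqrt of
  voxel count) is correlation-invariant downstream and purely
  conventional; the sign is not, so it is fixed by the mean spatial
  loading (ties: first nonzero loading).
- **Rank-deficient designs.** Constant nuisance columns are flagged, not
  dropped; residuals are computed by pivoted QR, for which the projection
  is unique even when coefficients are not.
- **Degenerate correlations.** Off-diagonal |r| numerically at 1 is
  rejected, not clipped: in this pipeline it indicates a simulation or
  extraction fault.
- **ALE kernels.** `sigma = fwhm / (2 sqrt(2 log 2))`, peak value equal
  to the Gaussian probability mass of one voxel at the focus (capped at
  1). Kernels are truncated where the Gaussian falls below 1e-4 of its
  peak; the same truncation is used for observed maps, the null
  histogram, and the permutation loop, so voxel-p calibration is
  internally consistent. The default width model
  `fwhm(n) = sqrt(74 + 260/n)` mm is an approximation (about 10 mm at
  n = 10, 8.9 mm at n = 50, the magnitudes empirical models in the field
  report); analyses that need exactness pin `fwhm_mm` per experiment.
- **ALE null.** The analytic method discretises MA values into 1e-5-wide
  bins (round-to-nearest) and convolves complement products exactly,
  pruning bins below 1e-16 mass; the Monte-Carlo method shares the same
  bin lattice so both estimate the same discretised tail probability and
  agree to < 0.005 everywhere on toy databases. Permutation maps reuse
  the observed maps' forming threshold (the standard practice; relocated
  foci sit on voxel centres, so their kernels come from a precomputed
  offset cube).
- **Clusters.** 26-connectivity; cluster peaks are located by ALE value
  (z saturates at the null's resolution inside strong clusters, ALE does
  not); conjunction component peaks use the minimum ALE statistic for
  the same reason. Cluster FWE p is the plain fraction of permutations
  whose maximum cluster size reaches the observed size.
- **Sub-seeds.** Pipeline stages derive their RNG seeds from the master
  seed by a fixed counter offset, so stages are independently
  reproducible and no stage's draw count affects another.

# Design decisions on open points

- "Second-order terms" of the nuisance variables are read as elementwise
  squares of the centred first-order regressors (the standard nuisance
  expansion), not lagged terms.
- Tissue means are extracted from the raw scan, before any regression:
  they are listed jointly with the motion terms among the nuisance
  variables.
- Welch's unequal-variance t for the extreme-group contrast: no test is
  named in the source analysis and Welch is the safe default.
- FDR is applied within each 36-test family separately.
- The subject-level correlation is Pearson; rank correlation enters only
  for the age analysis.
- The conjunction intersects FWE-thresholded maps (the conservative
  reading of the minimum-statistic approach).

# Known limitations

**Gray-matter-mean regression is a projection, and it moves
correlations.** Regressing the GM-mean signal removes, from every voxel,
whatever component it shares with the GM average; with a single regressor
carrying weights `a_i = cor(x_i, g)`, the post-regression correlation is
`(r_ij - a_i a_j) / sqrt((1 - a_i^2)(1 - a_j^2))`. In real data `g` is
dominated by global physiological fluctuations; in a noiseless phantom it
degenerates to pure seed-signal leakage and the projection can shift
seed-pair correlations by several tenths — the well-known route by which
global-signal regression can induce anti-correlations.
`preprocessBold(includeTissue = FALSE)` exposes the motion-only design
for sensitivity analyses; the test suite verifies closure (exact recovery
of realized coupling) on fully noiseless data and verifies that the full
31-column design matches an independent per-voxel `lm()` oracle, so the
deviation is the mathematics of the design, not an implementation
artefact. Relatedly, regressing ~19–31 stochastic nuisance columns from
band-limited series consumes a share of the band's roughly `2B` effective
degrees of freedom, perturbing per-subject correlation estimates by an
amount that shrinks with scan length.

**Statistical power at the reference effect sizes is bounded.** With 399
subjects, two-sided Spearman tests and BH at q = 0.05 over 36
connections, the critical |rho| is about 0.12 and the sampling s.d. about
0.05: planted effects at |rho| = 0.14–0.16 are detected in roughly
60–80% of replicates, and only effects of |rho| ≳ 0.17 clear 80%
per-connection power. This ceiling is a property of the design's sample
size and thresholds, not of the implementation; the calibration study in
the test suite reports the measured per-connection power alongside the
recovered group means (within 0.03) and the planted signs (recovered in
well over 95% of replicates).

**Desk-scale problem sizes.** The packaged studies use sizes chosen for
reproducible desk-scale runs: null-calibration cohorts of n = 100 at 128
volumes (500 cohorts), the calibration cohort at the full n = 399 with
site-profile scan lengths (100 replicates), meta-analysis on a 16-voxel
4-mm grid with 100 experiments and 500 permutations, and a
demonstration pipeline of 60 subjects on a 24-voxel 3-mm grid. All are
parameters, not constants; the same code runs larger grids and cohorts
unchanged.

# Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state; identical seeds give bit-identical cohorts, volumes,
foci databases, and pipeline outputs (the workflow writes an md5 manifest
of every artifact it produces and validates its configuration — including
Nyquist feasibility of the band for every site's TR — before any
compute).
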