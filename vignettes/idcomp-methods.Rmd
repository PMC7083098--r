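---
title: "Estimating and comparing among-individual behavioural covariance matrices"
author: "idcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing among-individual behavioural covariance matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Open field trials (OFT) yield four observed behaviours per trial:
tracklength (TL), activity (Act), area covered (AC) and time in the middle
zone (TIM). After preprocessing (below), the package models the 4-vector of
traits for individual $i$ on trial $j$ as

$$ y_{ij} = X_{ij}\beta + u_i + e_{ij}, \qquad
   u_i \sim \mathrm{N}(0, \mathbf{ID}), \qquad
   e_{ij} \sim \mathrm{N}(0, \mathbf{R}), $$

a multi-response Gaussian random-intercept model. $\mathbf{ID}$ is the
among-individual covariance matrix — the quantity of scientific interest,
capturing consistent individual differences and their correlations across
behaviours — and $\mathbf{R}$ is the within-trial residual covariance.
Fixed effects per trait are a factor of cumulative trial number ("repeat",
absorbing habituation across trials) and a linear effect of within-group
testing order (absorbing handling-stress or water-borne-cue trends within a
housing group). Assumptions worth keeping in mind: Gaussian deviations on
the transformed scale, a single random intercept per individual (no
individual-by-trial-number interaction, i.e. no plasticity variance), and
homogeneous $\mathbf{R}$ across repeat levels.

Univariate versions of the same model give per-trait repeatability
$V_I/(V_I+V_R)$; its significance uses a likelihood ratio test against the
model without the random effect, with the boundary-corrected reference
distribution (50:50 mixture of a point mass at zero and $\chi^2_1$), so the
p-value at statistic 0 is 0.5.

## Preprocessing

The transformation pipeline has a fixed order:

1. TL (cm) is divided by the *species mean* standard length (mm; the factor
   10 converts units) to give distance in body lengths. The species mean,
   not each fish's own length, is used so that size-dependent
   among-individual variation is retained rather than absorbed.
2. TIM is square-root transformed (residual normality for a time duration
   bounded below at 0).
3. All four traits are mean-centred and scaled to standard deviation units
   using the *global* mean and sample SD across all observations of all
   species. Global (not per-species) scaling keeps species mean differences
   in the data while putting traits on one scale.

Two conventions had to be fixed where none is canonical: the SD is the
sample SD ($n-1$), and the standardization statistics are computed on
trial-level observations rather than individual means (the natural reading
of "across all observations"). The `ScalingRecord` returned by
`global_standardize()` makes the transform exactly invertible.

## Estimation

Both covariance matrices are parameterized by Cholesky factors with
log-diagonals, so estimates are symmetric and positive (semi-)definite by
construction — never by post-hoc clipping. Boundary solutions ($V_I \to 0$)
are admitted as a log-diagonal runs to its floor (−8 on the log-SD scale for
$\mathbf{ID}$, −7 for $\mathbf{R}$, which must stay positive definite). The
restricted likelihood is profiled over $\beta$ and maximized with L-BFGS-B
using an analytic gradient (derived via the matrix calculus of
$\partial \log L / \partial \mathbf{ID}$ and $\partial \log L / \partial
\mathbf{R}$, then chained through the Cholesky parameters). Individuals
sharing a design (same trial count, same covariate rows) are collapsed into
design classes, so one likelihood evaluation factorizes a single
$4n_i \times 4n_i$ marginal covariance per class; this is what makes the
bootstrap and the calibration simulations cheap. The C++ kernel lives in
`src/reml.cpp`.

Convergence is declared when L-BFGS-B reports success or when the projected
gradient max-norm falls below $10^{-6}$ (the optimizer occasionally aborts
its line search at a point whose gradient is already at machine precision;
such points are restarted and, if stationary, accepted). Genuine
non-convergence is reported with a warning and a `converged = FALSE` flag —
never silently.

Moment estimators (between-individual covariance of individual means minus
a within correction, and the pooled within-individual covariance) provide
starting values; bootstrap refits warm-start at the point estimates.

Three likelihood-ratio tests mirror the analysis design:

- covariance structure in $\mathbf{ID}$: unstructured vs. diagonal
  $\mathbf{ID}$, 6 df for four traits. The reduced model zeroes only the
  $\mathbf{ID}$ covariances; $\mathbf{R}$ stays unstructured in both (the
  natural choice where only among-individual covariance is under test);
- equality of two species' matrices: the blocked eight-trait pair model
  (cross-species covariances structurally zero, so the restricted
  likelihood separates) vs. a fit sharing one $\mathbf{ID}$ across the two
  blocks while each species keeps its own $\mathbf{R}$ — 10 df;
- the univariate boundary-mixture test above.

P-values across the 21 species pairs are nominal; no multiplicity
correction is applied because the pair comparisons are non-independent by
design.

## Comparison statistics

- **Trace / Δ.** Total among-individual variance is tr(**ID**); pairs are
  compared by $\Delta = |\mathrm{tr}(\mathbf{ID}_1) -
  \mathrm{tr}(\mathbf{ID}_2)|$. The bootstrap CI is on the *signed*
  difference (2.5/97.5 percentiles over paired draws), so significance is
  read as the CI excluding zero.
- **θ.** The angle between leading eigenvectors uses the absolute dot
  product, folding into [0°, 90°], because eigenvector sign is arbitrary.
- **Krzanowski K.** For orthonormal bases **A**, **B** of the leading-$x$
  subspaces ($x \le n/2$, here $x = 2$), $K = \sum \mathrm{eig}
  (\mathbf{A}^\top\mathbf{B}\mathbf{B}^\top\mathbf{A}) = \sum \cos^2$
  principal angles; $x - K$ is reported as the dissimilarity. Published
  loading vectors are renormalized (and the second vector re-orthogonalized
  against the first) before use, since printed values carry rounding.

Numerical corner cases: eigenvectors whose eigenvalues are tied within
$10^{-8}$ are flagged as directionally unstable (their individual
directions are arbitrary although subspace statistics remain valid), and in
bootstrap draws eigenvectors are matched by eigenvalue *rank*, not by
continuity — when $\lambda_1 \approx \lambda_2$ the "leading" vector can
swap identity between draws, which widens θ intervals rather than hiding
the instability.

## Bootstrap and phylogenetic signal

Uncertainty in each species' $\mathbf{ID}$ uses a parametric bootstrap in
the strict sense: simulate a full dataset from the fitted model on the
original design, refit, store the refitted matrix. Draws whose refit fails
are excluded and counted. Ensembles are independent across species, so CI
computation pairs draw $i$ of one ensemble with draw $i$ of the other.

Phylogenetic signal in ID dissimilarity is the Kendall tau-b rank
correlation (tie-corrected denominator) between the 21 unordered-pair
entries of a dissimilarity table and of a patristic distance matrix. Both
matrices are vectorized in a canonical alphabetical species order; any
shared order gives the same tau. K being a similarity, $2-K$ is used so
that all three statistics predict positive correlation under signal. The
nested bootstrap draws, per replicate, one tree from the tree set and one
matrix per species from its ensemble, recomputes the table, and takes
tau-b; the CI is the 2.5/97.5 percentile over replicates. The *point* tau
uses a designated point tree with the point estimates — the bootstrap only
quantifies uncertainty. No Mantel permutation p-value is computed (the
analysis design reports tau and bootstrap CIs only). With seven species
(21 pairs) this is deliberately descriptive; formal phylogenetic
comparative modelling is out of scope.

The bundled reference tree is constructed from the published
between-species substitution distances under ultrametry (each pair's
distance is twice its MRCA depth, which pins every node depth); its
patristic matrix reproduces the published distances exactly. A
pseudo-posterior stands in for a Bayesian tree sample when only a point
tree is available: multiplicative log-normal branch-length jitter with
median 1 and log-SD `jitter` (default 0.2), topology fixed. This captures
depth uncertainty but, by construction, no topological uncertainty.

## Canonical variate analysis

Species differences in *mean* behaviour are described by CVA on
within-individual mean trait vectors: the between- vs pooled-within-group
generalized eigenproblem, solved by whitening with the Cholesky factor of
the pooled within-group covariance. Group means enter the between-group
scatter unweighted by group size (sample sizes differ enormously across
species, and weighting would let one species dominate the axes). Canonical
scores are scaled so their pooled within-group covariance is the identity.
Confidence ellipses describe the *score distribution* (covariance
eigen-axes scaled by the $\chi^2_2$ quantile), not the standard error of
the mean — they portray phenotypic spread.

## The synthetic generator

`simulate_species()` draws data from exactly the model the estimation
stage assumes — one $u_i$ per fish from `true_ID`, one $e_{ij}$ per trial
from `true_R`, plus repeat and order fixed effects — so full-pipeline
parameter recovery is a meaningful correctness check. Design choices:

- Fish are blocked into housing groups of `group_size` in ID order, with
  within-group order $1..g$; no assignment rule is canonical, and this is
  the simplest one consistent with order effects acting within groups.
- Parameters live on the *analysis* scale (body lengths, %, $\sqrt{s}$),
  where covariances are interpretable in (approximate) SDU²; the recorded
  file columns are produced by the exact inverse of the preprocessing
  transforms. Parameterizing a Gaussian model directly in raw units while
  specifying covariances in SDU² would be incoherent and would break
  recoverability. A consequence: a strongly negative Gaussian deviation in
  $\sqrt{\mathrm{TIM}}$ is clamped at 0 before squaring (the clamp count is
  recorded); defaults keep the clamping probability negligible.
- The realized latent $u_i$ are attached as an attribute for oracle checks
  but excluded from the file format.

Default study conditions mirror the source design: seven species with
26–831 fish each, 4–6 trials per fish, groups of 8; generating
$\mathbf{ID}$ matrices are reconstructed from the published eigenstructure
(leading plane exact, residual variance split isotropically over the
orthogonal complement — the trailing orientation is unreported, so an
isotropic split adds no spurious structure); residual covariances target
the published median repeatability (0.366) per trait with moderate (0.25)
residual correlation; species mean separations are kept at 1–2
within-species SDs so global standardization preserves both mean structure
and within-species variance, as in the real data. Habituation
(−0.04 SDU/trial on movement traits, +0.05 on TIM) and order slopes
(−0.01 to −0.02 SDU per order unit) are small, plausible values.

What the generator does *not* emulate: tracking noise, arena-geometry and
tank-size effects, sex structure, non-Gaussian tails, and
individual-by-environment plasticity. Passing the recovery and calibration
suites therefore demonstrates correctness of the estimation machinery
under the stated model, not robustness to real-data violations of it.

## Problem sizes used by the test suite

Simulation-based checks are sized to be informative yet quick: parameter
recovery at 500 fish × 5 trials with a 200-draw bootstrap (elementwise
3-SE band); LRT size at 60 fish × 4 trials (6 df) and 50+50 × 4 (10 df)
over 200 null replicates, asserted against exact binomial 95% bands around
0.05; trace-CI coverage at 100 fish × 4 trials, 100 bootstrap draws, 100
outer replicates against the binomial band around 0.95; signal-CI null
coverage with Wishart-perturbed matrices over 100 replicates of 200
bootstrap reps. Publication-scale settings (5000 bootstrap draws, 1000
signal reps) remain available through `analysis_config()`.

## Known limitations

- The equality LRT relies on the $\chi^2_{10}$ asymptotics of REML LRTs;
  at very small n it can be mildly miscalibrated.
- Percentile bootstrap CIs are first-order; trace CIs can undercover
  slightly at small n (the coverage test quantifies this at its stated
  size).
- One published pairwise angle is internally inconsistent with the
  published loadings (see the comment in
  `tests/testthat/test-matrix-compare.R`); the package reproduces the
  loadings' implication, not the likely-typographic table entry.
- The reconstruction of full ID matrices from a two-eigenvector summary is
  exact only on the leading plane; statistics that depend on the trailing
  subspace orientation would not be reproducible from published values and
  are not asserted against them.
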