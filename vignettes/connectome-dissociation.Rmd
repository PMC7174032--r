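---
title: "Methods: structural subnetworks and the working-memory/reasoning dissociation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural subnetworks and the working-memory/reasoning dissociation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcog)
```

## The scientific question

Diffuse axonal injury after moderate-severe traumatic brain injury damages
white matter throughout the brain, but patients differ widely in which
cognitive functions suffer. This package implements a connectomic analysis
of that heterogeneity for two higher-order abilities, working memory and
reasoning. Each subject contributes a structural connectome — a 90-node
grey-matter parcellation whose edges are white-matter tracts weighted by
fractional anisotropy (FA) — and scores on six computerized tasks, three
loading on working memory (MKL, PAL, SOS) and three on reasoning (FTM, OOO,
HTT). Two functionally defined subnetworks of the connectome (31
working-memory nodes, 26 reasoning nodes, 9 shared) are interrogated with
graph-theoretic measures, and those measures are related to latent
cognitive components through correlation, canonical correlation and
kernel-ridge prediction. The hypothesis of interest is an *asymmetric*
(one-way) dissociation: working-memory subnetwork integrity matters for
both abilities, reasoning subnetwork integrity for reasoning only —
the signature predicted by hierarchical models in which material must be
held in working memory before it can be manipulated.

## Pipeline and modelling choices

### Connectome construction and thresholding

Edge values are mean tract FA multiplied by streamline count
(`build_connectome()`), so large tracts dominate over weak, noise-prone
connections; absent tracts are zero-filled. Thresholding is
control-referenced (`fit_threshold_scheme()`, `apply_threshold()`): for
every connection the control cohort supplies a mean $\mu_{ij}$ and SD
$\sigma_{ij}$ (zeros included, population denominator by default,
switchable), and at level $t$ any value below $\mu_{ij} - t\,\sigma_{ij}$
is set to zero. Ten levels, 0.5–5.0 SD in 0.5 steps, are always available;
analyses report the moderate level $t = 2.5$. Three consequences of the
formula are worth making explicit because they are asserted in tests:
larger $t$ means a *lower* cutoff and therefore weakly more surviving
edges; values exactly at the cutoff survive (the rule replaces values
strictly below it); and negative cutoffs keep every present edge. These
follow from applying the stated formula literally.

### Graph measures

Degree centrality is the binary count of surviving edges — its role is a
dysconnectivity index after thresholding, so weights are deliberately not
summed (weighted strength is available via `strength = TRUE`). Path-based
measures map weights to lengths by $1/w$, the standard connectomics
convention. Global efficiency is the mean inverse shortest-path length with
disconnected pairs contributing zero, which keeps the measure finite on
fragmented patient networks. Local efficiency of a node is the global
efficiency of its neighbour-induced subgraph (zero below two neighbours);
of the two variants in circulation this is the common toolbox default, and
the oracle test suite pins its exact semantics. Clustering uses the Onnela
geometric-triangle form on max-normalised weights, which makes it
scale-invariant. Hubs are the top `floor(0.2 * N)` member nodes by
control-average degree within the subnetwork, ties broken by label order;
with 31 and 26 member nodes this yields 6 and 5 hubs.

### Behavioural preprocessing and components

Task scores are residualised on age, age², age³ (OLS), then mapped through
a rank-based inverse normal transform using the Blom offset
$\Phi^{-1}((r - 3/8)/(n + 1/4))$ with average ranks for ties — the offset
convention is unstated in the source analyses, and Blom is the common
default. Components come from a PCA of the task correlation matrix with
Kaiser retention (unrotated eigenvalue > 1) and varimax rotation with
Kaiser row normalisation; scores are least-squares regression scores, and
each component's sign is flipped so its dominant loading is positive.
One numerical caveat discovered during development: the single-start
varimax iteration in base R can stall at a saddle point when the unrotated
loadings are nearly symmetric across components — exactly the geometry of
a balanced two-factor battery — so `pca_varimax()` restarts the rotation
from a deterministic set of random orthogonal bases and keeps the solution
with the highest varimax criterion.

### Association, CCA and prediction

Group comparisons are pooled-variance t-tests with the control-minus-
patient sign convention. All multiplicity correction is Benjamini-Hochberg,
with families mirroring the analysis design: the 12 global correlations
(2 networks × 3 metrics × 2 components) form one family; nodal
correlations are corrected across nodes within each network × metric ×
component family (whether the source analyses pooled metrics within a
nodal family is not fully explicit; per-metric families are used and the
family label is exposed in the output so the choice is auditable).

The CCA stage first reduces the 90 whole-brain degrees to the smallest
standardised-PCA basis capturing 90% of variance (standardising first
makes the rule scale-free). The canonical decomposition itself is QR + SVD;
mode significance uses marginal per-mode permutation nulls (subject
correspondence shuffled, 10,000 permutations by default) with the $+1$
p-value correction so $p > 0$. Marginal nulls mirror the stated procedure
rather than sequential (Wilks-style) testing, although modes are not
independent. Back-projection correlates each canonical variate with the
raw tasks and raw node degrees. The subsampling routine refits the CCA on
random training subsets over the fraction grid {0.5, …, 0.9} (the grid is
a package choice; only "systematic variation" is specified) and evaluates
held-out correlations, with a row-permuted reference quantifying overfit.

Prediction uses kernel ridge regression with a linear kernel (which keeps
primal weights $w = X^\top\alpha$ interpretable), nested 5-fold
cross-validation with the penalty chosen on inner folds from a 13-point
logarithmic grid $10^{-4}..10^{2}$, feature standardisation inside each
training fold only, pooled out-of-fold Pearson $r$, and permutation
p-values from rerunning the whole nested procedure on permuted targets.
The grid's upper end is deliberately kept below the kernel's eigenvalue
scale (with fold-standardised features the linear-kernel eigenvalues grow
with the training-set size): penalties far above that scale collapse
predictions toward the training mean, and because fold training means
anti-correlate with held-out values, the pooled cross-validated
correlation then acquires a spurious negative bias under the null. With
the bounded grid the null pooled $r$ is centred near zero, which the
acceptance suite checks directly.
Because the fold structure and kernels depend only on the features, they
are computed once per model and shared across permutations. Reported
$R^2$ is the squared pooled correlation and normalised MSE is MSE divided
by the variance of the observed target; both are descriptive conventions
of this package (the source material leaves them undefined).

## The synthetic cohort generator

No subject-level data are distributed with the study this analysis
emulates, so the generator (`generator_config()`, `simulate_cohort()`) is
a first-class module: it plants a known statistical structure through the
whole causal chain (edges → subnetwork integrity → latent abilities →
task scores) so that every downstream stage can be tested for recovery and
calibration.

Study conditions (defaults): 105 controls and 92 patients (the cohort
sizes of the motivating study); control edge FA ~ Normal(0.45, 0.06)
truncated to (0,1) by resampling (typical skeletonised-FA statistics; the
truncation preserves FA's physical range); atlas edge density 0.30;
patients carry a 1.0 SD global FA deficit on every tract (diffuse injury).
Two independent per-subject factors per subnetwork act on the tracts
*exclusive* to that subnetwork's induced subgraph: a Gaussian biological
integrity factor (`bio_sd = 1`, all subjects) and a half-normal injury
factor (`subnet_deficit_sd = 1.5`, patients only). Latent abilities follow
the asymmetric preset

$$\mathrm{WM} = 0.8\,z_{wm} + \varepsilon,\qquad
  \mathrm{RSN} = 0.6\,z_{wm} + 0.8\,z_{rsn} + \varepsilon,
  \qquad \varepsilon \sim N(0, 0.7^2),$$

where $z$ are subnetwork integrities (mean exclusive-tract FA,
standardised against controls), and tasks load 0.8/0.7/0.6 on their
ability with residual SD $\sqrt{1-\lambda^2}$, plus a cubic trend in
standardised age. Ages match the study groups (controls ~ N(45, 15),
patients ~ N(43, 12.4), truncated to 20–80).

Two design choices deserve justification:

* **Exclusive-tract assignment.** Tracts inside the shared 9-node
  subgraph carry only the global components. If the working-memory factor
  also degraded shared tracts, it would leak into the reasoning
  subnetwork's mean FA and the generative null — reasoning integrity
  uncorrelated with working-memory ability — could not hold. The planted
  factors are therefore identifiable by construction, at the cost of not
  modelling shared-tract individual differences.
* **Effect-size calibration.** `noise_sd`, the cross-coupling and the
  injury scale were fixed, once, so that the synthetic cohort reproduces
  the order of magnitude of the reported statistics of the motivating
  study (brain-behaviour correlations around 0.2–0.5 rather than a
  near-deterministic chain; cross-sectional t statistics in the 5–9
  range). Without biological between-subject variation the integrity
  z-scores of patients sit many control-SDs from zero and every
  correlation saturates, which no empirical cohort shows.

What the generator does *not* emulate: spatial structure of lesions,
shared global individual differences across subnetworks (each subject's
two integrity factors are independent), tractography artifacts,
floor/ceiling effects in task scores, and missing data. Uniform edge
degradation also lowers *every* graph measure in patients; the
empirically reported shift away from small-world topology — lower
integration but *higher* segregation (local efficiency, clustering) — is
a topological reorganisation the edge-level deficit model does not
produce. Passing recovery
tests therefore demonstrate that the *machinery* detects the planted
structure at realistic signal-to-noise — not that real cohorts satisfy
the generative assumptions.

One behaviour of the analysis worth knowing about, visible only because
the generator makes truth available: varimax components are (nearly)
orthogonal scores of correlated abilities, so the working-memory component
acquires a small *negative* weight on the reasoning ability. Reasoning-
network measures consequently show a weak negative association with the
working-memory component (a suppression artifact of orthogonal scoring,
around $r \approx -0.1$ under the default conditions) even though the
generative coupling is exactly zero. At the study's sample size this stays
below the detection threshold of the FDR-corrected nodal families in the
large majority of cohorts, which is how the one-way dissociation remains
recoverable.

## Problem sizes and determinism

All stochastic steps draw from explicit seeds (`withr::with_seed`), so
every result in the scripts and tests is bit-reproducible. The test suite
runs its Monte-Carlo checks at reduced but stated sizes: 200 random ≤8-node
graphs against brute-force oracles; 100 synthetic cohorts for component
recovery; 200 replicates at 500 permutations for CCA type-I calibration;
50 cohorts with 200-permutation KRR tests for the dissociation recovery.
The analysis scripts use 10,000 CCA permutations and 1,000 KRR
permutations, matching the reported procedure.

## Known limitations

* The 31/26-node membership lists are a fixture convention: the shared
  nine regions and the hub regions are fixed by name, the remaining
  members fill the lists from the Desikan-Killiany label set (the
  original supplementary lists are not distributed), and the 90-region
  composition beyond the 68 cortical parcels is likewise a convention.
* Only the linear KRR kernel is implemented; weight maps are undefined
  for nonlinear kernels and the analysis does not use them.
* Marginal CCA permutation nulls ignore dependence between modes.
* The mask-based FA extraction assumes voxel arrays are already aligned;
  no registration is performed.
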