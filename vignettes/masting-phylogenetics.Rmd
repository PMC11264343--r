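---
title: "Methods: linking mast-seeding intensity to plant traits on a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking mast-seeding intensity to plant traits on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastphylo)
```

# The scientific problem

Many perennial plants mast: they produce seed crops that vary enormously
from year to year, often synchronously across a population. A comparative
question follows: is the *intensity* of masting an evolved trait that
co-varies with other functional traits — adult height, pollination mode,
growth form, or the deep angiosperm/gymnosperm split — once the
non-independence of related species is accounted for? `mastphylo`
implements the full analysis chain for that question: a masting index
computed from raw seed-crop series, phylogenetic-signal estimation,
phylogenetic mixed models, and a likelihood-based variance partition.

# The masting index

For a series $p_1,\dots,p_n$ of annual production values, the consecutive
disparity index is

$$D = \frac{1}{n-1}\sum_{i=1}^{n-1}\left|\,\ln\frac{p_{i+1}+k}{p_i+k}\right|.$$

It is the mean absolute log fold-change between consecutive years, so it
responds both to the spread of the values and to their temporal
arrangement (lag-1 autocorrelation): a sawtooth series scores higher than
the same values sorted. Properties worth knowing:

* $D \ge 0$, with equality iff the series is constant. Zero-variance
  series return $D = 0$ with a warning rather than an error — the formula
  is perfectly well-defined there.
* The pseudo-count $k$ (default 1, the conventional choice) keeps the
  index finite through complete crop failures. With $k>0$ the index is
  *not* scale invariant; with $k=0$ (allowed only for strictly positive
  series) it is exactly scale invariant.
* If log increments are i.i.d. normal with SD $\sigma_\Delta$ and crops
  are large relative to $k$, $E[D] \to \sigma_\Delta\sqrt{2/\pi}$ — the
  half-normal mean. The test suite checks this closed form by simulation.

Series handling is deliberately strict: records shorter than
`min_length` (default 2; no minimum beyond the formula's requirement is
imposed, and the cutoff is exposed as a parameter) are excluded with a
logged reason, monocarpic-style single observations fall out of the same
rule, and a gap in the year sequence is a hard error because no defensible
imputation rule exists for missing mast years. All trait variables are
log10-transformed before analysis (base 10 rather than natural log so that
axes and coefficients read in orders of magnitude); the disparity formula
itself uses natural log as written.

# Phylogenetic signal

## Continuous traits: Pagel's lambda

The trait is modeled as multivariate normal with mean $\mu\mathbf{1}$ and
covariance $\sigma^2 C(\lambda)$, where $C$ is the Brownian covariance of
the tree (shared root-to-MRCA path lengths, normalized to height 1) and
$C(\lambda)$ multiplies its off-diagonal entries by $\lambda \in [0,1]$.
$\mu$ (GLS mean) and $\sigma^2$ (ML variance) are profiled in closed form;
the remaining 1-D likelihood in $\lambda$ is maximized by bounded search
(21-point grid to bracket the optimum, then golden-section refinement at
tolerance 1e-8, with both boundaries evaluated explicitly so estimates of
exactly 0 or 1 are attainable). The upper bound is fixed at 1.0 — not the
algebraic maximum the tree would allow — to keep the estimate on the
conventional interpretable range.

Two significance measures are reported side by side, because practice in
the field uses both: a likelihood-ratio test against $\lambda = 0$ using
the boundary null $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, and a
randomization test that re-estimates $\lambda$ on tip-shuffled traits,
with $p = (1 + \#\{\hat\lambda_{perm} \ge \hat\lambda_{obs}\})/(n_{perm}+1)$.
The pipeline reports the randomization p as primary.

Numerical notes: for an ultrametric tree the whole family $C(\lambda)$
shares one eigenbasis, so a single eigendecomposition makes each
likelihood evaluation $O(n)$ — this is what makes 999-permutation
randomization tests cheap. Non-ultrametric trees fall back to a Cholesky
factorization per evaluation. On a star phylogeny the likelihood is flat
in $\lambda$; the fit is returned flagged `unidentifiable` instead of an
arbitrary interior value.

## Binary traits: the Fritz–Purvis D statistic

Each internal node is assigned the mean of its children's values
(equal weights; branch lengths play no role in the traversal) and the
absolute differences between each child and its parent are summed to give
$d_{obs}$. Two nulls are simulated: tip shuffles preserving prevalence
(phylogenetically random), and Brownian traits simulated on the tree then
thresholded *by rank* so that exactly the observed number of tips is in
state 1 (prevalence preservation is thus guaranteed, rather than
approximated through a liability cutoff). The standardized statistic

$$D = \frac{d_{obs} - \overline{d_B}}{\overline{d_R} - \overline{d_B}}$$

centers on 0 under Brownian clumping and 1 under random structure — the
calibration the acceptance script verifies by simulation. $P_r$ and $P_b$
are one-sided permutation probabilities with a +1 pseudo-count, so a
maximally extreme observation reports $p < 1/(n_{sim}+1)$ rather than 0.
Implementation detail: node averaging is linear in the tip values, so the
package precomputes a per-edge difference operator once per tree and
scores all null replicates in a single matrix product.

Polytomies are retained for covariance construction but resolved
deterministically with zero-length branches before contrasts and the
sister-difference traversal; the likelihood and path lengths are
unchanged by that resolution.

# The phylogenetic mixed model

The response (log10 masting intensity) is modeled as
$y = X\beta + u + e$, $u \sim N(0, \sigma^2_p C)$,
$e \sim N(0, \sigma^2_e I)$, a Gaussian phylogenetic GLMM with the
phylogeny as a random intercept. The fit is full ML — not REML — so that
log-likelihood differences across *fixed-effect* structures are valid for
AIC and for the likelihood R² below. The variance structure is
reparameterized as $V = \sigma^2\{hC + (1-h)I\}$ with
$h = \sigma^2_p/(\sigma^2_p+\sigma^2_e) \in [0,1]$: $\beta$ is profiled by
GLS and $\sigma^2$ in closed form, leaving a 1-D profiled likelihood in
$h$, optimized the same way as $\lambda$ (grid bracket + bounded search;
$h$ on its boundary is a legitimate solution, not a failure). Because
$hC + (1-h)I$ commutes with $C$, one eigendecomposition serves every
candidate $h$.

$C$ is normalized to height 1 before fitting so that $\sigma^2_p$ and
$\sigma^2_e$ are on the same scale and comparable across trees. Standard
errors come from the GLS information matrix at the ML variances, and
p-values are two-sided normal (Wald z) to match the usual reporting
convention for these models. AIC is $-2\ln L + 2k$ with $k$ counting the
coefficients plus two variance components (one for the non-phylogenetic
model). Binary predictors are coded 0/1 with the alphabetically first
level as 0 unless supplied numerically; the coding is echoed in the fit
print-out because coefficient signs depend on it.

Degenerate inputs are surfaced, not absorbed: rank-deficient designs name
the collinear columns, incomplete rows are dropped with a message, and a
subset leaving fewer than 5 species (or fewer than p+3 in general) is an
error.

## Correlation corrected for phylogeny

The evolutionary correlation between two traits is computed from
Felsenstein's independent contrasts as the correlation through the origin,
$R = \sum c_x c_y / \sqrt{\sum c_x^2 \sum c_y^2}$, with a t test on
$n_{contrasts} - 1$ degrees of freedom. A GLS formulation (equivalent on
bifurcating trees, and the package tests that equivalence) is available
via `method = "pgls"`. Contrasts are the default because they are the
most transparent construction for a pairwise question.

## Group comparisons

Height and masting differences between angiosperms/gymnosperms,
trees/non-trees and wind-/insect-pollinated species are Welch two-sample
t tests on log10 values by default; the pooled-variance and untransformed
variants sit behind flags since reports in this literature rarely state
which was used. Group 1 is the alphabetically first level, so the sign of
t is interpretable from the stored group means.

# Variance partition by likelihood R²

For a full and a reduced model on the identical species set,

$$R^2_{lik} = 1 - \exp\{-\tfrac{2}{n}(\ln L_{full} - \ln L_{reduced})\},$$

with $n$ the number of species actually fitted (complete cases). One
reduced model is fitted per predictor (that column dropped, phylogeny
kept) plus one with the random effect removed and all fixed effects kept
— the "phylogeny partial". For an intercept-only reduction of an ordinary
regression this reproduces the classical $R^2$ exactly (ML variance
estimates make the identity exact; the suite asserts it to 1e-10).
Negative values are reported as computed: a reduced model can attain the
higher likelihood when the comparison crosses model classes. The p-value
for fixed-effect drops is a $\chi^2$ LRT; for the phylogeny partial it
uses the $\tfrac12\chi^2_0+\tfrac12\chi^2_1$ boundary mixture and is
flagged approximate, since removing a variance component is a boundary,
not a nested-mean, comparison. Note that although parts of this
literature describe the partial R² under a "logistic regression" heading,
the response here is Gaussian and the partition is implemented for the
Gaussian model throughout.

# The synthetic-data generator

The generator is the package's ground truth and emulates the study
conditions the analysis was designed for:

* **Tree**: pure-birth, 158 species by default, rescaled to height 1.
  Birth–death and non-ultrametric trees are deliberately out of scope for
  the generator (the analysis side accepts slightly non-ultrametric trees
  with a warning).
* **Height**: one draw from $N(\mu, \sigma^2 C(\lambda))$ with
  $\lambda = 0.926$ — the strong signal typical of adult height — and
  $\sigma^2 = 0.25$ on the log10 scale (heights spanning roughly 0.1–60 m).
* **Binary traits**: pollination vector (prevalence 80/158) and
  Spermatophyte type (35/158) from the Brownian-threshold model, because
  these traits are strongly conserved; life form from a random shuffle at
  prevalence 0.5, mimicking a trait with weak signal. Prevalence is exact
  by construction.
* **Response**: $X\beta + u + e$ directly on the log10 analysis scale
  (no invented back-transformation), with effects defaulting to the
  multivariate estimates (height 0.288, pollination 0.654, life form
  −0.010, Spermatophyte −0.225, intercept −0.273) and variance components
  $\sigma^2_p = 0.1$, $\sigma^2_e = 0.3$ — a modest phylogenetic share
  consistent with the moderate signal of masting indices.
* **Seed-crop series**: stationary AR(1) log production, default 20
  years, $\phi = 0.3$, innovation SD 1 — short, strongly fluctuating
  records typical of masting datasets. With `series_link = TRUE` the
  innovation SD is set per species so the expected disparity matches the
  species' linear predictor, and the realized log10 D replaces the
  response; this couples the index module to the model stages but changes
  the response's noise distribution, so it is off by default and both
  paths carry ground truth.

What the generator does **not** emulate: measurement error in height,
heterogeneous series lengths and observation protocols across species,
climate drivers and spatial synchrony of masting, polytomies, and
taxonomic name noise. Passing tests therefore demonstrate the estimators'
correctness and calibration under the stated model, not robustness to
every failure mode of real trait databases.

# Reproducibility and problem sizes

Every stochastic operation takes an explicit seed and is bit-reproducible
given it; the pipeline derives per-stage seeds from one master seed and
reruns byte-identically. The test suite runs its calibration checks at
reduced replicate counts (60–200 replicates, 50–200 tips) chosen so the
whole suite completes in well under a minute while keeping Monte-Carlo
error small relative to each tolerance; binomial calibration bands are
computed at the replicate count actually used. The acceptance script runs
the headline calibrations at full size (200 replicates; 100-tip trees
with 500 nulls per trait for the D statistic; 200-tip trees for λ
recovery).

# Known limitations

* The Gaussian PGLMM supports one phylogenetic random intercept; no
  non-Gaussian families, multiple random effects or measurement-error
  models.
* λ is estimated on [0, 1]; trees whose structure would support λ > 1 are
  truncated at the bound by design.
* The phylogeny-partial R² mixes covariance classes; its p-value is
  approximate by construction and labeled as such.
* Exact reproduction of any particular published dataset requires that
  dataset and its pruned mega-tree as inputs; the package validates its
  methods by simulation instead.
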