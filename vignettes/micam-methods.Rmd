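---
title: "Adaptive microbiome association testing and comprehensive taxonomic mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive microbiome association testing and comprehensive taxonomic mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micam)
```

# The testing problem

Given an OTU count table $Z \in \mathbb{N}^{n \times p}$, a rooted
phylogenetic tree over the OTUs, and a host trait $Y$ (continuous or
binary) with optional covariates $X$, the package tests the global null
$H_0: \beta_1 = \cdots = \beta_p = 0$ in the generalized linear model

$$g\,\mathbb{E}[Y_i] = \beta_0 + \textstyle\sum_k X_{ik}\alpha_k +
\sum_j Z_{ij}\beta_j,$$

with the identity link for continuous traits and the logit link for
binary traits.  Everything is built on score statistics, so only the
covariate-only null model is ever fitted: `fit_null()` returns the null
means $\hat\mu_{i,0}$, residuals $r_i = Y_i - \hat\mu_{i,0}$ and the
dispersion $\Phi$ ($\widehat{\sigma}^2_0$ for continuous traits, $1$ for
binary).  The per-OTU score is $U_j = \sum_i r_i z_{ij}$, where $z_{ij}$
is the column-standardized composition (proportions, centered and scaled
by the sample standard deviation).  The sign of $U_j$ is the per-OTU
effect direction reported in the discovery map.

# The candidate tests

**SPU.**  $T_{\mathrm{SPU}(\gamma)} = \sum_j U_j^\gamma$ over the grid
$\Gamma = \{1, \dots, 8, \infty\}$, with
$T_{\mathrm{SPU}(\infty)} = \max_j |U_j|$.  Odd exponents suit
same-direction effects, even exponents survive mixed directions, and
larger exponents concentrate on the largest score components (abundant
OTUs).  The adaptive SPU (aSPU) takes the minimum permutation p-value
across the grid.

**MiRKAT.**  For a distance matrix $D$ the kernel is
$K = -\tfrac12 (I - \tfrac{11'}{n}) D^{(2)} (I - \tfrac{11'}{n})$
($D^{(2)}$ element-wise) and the statistic
$Q = r' K r / (2\Phi)$.  The candidate set is the seven measures:
Bray-Curtis, unweighted UniFrac, normalized weighted UniFrac, and
generalized UniFrac with $\alpha \in \{0, 0.25, 0.5, 0.75\}$.  The
Optimal MiRKAT takes the minimum p-value over the kernels.

**OMiAT.**  The combined statistic is the minimum of all sixteen
per-candidate p-values (nine SPU, seven MiRKAT); its null distribution
comes from the same shared permutation set by the leave-one-out rank
construction, so no nested resampling is needed.

**Aggregate comparator.**  The conventional approach collapses a group to
one predictor $a_i = \sum_j z_{ij}$ and score-tests it.  Opposite-signed
OTU effects cancel inside $a_i$; the simulations below quantify exactly
that failure.

# Permutation inference

All statistics share a single seeded permutation set
(`make_permutations()`).  P-values use the add-one estimator
$(1 + \#\{b: s^{(b)} \succeq s\})/(B+1)$ with ties counted as
exceedances, so no p-value is ever zero and none falls below $1/(B+1)$.
SPU, aggregate and single-OTU statistics are compared by absolute value;
$Q$ is compared one-sided.

Permuted residual vectors are re-projected onto the orthogonal complement
of the $(1, X)$ column space and rescaled to the observed residual norm
before scoring.  The observed residuals satisfy the null-model score
equations (exact orthogonality to the intercept and covariates for both
trait types); the projection makes every permuted copy satisfy them as
well, in the spirit of the Freedman-Lane scheme, and the rescaling
removes the norm shrinkage the projection would otherwise introduce, so
observed and permuted vectors differ only in direction within the
covariate-orthogonal subspace.  Without the projection the null is
noticeably conservative when a covariate is correlated with the
microbiome — the hardest cell of the calibration study — and with the
full scheme every cell sits at the nominal level to within Monte-Carlo
error.

For the adaptive combinations, each permutation's minimum p-value is
computed against the remaining permutations via ranks (the standard
single-layer device), and the final p-value is the add-one tail
probability of the observed minimum.

# The rank scan

`micam_scan()` fits the null once, draws one permutation set, and walks
kingdom → species:

* the kingdom rank holds the entire community as one group, so the
  community-level test is an ordinary scan row;
* at every lower rank OTUs are partitioned by their lineage label;
  OTUs unassigned at a rank are not pooled into a pseudo-taxon and are
  simply not tested there (they remain members of their named
  higher-rank taxa);
* groups of one OTU get the single-OTU score test; groups whose UniFrac
  distances are degenerate (no phylogenetic disparity between any sample
  pair: a zero denominator or an all-zero distance matrix for any
  measure) fall back to the SPU pool plus the Bray-Curtis kernel only;
  all other groups get the full sixteen-candidate pool;
* multi-OTU species are treated as groups like any upper-level taxon;
* Benjamini-Hochberg FDR is applied within each rank at 5%; discovery
  means $q \le 0.05$.

Subgroup tests reuse the global per-sample library sizes: a taxon's
proportions are fractions of the whole community, not renormalized within
the taxon.  This keeps samples with zero counts in a taxon well-defined
and lets a taxon's overall abundance shift contribute signal.  Pruned
subtrees collapse degree-2 nodes with branch lengths summed, so
leaf-to-leaf distances are preserved.

# The synthetic-data generator

The generator emulates a small infant-gut 16S study after abundance
filtering:

* $p = 71$ OTUs, $n = 100$ samples;
* library sizes $\sim$ NB(mean 300, size 10), zero draws redrawn;
* counts from a Dirichlet-multinomial with concentration
  $\pi (1-\theta)/\theta$.  The default mean composition is power-law
  ranked, $\pi_j \propto j^{-1.2}$, giving a dominant OTU near 20% and a
  rarest mean proportion of about $1.5\times10^{-3}$ — i.e. every OTU
  clears the $10^{-3}$ mean-proportion filter that defines the intended
  post-filter community.  The default overdispersion $\theta = 0.02$ is
  in the range reported for human gut Dirichlet-multinomial fits;
* a random rooted binary tree (`ape::rtree`) stands in for the real
  phylogeny, with PAM clustering of its cophenetic distances defining
  five phylogenetically coherent clusters;
* outcomes follow
  $y_i = 0.5\,\mathrm{scale}(X_{1i}+X_{2i}) + \sum_{j\in\Lambda} \beta_j\,
  \mathrm{scale}(Z_{ij}) + \epsilon_i$ (linear) or the logit analogue,
  with $X_1 \sim$ Bernoulli(0.5) and $X_2$ either N(0,1) or correlated
  with the associated OTUs;
* associated sets $\Lambda$: top-decile abundance, random decile, bottom
  decile, or one PAM cluster drawn uniformly per replicate; coefficients
  $\beta_{j\in\Lambda} \sim U(0, c)$ (same direction) or $U(-c, c)$
  (mixed), $c \in \{1, 2, 3\}$.

A third direction mode, `balanced`, re-projects mixed draws so the
planted signal is exactly uncorrelated with the aggregate test's
predictor.  $U(-c,c)$ draws balance only in expectation — with seven
associated OTUs the realized net effect is usually non-zero and the
aggregate test retains some power — so the projection is what isolates
the cancellation failure mode cleanly.  Under it, the aggregate test
collapses to (at or below) the nominal level while score-based tests
keep their power.

What the generator does **not** emulate: real phylogenetic signal in the
mean composition (the tree is random), zero inflation beyond what the
Dirichlet-multinomial produces, longitudinal or repeated-measures
structure, and uneven taxonomic annotation quality.  Passing tests on
this generator show calibration and relative power under the stated
model, not performance guarantees on any particular real dataset.

# Experiment scales

The packaged experiments use sizes chosen to give Monte-Carlo standard
errors small relative to the quantities checked: the calibration study
runs 2000 replicates with 1000 permutations per test (binomial SE at 5%
is about 0.5 percentage points); power comparisons use 500 replicates
per cell with a 3-point tolerance; the planted-signal rank scan uses
5000 permutations.  All four methods are evaluated on the same
replicates under one shared permutation set (common random numbers),
which makes across-method and across-effect-size comparisons paired.
The interactive default for a single scan is 50,000 permutations, which
stabilizes q-values near the 0.05 boundary.

# Numerical and design choices

* Sample standard deviation ($n-1$ divisor) everywhere a scale appears;
  $\Phi = \mathrm{RSS}/(n-q-1)$.  Permutation inference is invariant to
  these constants; they only fix reported statistic scales.
* Zero-variance OTU columns standardize to all-zeros and are flagged, so
  small-taxon tests stay defined.
* Kernels are eigendecomposed and negative eigenvalues clipped to zero
  (Bray-Curtis kernels are generally indefinite); the repair is flagged,
  and the positive-eigenvalue factor is reused by the permutation engine
  to evaluate $r'Kr$ as a sum of squares, which also guarantees
  $Q \ge 0$.
* A UniFrac distance for a sample pair with a zero denominator is
  defined as 0 with a warning and flags the whole measure degenerate;
  degeneracy triggers the Bray-Curtis-only fallback rather than a crash
  inside a subgroup scan.
* Weighted UniFrac is the normalized variant, so all seven candidate
  measures live on $[0, 1]$ and are comparable inside a min-P
  combination.
* Missing branch lengths are a hard error unless unit lengths are
  explicitly requested; no rarefaction is applied anywhere.
* PAM runs on the exact cophenetic matrix with the deterministic
  build-and-swap algorithm, so cluster assignments are reproducible.

# Known limitations

* The sixteen-candidate pool pays an adaptivity penalty: when one branch
  (say, small-exponent SPU for rare mixed-direction signals) is clearly
  best, the combined test can trail that branch by a few percentage
  points of power near the rejection boundary, in exchange for
  robustness across all the other regimes.
* Inference is permutation-only; there are no analytic p-value
  approximations, so very small p-values require proportionally many
  permutations.
* The null model has no overdispersed-count variant (no negative
  binomial or zero-inflated fits), and the scan applies no hierarchical
  gatekeeping across ranks — each rank's FDR family stands alone.
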