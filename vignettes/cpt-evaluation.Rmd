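---
title: "Genomic evaluation of cloned progeny trials with cptEval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic evaluation of cloned progeny trials with cptEval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptEval)
```

## The problem

In eucalypt (and other clonally propagated tree) breeding, a cloned progeny
trial (CPT) merges the progeny-test and clonal-test stages: every
seed-derived progeny (the *ortet*) is vegetatively multiplied and its
*ramets* are planted as replicates of the same genotype. Combined with SNP
genotyping, a CPT lets the analyst split genetic variance into additive and
dominance parts, predict genotypic values `g = a + d` with useful accuracy
at age three, and ask a very practical question: how few ramets per ortet
can future trials afford before heritability, accuracy and the clone
ranking degrade?

`cptEval` implements that full evaluation chain. Because CPT field data
sets are proprietary, the package also ships a first-class synthetic
generator that emulates the design and variance structure such trials
assume, so every stage of the pipeline is testable end to end.

## The data design

The reference design simulated by `cptConfig()` defaults:

* 48 founder genitors; 58 families (47 open-pollinated half-sib with a
  hidden pollen parent, 11 controlled-cross full-sib), 60 progeny each
  (3,480 ortets), of which a fraction 3142/3480 survives the nursery;
* each survivor cloned into 5 ramets and evaluated at two sites with 11 and
  12 sub-trials; each sub-trial is an alpha-lattice with 256 treatments
  (250 progeny + 6 shared control clones), 5 replicates, and 16 incomplete
  blocks of 16 trees per replicate (single-tree plots, 2.5 m x 3.6 m
  spacing);
* a biallelic SNP panel (15,490 markers by default, frequencies in
  [0.02, 0.5]).

The trait is standardized stem volume. Field measurements enter through
`computeVolume()` (`VOL = CBH^2 * pi / 40000 * TH * ST`, CBH in cm, TH in
m, stem taper `ST = 0.45`) and `standardizeTrait()`; the generator
simulates the volume (dm^3) scale directly.

## Models

**Stage one (per sub-trial).** `fitStage1()` fits, within each (site,
sub-trial),

$$y = X_1 g + Z_1 r + Z_2 b + \xi,$$

with genotype `g` fixed, replicate `r` and incomplete block `b` iid random,
and a spatially correlated residual
$\xi \sim N(0, \sigma_\xi^2\, AR1(\rho_c) \otimes AR1(\rho_r))$ over the
plot grid. The genotype BLUEs are the spatially adjusted means passed
downstream. The AR1 correlations are profiled: an outer bounded
Nelder-Mead search over $(\mathrm{atanh}^{-1}$-transformed$)$ correlations
wraps the inner variance-component updates.

**Stage two (across environments).** `fitStage2()` models the adjusted
means with site fixed and random sub-trial-within-site, additive
($\sigma_a^2 G^*$), dominance ($\sigma_d^2 G_d$), additive-by-site
($G^* \otimes I$), dominance-by-site ($G_d \otimes I$) and iid residual
terms. Heritabilities come from
$\sigma_p^2 = \sigma_a^2 + \sigma_d^2 + \sigma_t^2 + \sigma_j^2 +
\sigma_k^2 + \sigma_e^2$ as $h_a^2 = \sigma_a^2/\sigma_p^2$,
$\delta^2 = \sigma_d^2/\sigma_p^2$, $H^2 = h_a^2 + \delta^2$
(`summarizeParameters()`), accuracy as $r = \sqrt{1 - \overline{PEV} /
\sigma^2}$ from the mean prediction error variance and per-clone
reliability as $1 - PEV_i/\sigma^2$.

**Single stage (replicate study).** `fitSingleStage()` fits tree-level
records across both sites with fixed site / sub-trial / replicate margins,
random incomplete block, additive and dominance kernel terms, and a
separate residual variance per site (block-diagonal heterogeneous
structure), using $\sigma_{p_s}^2 = \sigma_{a_s}^2 + \sigma_{d_s}^2 +
\sigma_{b_s}^2 + (\sigma_{e1_s}^2 + \sigma_{e2_s}^2)/2$.
`replicationStudy()` refits this model for every subset of the replicates
of each size `k`, averages the parameters per `k`, aggregates the
per-subset rankings by Mulamba-Mock rank sum (ties broken by clone
identifier), and reports ranking coincidence $R = 100\,C/S$ against the
full-replication reference plus the minimum selection size needed to
recover the reference top set.

## Relationship matrices

* `numeratorA()` builds the pedigree numerator matrix by the tabular
  method; `a22Matrix()` restricts it to genotyped individuals.
* `grmAdditive()` uses centered dosages,
  $G_a = ZZ' / (2\sum_j p_j(1-p_j))$, with $p_j$ the frequency of the
  counted (second most frequent) allele, per-marker mean imputation of
  missing calls, and coding anchored to the minor allele when frequencies
  are estimated in-sample.
* `grmDominance()` uses the dominance-deviation codes
  $\{-2p_j^2,\; 2p_j(1-p_j),\; -2(1-p_j)^2\}$ for dosages 0, 1, 2. The
  codes are read in the same dosage order as the additive coding; this is
  the orientation that makes the coding mean-zero under Hardy-Weinberg
  proportions (the average $G_d$ diagonal is then ~1; the reversed reading
  inflates it severely, which is how we catch it in tests).
* `blendGrm()` forms $G^* = \alpha G_a + (1-\alpha)A_{22}$ with
  $\alpha = 0.98$ by default, restoring invertibility when clones or a
  markers-greater-than-individuals panel make $G_a$ singular. Blending is
  applied to the additive kernel; $G_d$ is used unblended (a flag allows
  otherwise) because the singularity problem is stated for $G_a$.

Allele frequencies are computed once per ortet, never per ramet, so clone
duplication cannot distort them.

## Quality control and pedigree correction

`filterGenotypes()` applies, in a fixed documented order, marker rules
(optional exclusion list, non-autosomal and duplicate-position when
metadata exist, call rate < 95%, MAF < 2% with a strict `<` so exactly 2%
is retained) and then the sample call-rate rule (< 80%). `mendelErrorRate()`
is the opposing-homozygote rate (dosages 0 vs 2) over jointly called
markers; `verifyPedigree()` flags declared parent-offspring pairs above a
1% per-pair rate, substitutes the candidate parent with the lowest rate
when one passes (ties broken by the lowest identifier; exhaustive scan --
the candidate pools here are small), recovers undeclared pollen parents the
same way, and otherwise sets the slot unknown. The 1% threshold is applied
per pair; a per-marker reading is also conceivable, but the per-pair rate
is what the opposing-homozygote statistic naturally delivers.

## The REML engine

`remlFit()` is a dense average-information (AI) REML with:

* linear covariance structure $V = \sum_t \theta_t M_t$, where each
  $M_t = Z_t K_t Z_t'$ (supplied kernel or identity) or a residual slope
  matrix (identity, per-group diagonal, or an AR1 x AR1 correlation);
* an EM-style multiplicative fallback with step halving whenever the AI
  step would decrease the restricted likelihood, making the likelihood
  trace non-decreasing by construction (asserted in tests);
* components bounded below at `1e-8 * var(y)`; aliased fixed-effect
  columns dropped by pivoted QR; convergence at a relative likelihood
  change below `1e-8` *and* relative component change below `1e-6`
  (defaults; batch refits in the replicate study use `1e-6`/`1e-3`), with
  at most 200 iterations and a flagged, last-iterate return on
  non-convergence;
* AR1 correlations bounded to (-0.99, 0.99) and profiled rather than
  jointly AI-updated -- slower but robust, and the per-sub-trial problems
  are small;
* BLUPs $\hat u = \theta K Z' P y$ and prediction error variances from
  $\theta K - \theta^2 K Z' P Z K$, the standard identity with the inverse
  coefficient-matrix block of the mixed-model equations;
* starting values: an equal split of the phenotypic variance across terms.

Everything is dense and sized for desk-scale problems (one Cholesky of an
n x n matrix per iteration; n up to a few thousand).

Accuracy can legitimately clamp to zero in information-poor fits: when the
data carry almost nothing about a term, the mean PEV approaches
$\sigma^2 \overline{\mathrm{diag}(K)}$, which exceeds $\sigma^2$ whenever
the mean kernel diagonal exceeds one. The reported formula divides by
$\sigma^2$ (not $\sigma^2 K_{ii}$), so such fits report accuracy 0 with a
warning rather than a negative square root.

## What the generator does and does not emulate

`simulateCpt()` draws founders from Hardy-Weinberg proportions at
frequencies uniform over the configured MAF range, gene-drops progeny
(hidden pollen fathers drawn uniformly per seed and masked in the declared
pedigree), applies nursery survival, assigns the alpha-lattice layout
(blocks are a uniform random partition per replicate, laid out one block
per grid row, replicates tiled side by side -- the randomization algorithm
and plot arrangement of a real resolvable alpha-design generator are out of
scope), and builds phenotypes as

site + sub-trial + a + d + (a x site) + (d x site) + AR1 x AR1 field +
nugget,

with marker-derived `a` and `d` rescaled so their realized variances match
the configured components exactly, and interaction effects drawn iid.
Default variances are the Table-style components of the reference analysis
(250.76 / 365.14 / 796.16 / 37.47 / 6.28 with site residuals 200.39);
default autocorrelations are the near-zero row/column averages such trials
report (-0.09, -0.01). Controls are unrelated founder-equivalent genotypes:
whether real control clones are related to the population is not stated
anywhere, so the neutral default was chosen.

Not emulated: linkage and LD structure, recombination maps, selfing,
inbreeding depression, spatially structured mortality, measurement-error
models for CBH/TH, and real soil/climate covariates. Passing tests on this
generator therefore demonstrate internal statistical correctness of the
estimation chain, not field realism.

## Design choices in genuinely open spots

* **Standardization scope**: global mean/sd by default, per-site via
  `perSite = TRUE`; the sample (n-1) denominator is used.
* **Stage-two weighting**: adjusted means enter unweighted, matching the
  model statement of the stage-wise approach.
* **Controls in stage two**: excluded (they appear in every sub-trial and
  would break the one-mean-per-site indexing; they are design checks, not
  selection candidates).
* **Response to selection**: reported as `deltaR = S * H^2` with
  `S = xs - x0`, plus the standardized-scale variant `i * H^2` and
  `100 * deltaR / x0`. With the reference means (x0 = 52.36,
  xs = 113.56) and H^2 = 0.37 this yields 22.64 dm^3, i.e. about 43% of
  the base mean; a response near 97% is not reproducible from this formula
  and is therefore not asserted anywhere in the package.
* **Survival**: applied as a random draw of ortets before layout; the
  survival fraction is configurable and defaults to 3142/3480.

## Problem sizes used in the tests

The test suite exercises the chain at reduced scale (its own choice of
study sizes): 20 x 10 x 3 CPTs on 6x6 lattices for the pipeline tests;
spatial-correlation recovery on single 6x6 sub-trials over 12 seeds;
two-kernel recovery on 500 genotypes and full second-stage recovery on
1,000 genotypes x 2 sites over 30 seeds (each component checked against
three Monte-Carlo standard errors); and the replicate-reduction trend on a
full-sib-rich 8x8 design with 5 ramets over 10 seeds. The full reference
design (3,480 progeny, 29,440 trees) is simulated for the counting checks
with a light marker panel.

## Known limitations

* Dense algebra only; no sparse MME path, so populations beyond a few
  thousand genotyped individuals are out of reach.
* Single-trait models; no factor-analytic G x E, spatial splines or
  competition effects.
* Non-genotyped individuals are dropped from genomic stages (no
  single-step H-matrix).
* The likelihood surface for small variance components is flat near the
  boundary; such components converge to the clamp value and their standard
  errors are reported as NA when the AI matrix is degenerate.
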