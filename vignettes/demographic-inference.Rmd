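---
title: "Microsatellite demographic inference: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite demographic inference: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msatabc)
```

This vignette is the package's own account of the science it implements:
the estimators, the coalescent model, the ABC machinery, the tunable
parameters that matter, and what the synthetic-data tests do and do not
demonstrate about real data.

## The setting

The motivating system is a paleoendemic conifer sampled as open-pollinated
seed collections from ~23 groves at 11 microsatellite loci (10
dinucleotide, 1 trinucleotide). Three features drive the design:

1. **The sampling contains relatives.** Seedlings of one mother tree are at
   least half sibs, so diversity and differentiation statistics would be
   biased without kin pruning.
2. **Microsatellites mutate stepwise.** Allele *size* carries information
   about divergence age beyond allele *frequency*; R~ST~ vs permuted R~ST~
   exploits exactly this.
3. **Competing histories are explicit demographic models** — stepping-stone
   colonization, mass colonization, simultaneous divergence after a range
   contraction, and ancient independent origins — compared in a
   simulation-based (ABC) framework because their likelihoods are
   intractable.

## Data model

Allele calls are stored in base pairs; repeat units are derived as
`(size - offset) / motif_length` with a per-locus offset defaulting to 0.
The offset is configurable because fragment-size scoring conventions vary
between laboratories and the stepwise machinery needs repeat counts;
`validate_dataset()` flags sizes incongruent with the motif. Missing data
are handled by pairwise deletion per locus, the convention of the standard
GENEPOP/FSTAT tool chain. GENEPOP reading accepts 2- and 3-digit coding and
names each population block from its first individual label (the part
before the first underscore, else the label minus trailing digits); output
is always 3-digit.

## Estimators

**Gene diversity** uses the unbiased small-sample form
$H_E = \frac{2n}{2n-1}\bigl(1 - \sum_i p_i^2\bigr)$; **allelic richness**
is rarefied hypergeometrically to $g$ diploid individuals ($2g$ genes),
$A_R(g) = \sum_i \bigl[1 - \binom{2N-N_i}{2g}/\binom{2N}{2g}\bigr]$,
computed on log-binomials for stability. $g = 5$ matches the smallest
usable grove sample. The test suite pins the rarefaction to exhaustive
enumeration over all gene subsets on loci with at most 6 individuals.

**Hardy–Weinberg exact tests** use the probability-ordering criterion. The
Monte-Carlo engine is a random-transposition chain: two individuals swap
one gene slot each. On slot-labelled genotype arrays this walk is uniform,
and a uniform array induces the Levene conditional distribution on genotype
tables (a table owns $n!\,2^H/\prod n_{ij}!$ arrays), so every proposal is
accepted and no Metropolis correction is needed. Batch means give the
Monte-Carlo standard error; the chain is verified against complete
enumeration on two-allele tables. Defaults (10^4 dememorizations, 1000
batches, 10^4 iterations per batch) mirror conventional GENEPOP settings
and can be reduced for interactive use.

**Linkage disequilibrium** is screened by a genotypic log-likelihood-ratio
permutation test (shuffling one locus's genotypes across individuals). It
is a screen, not a composite-disequilibrium estimate: the original
LinkDos-style statistic is deliberately not reproduced.

**Relatedness.** The Lynch–Ritland estimator is computed with allele
frequencies from the full sample (the estimator's reference population),
loci combined by the information weights, and the two directed estimates
averaged. Pruning removes, iteratively, the individual with the most
pairwise coefficients above 0.25, recomputing ranks after each removal;
ties break by higher mean offending relatedness, then lexicographic id —
the tie rule is a package choice (any fixed rule gives a valid kin-free
set; determinism makes runs reproducible). The threshold comparison is
strict (> 0.25), and whole populations can be exempted, for the case where
a tiny grove is entirely inter-related and would otherwise vanish.

**Differentiation.** Weir–Cockerham θ sums variance components over
alleles and loci. R~ST~ is the allele-size analogue: gene-copy-level
one-way ANOVA per locus, components summed across loci (ratio-of-sums, not
mean-of-ratios, so low-information loci cannot dominate). The allele-size
permutation test permutes size labels among the distinct observed allele
states within each locus — a bijection, so all frequency structure is
preserved exactly and only stepwise memory is destroyed. The suite checks
both calibration (nominal size under frequency-only divergence) and the
anchor property that mean permuted R~ST~ tracks the θ-scale estimate.

**Isolation by distance.** Rousset's $F_{ST}/(1-F_{ST})$ against log
great-circle distance (radius 6371 km), with a binary indicator matrix for
the like/unlike group contrast. Mantel tests correlate upper triangles and
permute rows/columns of one matrix; the partial Mantel permutes the
residuals of $A|C$ (Legendre), matching the method of the standard IBD web
service. Tails are directional by default because the hypotheses are
directional; a two-sided option exists.

## The coalescent simulator

A continuous-time coalescent with exponential waiting times and
piecewise-constant deme sizes: a diploid deme of size $N$ coalesces a
lineage pair at rate $1/2N$ per generation. Backward-time events are
mergers (colonizations read backward) and size changes; a founder
bottleneck is a size change to `founder_N` covering the `duration`
generations just before (backward of) the colonization. This approximation
is standard and accurate for $N \gtrsim 10$; priors keep sizes at 2 or
more. Mutations are Poisson on branches under a generalized stepwise model:
step length $1 + \text{Geom}(1-P)$, sign symmetric, reflected into a ladder
of 40 contiguous repeat states (strict SMM is $P = 0$). The simulator is
validated against $E[T_{MRCA}] = 2N$, total tree length
$4N\sum_{i<n} 1/i$, and the strict-SMM equilibrium
$H = 1 - 1/\sqrt{1 + 8N\mu}$ (the equilibrium checks use a 200-state
ladder so boundary reflection does not bias the comparison with the
unbounded formula).

Scenario builders produce the four competing histories over five analysis
demes (the pooled southern groves and four northern groups; one tiny,
low-diversity northern grove is excluded from the demographic analysis,
and adjacent grove pairs are pooled). Inter-parameter conditions — ordered
stepping-stone times, ancestral change predating all splits, bottleneck
shorter than the youngest colonization — are enforced both at prior
sampling (rejection) and at scenario construction (errors).

## Priors and mutation model

Exact prior bounds for the original analysis live in supplementary material
that is not part of the main text, so the package ships defaults chosen to
contain all published posterior 95% intervals with room to spare, and every
bound is overridable: $N_1 \in [10^2, 10^4]$, northern deme sizes
$[10, 10^3]$, $N_{div} \in [10^2, 10^4]$, $N_{anc} \in [10^2, 10^5]$,
recent event times $[10, 10^3]$ generations, deep-split time
$[10^3, 10^4]$, ancestral-change time $[10^2, 10^4]$, founder sizes
$[2, 100]$ for $[1, 50]$ generations. The mutation model follows the
DIYABC-style default family: per dataset, each locus group (dinucleotide
vs trinucleotide) draws a mean rate uniform on $[10^{-4}, 10^{-3}]$ and a
GSM parameter uniform on $[0.1, 0.3]$; per-locus rates scatter about the
group mean as Gamma with shape 2. These hyper-parameters are carried in
the reference table as nuisance parameters.

## ABC

The summary vector is fixed by contract: per-deme mean allele count, mean
unbiased gene diversity and mean allele-size variance, then pairwise
Weir–Cockerham F~ST~ and δμ², pairs in lexicographic deme order (35
statistics for five demes). Model checking uses a disjoint holdout set:
mean Garza–Williamson M and pairwise pooled allele counts, pooled size
variances, and shared-allele distances.

Scenario choice standardizes all statistics by the reference table's
median and MAD (robust to the heavy tails prior-predictive simulation
produces), retains the closest `tolerance` fraction (default 1%, with a
floor of 50 retained), weights them with an Epanechnikov kernel, and fits
a multinomial logistic regression of scenario label on the standardized
deviations, read off at the observed point. Confidence limits come from
parametric draws of the regression coefficients (asymptotic covariance) —
a pragmatic choice; if a scenario vanishes from the retained set the
weighted rejection count is reported instead and flagged.

Parameter estimation is Beaumont local-linear adjustment with every
bounded parameter logit-transformed to its prior support before the
regression and back-transformed after, which guarantees adjusted draws
respect the prior bounds. Posterior summaries are weighted quantiles
(median, 2.5%, 97.5%). With `tolerance = 1` and no adjustment the
posterior reproduces the prior — the no-information sanity limit the
tests assert.

Validation: `confidence_evaluation()` computes type I (focal true, not
selected) and type II (competitor true, focal selected) rates over
pseudo-observed datasets with parameters drawn from the priors (the
prior-draw convention; posterior-draw validation can be emulated by
overriding the priors). `rmae()` gives the relative median absolute error
per parameter; `model_check()` simulates from the weighted posterior
sample and locates each observed holdout statistic in its
posterior-predictive distribution.

## Problem sizes and numerical choices

The test suite runs the whole design at desk scale, chosen so the full
suite completes comfortably on one CPU: the ABC replica uses 2×10^4
simulations per scenario (8×10^4 rows) and 50 pseudo-observed datasets; at
these sizes the true simultaneous-divergence scenario wins in 80% of
replicates and the 95% interval for the southern deme size covers the
truth in over 90% — the package's own reproduction, at reduced scale, of a
design originally run at 4×10^6 simulations per scenario. Monte-Carlo
tolerances in tests are set from binomial or delta-method standard errors
at roughly three sigma. Degenerate inputs are contracts, not surprises:
monomorphic loci yield NA for HWE and R~ST~; fixation yields an infinite
Rousset distance with a warning; a control matrix collinear with the
tested matrix is an error.

## What the synthetic data do and do not show

The orchard generator reproduces the relatedness *structure* of
open-pollinated families (half-sib classes, panmictic pollen pools,
optional selfing) and the divergence scenarios reproduce the *demographic*
signal under the stated mutation model. Passing tests therefore
demonstrate internal consistency and statistical calibration under the
model family — not robustness to null alleles, allele-calling error,
within-grove spatial structure, or migration after divergence (the
scenario set deliberately contains none, matching the modelled
histories). Real-data idiosyncrasies of that kind must be screened before
this pipeline, not by it.

## Known limitations

* The logistic confidence limits are asymptotic; at small retained counts
  they can be optimistic (the rejection fallback is more honest there).
* The coalescent ignores migration and overlapping generations; the
  generation-time conversion (Lande's $T = \alpha + s/(\lambda - s)$) is a
  point summary of a long, variable life history.
* The allele ladder truncates extreme sizes by reflection; with realistic
  rates this is invisible, but pathological rate/time combinations can
  compress variance near the boundaries.
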