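# msatabc

Population-genetic analysis and approximate Bayesian demographic inference
for diploid microsatellite data, built around the kind of question a relict
conifer such as giant sequoia (*Sequoiadendron giganteum*) poses: a narrow
chain of isolated groves, low allelic diversity, and several competing
histories — recent northward colonization (stepping-stone or *en masse*),
fragmentation of a formerly continuous range during the late Pleistocene, or
ancient independent origins — that must be discriminated from eleven
microsatellite loci.

The package covers the full analysis chain for such a study:

* **Data model and I/O** — a compact diploid dataset container, GENEPOP
  reading/writing (2- and 3-digit coding), CSV population metadata, and a
  validation report (motif congruence, missingness, sample sizes).
* **Diversity** — observed heterozygosity, unbiased gene diversity
  H<sub>E</sub> = 2n/(2n−1)·(1 − Σp²), allelic richness rarefied to *g*
  diploid individuals by hypergeometric sampling, Markov-chain exact tests
  of Hardy–Weinberg equilibrium, genotypic LD permutation tests, Holm
  sequential-Bonferroni correction, and partial correlations of diversity
  against latitude / grove area / sample size.
* **Relatedness** — the Lynch–Ritland pairwise estimator with information
  weighting, and the iterative kin-pruning rule: repeatedly remove the
  individual involved in the most pairwise coefficients above 0.25
  (half-sib expectation), recomputing ranks after every removal.
* **Differentiation** — Weir–Cockerham θ, Slatkin's R<sub>ST</sub> from
  allele-size variance components, and the allele-size permutation test:
  permuting size labels among allele states erases stepwise-mutation memory,
  so R<sub>STperm</sub> behaves like F<sub>ST</sub> and an observed
  R<sub>ST</sub> in the upper tail indicates phylogeographic signal.
  Rousset's F<sub>ST</sub>/(1−F<sub>ST</sub>), δμ², Garza–Williamson M and
  the shared-allele distance round out the distance statistics.
* **Isolation by distance** — haversine great-circle matrices, binary
  like/unlike-group indicator matrices, Mantel and residual-permutation
  partial Mantel tests with directional tails.
* **Coalescent simulation** — a continuous-time multi-deme coalescent
  (piecewise-constant sizes, backward-time merges, founder bottlenecks) with
  generalized stepwise mutation (geometric step parameter P, reflecting
  boundaries), written in C++ for reference-table throughput.
* **ABC** — DIYABC-style reference tables over four demographic scenarios,
  scenario choice by local multinomial logistic regression on
  median/MAD-standardized summary statistics (per-deme allele counts, gene
  diversities, size variances; pairwise F<sub>ST</sub> and δμ²), parameter
  estimation by Beaumont local-linear regression with logit-transformed
  bounded parameters, and the validation suite: pseudo-observed datasets,
  type I/II error, RMAE, and posterior-predictive checks on holdout
  statistics.
* **Synthetic data** — an open-pollinated clonal-orchard generator (half-sib
  families with a known pedigree) and pseudo-observed datasets with recorded
  truth, so every stage is testable without any external download.

## Worked example

Simulate a study-shaped dataset under the simultaneous-divergence history
(five demes: pooled southern groves plus four northern groups; southern
sample ~200, northern 16–50), then run the inference chain:

```r
library(msatabc)

po <- generate_pseudo_observed(seed = 7)   # truth: N1 = 5380, t_div1 = 68, ...
diversity_table(po$dataset, g = 5)
#>    population_id   n  A_R   H_E   H_O
#> 1          South 200 3.80 0.665 0.656
#> 2       McKinley  19 3.47 0.606 0.598
#> 3 MariposaNelder  44 3.17 0.570 0.548
#> 4 TuolumneMerced  16 3.58 0.626 0.682
#> 5      Calaveras  50 3.55 0.648 0.658

allele_size_permutation_test(po$dataset, n_perm = 2000, seed = 7)
#> R_ST obs = 0.092, mean permuted = 0.047, p = 0.0230
```

The observed R<sub>ST</sub> exceeds its allele-size-permuted reference
(which approximates F<sub>ST</sub>), so divergence here carries stepwise
mutational memory — a phylogeographic signal, as expected for an old split.

```r
tab <- build_reference_table(
  c("mass_colonization", "simultaneous_divergence", "ancient_divergence"),
  n_per_scenario = 5000, seed = 1)
obs <- summary_vector(po$dataset)
model_choice_logistic(tab, obs, tolerance = 0.02)
#> ABC scenario choice (rejection, 300 retained)
#>                 scenario  prob lower upper
#>        mass_colonization 0.221 0.165 0.277
#>  simultaneous_divergence 0.779 0.723 0.835
#>       ancient_divergence 0.000 0.000 0.000

estimate_parameters(tab, obs, "simultaneous_divergence", tolerance = 0.02)
#>   parameter    median     lower     upper
#>          N1 7.195e+03 3.950e+03 9.645e+03
#>      t_div1 3.519e+01 1.938e+01 8.678e+01
#>       N_anc 2.209e+04 2.868e+03 8.527e+04
#>   ...
```

The true scenario wins (posterior 0.78 at this reduced table size; the
ancient-divergence scenario attracted no retained simulations, so the
rejection-count estimate is reported, flagged in the output), and the truth
N1 = 5380 sits inside its 95% interval. Times convert to years through the
Lande life-history formula T = α + s/(λ − s): with s = 0.995 and λ = 1 the
maturity-age range 60–150 y gives generation times 260–350 y (mid value
305 y used for reporting):

```r
generation_time(60, 0.995); generation_time(150, 0.995)
#> 259   349
generations_to_years(68.3, 305)$kya
#> 20.8
```

`run_pipeline("config.yaml")` chains pruning, diversity, IBD, the
R<sub>ST</sub> test and (optionally) ABC, writing CSVs and a seed-carrying
JSON manifest.

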