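---
title: "Models and methods in phylogap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phylogap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylogap)
```

phylogap is an integrated toolkit for a recurring study design in
phylogeography: a widespread species is split into two allopatric genetic
lineages by a band of unsuitable habitat, one lineage is further
subdivided into population clusters, and the analyst wants to know (i)
how the clusters are structured and connected by gene flow, (ii) how long
ago they diverged, and (iii) whether the habitat gap separating the two
lineages also existed under glacial climates, which would support
allopatric divergence maintained by ecology.  The package implements the
full inference chain — microsatellite population structure, assignment
and migrant detection, mitochondrial divergence and diversity,
maximum-entropy niche models, and a least-cost connectivity metric — plus
a seeded synthetic-data generator so every stage can be exercised and
validated without any external downloads.

This vignette documents the models, their assumptions, the tunable
parameters, and the numerical and design choices that were genuinely
open.

## Bayesian admixture clustering and ΔK

The clustering model is the classical admixture mixture model for
multilocus genotypes: individual $i$ carries a membership vector
$q_i \sim \mathrm{Dirichlet}(\alpha, \ldots, \alpha)$ over $K$ clusters;
each cluster $k$ has allele frequencies $p_{kl}$ at locus $l$ with a flat
$\mathrm{Dirichlet}(1)$ prior (independent frequencies, $\lambda = 1$);
each allele copy chooses its cluster of origin $z$ from $q_i$ and its
allele from $p_{z l}$.  `fit_admixture()` runs the standard Gibbs sweep —
$z \mid Q, P$, then $P \mid z$, then $Q \mid z$, then a Metropolis
random-walk update of $\alpha$ under a uniform prior on $(0, 10]$ — in
compiled code, using R's RNG so a seed fixes the chain exactly.

Two deliberate simplifications:

* **Independent allele frequencies.** The correlated-frequencies
  ("F-model") prior mainly adds sensitivity at weak structure.  The
  package targets — and its synthetic scenarios produce — strong
  structure, where the independent-frequency model recovers the same
  clusters; it is also simpler to reason about and test.  This is a
  documented deviation from the most common field configuration.
* **Desk-scale chain lengths.**  Defaults are burn-in = reps = 5000
  (pipeline default 2000 + 2000), far below the 50 000 + 50 000 typically
  used on real data, and 5 replicate runs per K rather than 20.  All are
  plain arguments; raise them for production data.

The marginal likelihood $\ln \Pr(X \mid K)$ is estimated by the standard
harmonic-style estimator $\widehat{\ln P} = \bar{\ell} - s^2_\ell / 2$
over the post-burn-in log-likelihood trace — the same estimator whose
output practitioners feed into the ΔK heuristic.  `delta_k()` computes
$\Delta K = |\bar{L}(K+1) - 2\bar{L}(K) + \bar{L}(K-1)| / s_L(K)$ from
replicate runs; it is undefined (flagged `NA`) when the replicate
standard deviation is zero, and needs at least three consecutive K
values and two runs each.  Label switching is handled only at evaluation
time (`match_cluster_labels()`), by exhaustive search over column
permutations with the lexicographically smallest permutation breaking
cost ties; the sampler itself is unconstrained.

## F-statistics, R-statistics and gene flow

`fst_pairwise()` implements the Weir–Cockerham (1984) θ estimator from
per-locus, per-allele variance components $a$ (among populations), $b$
(among individuals within populations) and $c$ (within individuals),
summed over alleles and loci before the final ratio — the convention of
the standard population-genetics packages.  `rst_pairwise()` is the
microsatellite analogue on allele repeat sizes: a gene-level one-way
ANOVA per locus yields among- and within-population variance components,
again summed over loci.  Because the estimators are unbiased, small or
perfectly balanced samples can produce slightly negative estimates; these
are reported as computed, not clipped.  Missing genotypes are dropped
pairwise per locus everywhere.

`nm_from_fixation()` is Wright's island-model conversion
$Nm = (1 - F)/(4F)$, defined for $F \in (0, 1]$; $F \le 0$ is an
explicit error (unbounded gene flow) rather than a silent `Inf`.  The
model's assumptions (infinite islands, equilibrium, symmetric migration)
rarely hold exactly; the quantity is reported, as in practice, for
comparison between population pairs.

Rarefied allelic richness uses Hurlbert rarefaction of allele counts to
a common number of genes $g$,
$AR = \sum_i [1 - \binom{N - N_i}{g} / \binom{N}{g}]$, delegated to
`vegan::rarefy()`; $g$ defaults to the smallest per-population gene
count in the data set, and requesting more genes than the smallest
sample is an error naming the limiting population.  The cluster-level
permutation test uses the population-weighted variance of cluster means
of per-population mean richness as its statistic, with population labels
permuted across clusters.  Because a variance statistic grows under
divergence of the cluster means in *either* direction, the reported
$P = \Pr(\text{perm} \ge \text{obs})$ is the two-sided test for a
location difference; this construction is what the classical
between-group permutation tests of the FSTAT family report.

`mantel_test()` correlates the off-diagonal entries of a genetic and a
geographic distance matrix, with three standard isolation-by-distance
transforms: raw kilometres, $\ln$ km, and $\ln$ km against
$F/(1-F)$ (pairs at $F = 1$ are excluded with a warning).  Significance
comes from jointly permuting rows and columns of one matrix; when
$n! \le$ `n_perm` the permutation distribution is enumerated exactly,
otherwise `n_perm` (default 1000) random permutations are drawn and the
add-one estimator $(1 + \#\{r^* \ge r\})/(n_{\mathrm{perm}} + 1)$ is
used, which is uniformly distributed under exchangeability.  Great-circle
distances use the haversine formula on a sphere of radius 6371.0088 km.

## Assignment tests and first-generation migrants

`assignment_scores()` offers the two classical likelihood criteria: the
frequency method (product of observed allele frequencies with the
heterozygote factor 2, and a configurable zero-frequency floor, default
0.01) and the Rannala–Mountain partial-Bayesian method (per-locus
Dirichlet posterior predictive with prior $1/J_l$, $J_l$ = alleles known
at the locus).  The home population's frequencies are computed
leave-one-out by default.  Reported scores are likelihoods normalised to
percentages across candidate populations, the convention of the standard
assignment software; an assignment-threshold, where one is wanted, is a
reporting cutoff only and does not change the likelihoods.

`detect_first_gen_migrants()` uses
$\Lambda = L_{\mathrm{home}} / L_{\max}$ on the $\log_{10}$ scale with
leave-one-out home likelihoods.  The null distribution is built per home
population by simulating `n_sim` (default 1000) genotypes from that
population's observed allele frequencies, drawing alleles independently
per locus with replacement — the Monte Carlo resampling recommended for
first-generation migrant detection.  The resident probability is the
fraction of simulated $\Lambda$ at or below the observed one;
individuals with $P < \alpha$ (default 0.01) are flagged.  Two
conventions deserve notice: simulated individuals are scored against the
sample frequencies as-is (they are not part of the sample, so no
leave-one-out), while observed residents are scored leave-one-out.  For
individuals carrying many sample-private alleles this asymmetry makes
the test anticonservative on real members of small samples — the same
behaviour the field software exhibits — whereas for a genuinely typical
genotype the type-I rate is close to nominal (the acceptance suite
measures it over 500 null replicates).

## Mitochondrial distances, dating, networks, diversity

Uncorrected p-distances are delegated to `ape::dist.dna(model = "raw")`
with pairwise deletion.  TN93 distances are computed in the package from
the closed form, with base frequencies estimated *from each pair* over
its comparable sites; this per-pair convention (rather than
alignment-wide frequencies) matches the pre/post contract of the rest of
the pipeline and is cross-checked in the tests against an independent
transcription of the formula and, for two-sequence alignments where the
conventions coincide, against ape.  Saturated pairs whose logarithms
leave the domain are flagged `NA`.  No gamma rate-heterogeneity
correction is applied: the reported quantities of interest are plain
TN93 and p-distances.

Divergence dating is the strict molecular clock $T = p / (2r)$ with a
per-lineage rate $r$ (default 0.007 substitutions/site/Myr, i.e. a
pairwise rate of 1.4%/Myr — the standard amphibian mitochondrial
calibration).  It is linear in $p$ and makes no attempt at rate
uncertainty; that is a documented non-goal.

`haplotype_table()` collapses identical sequences; numbering is
canonical (decreasing count, ties by sequence string), making collapsing
order-invariant and idempotent.  `diversity_indices()` reports $N$, $h$,
polymorphic sites $s$, haplotype diversity
$H_d = n(1 - \sum p_i^2)/(n-1)$ and nucleotide diversity $\pi$ (mean
pairwise p-distance), with standard deviations from Nei's (1987)
sampling formulas.  Sites containing gaps or Ns are excluded pairwise
for $\pi$ and excluded from the polymorphic-site count only where no two
valid bases differ.

The statistical-parsimony connection limit is the largest number of
mutational steps $j$ whose parsimony probability still reaches the
confidence level (default 95%).  The parsimony probability is computed
under a finite-sites, uniform-hit model: $j$ mutations thrown uniformly
on $L$ sites are parsimonious when no site is hit twice, so
$P(j) = \prod_{i=1}^{j-1}(1 - i/L)$.  This is a deliberately transparent
stand-in for the classical recursion used by the original
statistical-parsimony software: it preserves the criterion's qualitative
behaviour (monotone in $L$, decreasing in the confidence) and is
somewhat conservative (for $L = 487$ it yields a limit of 7 steps where
the classical computation allows a few more).  Because the package's
deep-clade scenarios separate clades by dozens of steps and tips by very
few, network topology is insensitive to this difference; analysts
comparing against legacy software should set the limit explicitly if
they need its exact value.

`build_haplotype_network()` is a minimum-spanning network: edge weights
(mutational steps between haplotype representatives) are processed in
increasing order, and every edge of the current weight that joins two
components *as they stood before that weight class* is kept, so
equal-weight alternatives produce reticulations.  Edges above the
connection limit are omitted, which may disconnect the network — that is
the statistical-parsimony behaviour for deeply diverged clades.  Edges
longer than one step carry `n_intermediates = steps - 1` unobserved
intermediate haplotypes as an attribute.

## Maximum-entropy niche models

`fit_maxent()` is a compact maxent: it maximises
$\frac{1}{n_p}\sum_{\mathrm{pres}} \lambda^\top f(x) - \log Z(\lambda)
- \sum_j \beta_j |\lambda_j|$ over linear and quadratic features of the
climate layers, standardised to zero mean and unit variance on the
background; $Z$ normalises $q(x) \propto e^{\lambda^\top f(x)}$ over the
background cells, so the fitted distribution sums to one there (asserted
after every fit).  The per-feature penalty is the maxent convention
$\beta_j = \beta \cdot s_j^{\mathrm{pres}} / \sqrt{n_p}$ with the
presence standard deviation floored at 0.1 background-sd units, and a
single class multiplier $\beta$ (default 1.0).  Only linear + quadratic
features are fitted — no hinge, product or threshold features.  That is
enough to represent any log-quadratic (Gaussian-band) suitability
surface exactly, keeps the problem strictly concave, and matches what
maxent itself uses at small presence samples; it is a documented
deviation from the full feature set of the reference implementation.

The optimiser is FISTA (accelerated proximal gradient) with backtracking
line search and adaptive restart; convergence requires the penalised
objective to move less than `tol` (default $10^{-5}$) with a coefficient
change below $10^{-7}$ on three consecutive iterations, within
`max_iter` (default 500) iterations, else the fit errors with
diagnostics rather than returning a half-converged model.

The logistic output is $LV = e^H q / (1 + e^H q)$ with $H$ the entropy
of the fitted distribution, so a model that has learned nothing
($\lambda = 0$, $q$ uniform, $H = \ln n$) scores 0.5 everywhere.
Projection to another climate stack (e.g. glacial layers) reuses the
training standardisation, normaliser and entropy; values are not clamped
to the training range — clamping is off, and projections into novel
climate space should be read with the usual caution.

Evaluation follows the standard recipe: a one-sided binomial test of the
fraction of test presences predicted suitable at a threshold against the
suitable fraction of the landscape (`binomial_threshold_test()`, with a
default panel of ten thresholds from 0.05 to 0.70 in
`default_thresholds()` — the "commonly used logistic thresholds" are not
standardised anywhere, so the panel is explicit and configurable), and a
rank-based (Mann–Whitney) AUC of presences against background with ties
counted half.  `suitable_area()` multiplies thresholded cell counts
(default threshold 0.1) by a cell area, default 100 km² for 10-km cells.

## Resistance and least-cost connectivity

The connectivity metric converts a suitability raster to resistance by
$1 - LV$ cellwise (`resistance_raster()`), then finds the minimum
accumulated cost between two range borders (`least_cost_path()`), using
Dijkstra's algorithm (via igraph) on the 8-connected grid graph with
move cost = mean resistance of the two cells × 1 for orthogonal and
$\sqrt 2$ for diagonal moves — the cost-distance convention of the
common GIS tools; a 4-connected mode is available by flag, and nodata
cells are barriers.  Costs are reported unitless (resistance × cell
steps).  Because the neighborhood convention of legacy GIS tools is not
always documented, the package treats the metric's *properties* (oracle
agreement, monotonicity under raised resistance, translation invariance,
linear scaling) as its contract, and scenario *comparisons* (current vs
glacial) as its scientific output.  `gap_connectivity_report()` pairs
the two scenario costs with the paired t-test of gap-cell logistic
values and a one-line verdict on the persistence of the gap.

## The synthetic-data generator

`scenario()` fixes the study conditions; the defaults mirror the
sampling design of the motivating system: 4 clusters — a northern
lineage and three southern clusters — across 25 localities (8/6/6/5),
19 diploid individuals per locality, 6 microsatellite loci; a 487-bp
mtDNA fragment at 0.007 subs/site/Myr per lineage on the cluster tree
(basal split 5.0 Myr, southern splits 3.6 and 1.4 Myr, within-cluster
tip depths 0 / 0.3 / 0.8 / 1.9 Myr, so within-cluster diversity rises
from north to south); and a 40 × 60 landscape with a 10-column gap band.

* **Microsatellites** evolve by stepwise mutation: cluster modal allele
  sizes random-walk (±1 repeat, Poisson steps at 3 steps/Myr) along the
  cluster tree, so size variance accumulates with split depth and
  R\_ST-type signals exceed F\_ST-type signals under deep divergence —
  the regime in which analysts prefer R\_ST.  Within clusters, locality
  modes drift along a transect (Gaussian steps, s.d. `ibd_sd` = 0.6
  repeats per locality by default), which produces isolation by
  distance; allele copies scatter geometrically (ρ = 0.5) around the
  locality mode.  An optional admixed locality draws each allele's
  cluster of origin from explicit weights, and the generating membership
  (`true_q`) is returned for recovery tests.
* **mtDNA** evolves by Poisson substitutions (each hit replaces the base
  with one of the other three).  Tips sit at the present: cross-cluster
  tip pairs diverge for exactly twice the split time, so for small
  divergences the expected p-distance is $\approx 2rT$, and the exact
  finite-sites expectation $\frac34(1 - e^{-4\lambda/3})$ with
  $\lambda = 2rT$ is what the generator-law test checks.  No
  transition/transversion skew is applied by default; TN93 then exceeds
  p only through the finite-site correction.
* **Landscape.**  Precipitation rises west to east (≈1300 → 3800 mm)
  with a 500-mm dip over the gap band and 60-mm noise; temperature
  varies by row; altitude falls west to east and is *identical* in both
  periods.  Ground truth: the southern lineage follows a logistic
  envelope of high precipitation (centre 3300 mm, scale 300 mm), so the
  gap is poor now and — after the glacial 600-mm precipitation drop —
  strictly poorer at the LGM; the northern lineage follows a wide
  Gaussian envelope of altitude, so its gap resistance is
  period-invariant *by construction*.  This is the package's cleanest
  way to encode the two qualitative regimes the connectivity metric must
  distinguish (a crossing that deteriorates under glacial climate vs one
  that does not); in the pipeline each lineage is accordingly modeled on
  its limiting variables (south: precipitation + temperature; north:
  altitude).

All generator randomness flows through `with_seed()`, which sets and
restores the RNG state, so a scenario's seed makes every output
byte-identical and nothing leaks into the caller's RNG.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: linkage and null alleles in the
microsatellites, coalescent variance within demes (allele copies are
drawn independently), recombination-free but clock-violating mtDNA
evolution, spatial autocorrelation structure in presence records beyond
the planted envelope, and observation error in climate layers.  Results
on real data will be noisier in all of these directions.

## Problem sizes and determinism

The test and acceptance workloads are deliberately desk-scale: ΔK
recovery uses a two-cluster scenario with 72 individuals and 25 chains
of 1000 + 1000 sweeps; the migrant type-I calibration uses 500 null
replicates with 200 simulated genotypes each; the least-cost oracle
suite uses 200 random 4 × 4 grids; Mantel calibration uses 500 null
replicates at 99 permutations.  Every stochastic step takes an explicit
seed, and the pipeline derives per-stage seeds deterministically from
the global seed and the stage name, so a rerun with one config is
byte-identical.

## Known limitations

* The admixture sampler has no correlated-frequencies prior, no linkage
  model, no location priors; ΔK on weakly structured data will be less
  decisive than field-standard software at full chain lengths.
* The parsimony-probability model is a conservative simplification of
  the classical recursion (above).
* The maxent variant omits hinge/product/threshold features and fits a
  single background (no bias layers); AUCs on landscapes whose suitable
  fraction is large are bounded well below 1 for any model.
* The clock is strict, with no confidence intervals on divergence
  times.
* Geographic distances assume a spherical Earth, and rasters are
  unprojected lat/lon grids; no CRS transforms are attempted.
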