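# phylogap

Integrated phylogeographic inference for species split into allopatric
genetic lineages by a gap of unsuitable habitat.

Many widespread tropical taxa — the motivating case is a Neotropical
frog — consist of two lineages separated by a band of habitat neither
occupies, with one lineage further subdivided into population clusters.
Settling whether such lineages diverged in allopatry, and whether the
gap persisted through glacial climates, takes a long chain of analyses
that normally spans half a dozen single-purpose programs.  `phylogap`
implements that chain as one tested R package, for population
geneticists and phylogeographers who want the whole pipeline scripted,
seeded, and reproducible:

* **Population structure** — Bayesian admixture clustering of multilocus
  microsatellite genotypes (Gibbs sampler, compiled core), marginal
  likelihoods ln Pr(X|K), and Evanno's ΔK for choosing the number of
  clusters K.
* **Differentiation and gene flow** — pairwise Weir–Cockerham
  F<sub>ST</sub> and Slatkin R<sub>ST</sub> from variance components;
  Wright's island-model migrants Nm = (1 − F)/(4F); rarefied allelic
  richness with a cluster permutation test; Mantel tests of isolation by
  distance with the three classical transforms.
* **Assignment and migrants** — frequency and Rannala–Mountain
  likelihood assignment; first-generation migrant detection with the
  Λ = L_home/L_max statistic against a Monte Carlo null.
* **Mitochondrial DNA** — uncorrected p and Tamura–Nei (1993) distances,
  strict molecular-clock dating T = p/(2r) (default r = 0.007
  substitutions/site/Myr per lineage), statistical-parsimony haplotype
  networks, and standard diversity indices (h, s, Hd ± SD, π ± SD).
* **Niche models and connectivity** — a compact maximum-entropy
  suitability model (L1-regularised, linear + quadratic features,
  logistic output LV ∈ [0, 1]), binomial threshold tests and ROC/AUC,
  projection to glacial climates, suitable-area summaries; then
  resistance = 1 − LV and a least-cost path across the distribution gap
  (Dijkstra on the 8-connected grid), so the gap's permeability can be
  compared between current and glacial conditions.
* **Synthetic data** — a fully seeded generator
  (`scenario()`, `simulate_microsatellites()`, `simulate_mtdna()`,
  `simulate_landscape()`) that produces genotypes with hierarchical
  structure and isolation by distance, clock-like mtDNA on a cluster
  tree, and a two-gradient climate landscape with a gap band, so the
  whole pipeline is testable end to end.

File formats: STRUCTURE two-row and Genepop genotype text, FASTA
alignments, CSV locality tables, ESRI ASCII grids — all with validating
readers and round-tripping writers.

## A worked example

Simulate a two-lineage scenario (two localities per lineage, 12 diploids
each, six stepwise-mutating microsatellite loci, a 5-Myr basal split)
and push it through the genetic half of the pipeline:

```r
library(phylogap)

sc <- scenario(n_clusters = 2, localities_per_cluster = 2,
               individuals_per_locality = 12, seed = 1)
ms <- simulate_microsatellites(sc)
cl <- ifelse(grepl("^North", ms$genotypes$locality_ids), "North", "South_1")

fst_pairwise(ms$genotypes, cl)
#> pairwise_matrix (fst), 2 labels
#>          North South_1
#> North   0.0000  0.2582
#> South_1 0.2582  0.0000
rst_pairwise(ms$genotypes, cl)
#> pairwise_matrix (rst), 2 labels
#>          North South_1
#> North   0.0000  0.8958
#> South_1 0.8958  0.0000
nm_from_fixation(0.8958)
#> [1] 0.02908238
```

R<sub>ST</sub> (0.896) far exceeds F<sub>ST</sub> (0.258): under
stepwise mutation, deep splits accumulate allele-*size* variance that
identity-based F<sub>ST</sub> underestimates — exactly why R<sub>ST</sub>
is preferred for microsatellites.  Nm ≈ 0.03 migrants per generation
says the lineages are effectively isolated.

```r
fit <- fit_admixture(ms$genotypes, K = 2, burnin = 2000, reps = 2000, seed = 2)
fit
#> cluster_fit: K = 2, ln Pr(X|K) = -1037.45 (burnin 2000, reps 2000)
mean(apply(fit$Q, 1, max))
#> [1] 0.9948...   # every individual confidently assigned to one cluster

aln <- simulate_mtdna(sc)
grp <- sub("_[0-9]+$", "", aln$ids)
pd  <- group_mean_distance(p_distance(aln), grp)
pd$between["North", "South_1"]
#> [1] 0.0586...
divergence_time(pd$between["North", "South_1"])
#> [1] 4.19     # Myr, from T = p / (2 * 0.007)
diversity_indices(aln)
#> N = 19, h = 6, s = 33, Hd = 0.678 +/- 0.093, pi = 0.0313 +/- 0.0164
```

The clock estimate (4.19 Myr) recovers the generating 5-Myr split to
within the finite-site and Poisson noise of a single 487-bp fragment.

The landscape half works the same way (`simulate_landscape()`,
`fit_maxent()`, `predict_logistic()`, `resistance_raster()`,
`least_cost_path()`, `gap_connectivity_report()`), and
`run_full_analysis(default_config(seed = 1))` drives every stage from
one config, writing per-stage CSV/JSON artifacts and a `summary.json`
that is byte-identical on rerun.  A thin command-line wrapper lives at
`inst/cli/phylogap.R` (`simulate`, `run-all`, `clock`, `nm`, `fst`,
`rst`, `diversity`).

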