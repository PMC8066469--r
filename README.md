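# CoupledOmics

Statistics for paired metagenome–metaproteome surveys of microbial
communities. A DNA survey says which taxa are *present*; a protein survey
says which are *metabolically active*. This package quantifies the
agreement — and the informative disagreement — between the two layers for
designs like a hatchery water-column time course: taxa (or Gene Ontology
terms) counted in sequencing reads and in peptide spectral matches (PSMs)
across days and treatments, with technical-replicate mass-spectrometry
runs.

It is aimed at microbial ecologists and proteomics analysts who already
have annotated count tables (MEGAN-style taxon/GO exports, Abacus-style
scored protein tables) and want the downstream analysis to be validated,
scripted and reproducible.

## What it computes

* **Protein evidence filtering and NSAF** — keep proteins with
  ≥ 2 unique peptides and ProteinProphet-style probability ≥ 0.93, average
  technical replicates on raw spectral counts, then
  NSAF<sub>i</sub> = (SpC<sub>i</sub>/L<sub>i</sub>) / Σ<sub>j</sub>(SpC<sub>j</sub>/L<sub>j</sub>)
  per sample.
* **Taxon/GO aggregation** — lineage-based, mixed Kingdom-through-Class
  reporting; GO terms receive each carrying protein's full count; mass is
  conserved via an `unassigned` bucket.
* **Concordance** — per (day, treatment): library-normalized ratios,
  first-zeroed temporal deltas Δ<sub>n</sub> = r<sub>n</sub> − r<sub>n−1</sub>,
  OLS of PSM ratios on read ratios with R², per-taxon activity bias
  log2((q + ε)/(p + ε)), and cross-layer presence/absence.
* **Diversity and community structure** — Shannon-Weaver H = −Σ p ln p,
  Simpson reciprocal 1/Σ p², Bray-Curtis dissimilarity, NMDS (Kruskal
  stress-1, multi-start, seeded), and a permutation ANOSIM
  R = (r̄<sub>between</sub> − r̄<sub>within</sub>)/(M/2) with exhaustive
  enumeration for small n.
* **Differential GO analysis** — Laplace-smoothed log2 ratio of a term's
  share between pooled conditions, two-proportion z-test,
  Benjamini-Hochberg q-values, q ≤ 0.05 decision rule, and per-taxon
  contribution breakdowns for significant terms.
* **A coupled synthetic-data generator** — multinomial read and PSM layers
  linked by per-taxon activity multipliers (q ∝ p·a), layer-specific taxon
  dropout, tanks and triplicate technical runs, with exact ground truth for
  recovery tests.

## Worked example

Simulate a coupled dataset with the default design (25 taxa, 2 treatments ×
4 days, activity multipliers distorting the PSM layer), then run the core
analyses:

```r
library(CoupledOmics)

config <- simulationConfig(seed = 1)
sim <- simulateCoupledOmics(config)

kept <- filterProteins(sim$proteins, minUnique = 2, minProbability = 0.93)
kept
#> ProteinSet: 201 protein(s) x 48 run(s)
#>   probability range: [0.934, 0.996]; unique peptides: 2-12

avg  <- averageTechnicalReplicates(proteinCountTable(kept, sim$sampleMeta),
                                   sim$sampleMeta)
nsaf <- computeNSAF(avg, proteinLength(sim$annotations, rownames(avg)))
mpTaxa <- aggregatePSMs(avg, sim$annotations, level = "taxon", rank = "Class")

anosim(brayCurtis(nsaf), sampleMeta(nsaf)$day, nPerm = 999, seed = 2)
#> ANOSIM: R = 0.9462, p = 0.001 (Monte-Carlo, 999 permutations)

head(concordanceByCondition(sim$metagenomeTaxa, mpTaxa), 4)
#>   day treatment feature_kind n_features     slope    intercept r_squared
#> 1   1     pH7.1        taxon         25 1.2019547 -0.008078189 0.6648286
#> 2   5     pH7.1        taxon         25 1.1457166 -0.005828663 0.6494449
#> 3   8     pH7.1        taxon         25 0.7052732  0.011789072 0.6003648
#> 4  12     pH7.1        taxon         25 0.7106150  0.011575399 0.5863172

bias <- activityBiasTable(sim$metagenomeTaxa, mpTaxa)
subset(bias, feature_id == "Deltaproteobacteria" & day == 8)
#>              feature_id day treatment read_ratio psm_ratio log2_bias
#> 54  Deltaproteobacteria   8     pH7.1   0.028019 0.1083166  1.950739
#> 154 Deltaproteobacteria   8     pH8.2   0.031611 0.1149621  1.862626
```

Reading the output: community composition separates strongly by day
(ANOSIM R = 0.95 at the permutation floor p = 0.001); read and PSM shares
correspond only moderately per condition (R² ≈ 0.59–0.66), because the
generator's activity multipliers decouple the layers; and
Deltaproteobacteria — simulated with multiplier 4, i.e. true bias
log2 q/p ≈ 1.9 at its abundance — is recovered as about 4-fold more active
(log2 bias ≈ 1.9) than its read share predicts.

`runPipeline(outDir, config)` chains all stages (including NMDS,
presence/absence, differential GO tests and a ground-truth recovery
report) and writes every input and result as deterministic TSVs; a
command-line wrapper is installed at `inst/scripts/run_pipeline.R`.

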