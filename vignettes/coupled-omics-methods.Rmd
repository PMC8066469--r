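---
title: "Coupled metagenome-metaproteome analysis: models and methods"
author: "CoupledOmics package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled metagenome-metaproteome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoupledOmics)
```

## The scientific problem

A DNA-based survey of a microbial community (metagenomics) tells you which
taxa are *present*; a protein-based survey (metaproteomics) tells you which
taxa are *metabolically active*. The two views routinely disagree: a taxon
can dominate the read pool while contributing almost no protein, or
contribute far more peptide spectral matches (PSMs) than its read share
predicts. CoupledOmics implements the statistics needed to quantify that
disagreement in a paired design — here, water-column bacterial communities
from a shellfish hatchery sampled on days 1, 5, 8 and 12 at two pH levels
(7.1 and 8.2), with metagenome sequencing libraries and triplicate-injection
LC-MS/MS metaproteome runs on the same biological material.

Both layers are reduced to feature-by-sample count tables: taxa (mixed
Kingdom-through-Class groups, because lowest-common-ancestor placement
often cannot reach the Class rank) or Gene Ontology terms, counted in reads
or PSMs. Everything downstream of taxonomic/functional annotation and
database searching is in scope; read trimming, gene prediction, LCA
assignment and peptide-spectrum scoring are upstream tools whose *outputs*
this package consumes.

## Metaproteome quantification

**Evidence filter.** Proteins enter the analysis only with
`unique_peptides >= 2` (pooled over all runs) and a ProteinProphet-style
posterior `probability >= 0.93`, the probability that corresponds to a 1%
protein-level FDR in a combined analysis. The probability is consumed, not
estimated: FDR machinery is upstream. The pooled reading of the two-peptide
rule (at least 2 unique peptides *across* all replicates, not per run) is a
deliberate choice; the per-run reading discards reproducibly observed
low-abundance proteins and is not what consensus tools report.

**Replicate averaging.** Technical (repeat-injection) runs are averaged
*on raw spectral counts*, before any normalization. Averaging normalized
values would give runs with fewer total PSMs the same weight as deeper
runs, inflating their sampling noise.

**NSAF.** For protein $i$ with length $L_i$ and spectral count
$\mathrm{SpC}_{i,s}$ in sample $s$,

$$\mathrm{NSAF}_{i,s} =
  \frac{\mathrm{SpC}_{i,s}/L_i}{\sum_j \mathrm{SpC}_{j,s}/L_j},$$

so each sample column sums to 1. Length correction removes the advantage
long proteins have in accumulating spectra.

**Aggregation.** Protein counts aggregate to taxa by lineage: at the
requested rank when the lineage reaches it, otherwise at the deepest
available rank (this is what produces mixed Kingdom-through-Class tables).
Proteins without a lineage accumulate under `unassigned`, so taxon
aggregation conserves per-sample mass exactly — a tested invariant. GO
aggregation adds a protein's full count to *every* term it carries; term
totals are therefore term-attributable PSM totals, not spectrum totals, and
must not be summed across terms.

## Concordance between layers

Each layer is library-normalized (each column divided by its own total) and
averaged within a (day, treatment) condition. For temporal display the
first observed time point is set to 0 and each later point shows
$\Delta_n = r_n - r_{n-1}$ over consecutive observed days; the deltas
telescope, $\sum_n \Delta_n = r_{\text{last}} - r_{\text{first}}$, which is
asserted to $10^{-12}$ in the tests. A feature unobserved at a sampled day
gets ratio 0 — in count data, absence is informative; carrying the last
value forward would invent observations.

**Concordance regression.** Per condition, PSM ratios (y) are regressed on
read ratios (x) by ordinary least squares, pairing features by id and
zero-filling features missing from one layer. $R^2$ answers "how well do
PSMs correspond to reads here?". Two deliberate choices: OLS rather than
total least squares (the question is directional — predict activity from
presence); and ratios rather than per-interval deltas as the default
regressed quantity, with deltas available via `on = "delta"`, because the
ratio reading is the literal one and the delta reading is retained for
sensitivity analysis. A constant PSM profile is reported as $R^2 = 0$:
there is no variance a varying read profile could explain (reporting a
technically perfect flat fit as 1 would answer the wrong question).

**Activity bias.** Per taxon and condition,

$$b = \log_2\frac{q + \varepsilon}{p + \varepsilon},$$

with $p$ the read share, $q$ the PSM share and $\varepsilon = 10^{-6}$ a
pseudocount that keeps the ratio defined when a taxon is absent from one
layer; exactly equal shares return exactly 0. Positive $b$: more active
than presence predicts. The pseudocount only matters for shares near or
below $10^{-6}$, far below the detection level of either layer at realistic
library sizes.

**Presence/absence.** Counts pooled within a condition classify each taxon
as `both`, `metagenome_only` (present but not detectably active),
`metaproteome_only`, or `neither`. Missing cells in the input are parse
errors, never zeros — silent zero-fill would corrupt exactly this analysis.

## Diversity and community comparison

Shannon-Weaver $H = -\sum p_i \ln p_i$ (natural log by default, base
configurable) and Simpson reciprocal $1/D = 1/\sum p_i^2$ are computed per
library; both are invariant to library-size rescaling, so any
library-normalization convention upstream leaves them unchanged.

Community comparison uses Bray-Curtis dissimilarity
$d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ on the NSAF table (the
protein-level, length-corrected view of the metaproteome), followed by:

* **NMDS** — Kruskal stress-1 minimization with monotone regression
  (engine: `vegan::monoMDS`), wrapped with a deterministic classical-scaling
  start plus 19 seed-derived random restarts, keeping the lowest-stress
  solution; coordinates are centred, rotated to principal axes, and
  sign-fixed so a given seed always yields the same orientation.
  Zero-dissimilarity samples are collapsed before fitting and re-expanded
  to coincident coordinates, avoiding a degenerate monotone-regression
  step. Non-convergence sets a flag rather than raising.
* **ANOSIM** — re-implemented from its definition:
  all $M = n(n-1)/2$ pairwise dissimilarities are ranked (average ranks on
  ties) and $R = (\bar r_B - \bar r_W)/(M/2)$. The Monte-Carlo p-value uses
  the add-one convention $p = (1 + \#\{R^* \ge R\})/(1 + B)$, so $p = 0.001$
  is the floor at $B = 999$ — matching how permutation tests are
  conventionally reported. An exhaustive mode enumerates all $n!$
  labellings for small $n$; the test suite uses it as the oracle for the
  sampler, and checks the $R$ statistic against an independent
  implementation (vegan's). Null calibration (type-I error at
  $\alpha = 0.05$ within the binomial interval over 500 simulated null
  datasets) is part of the acceptance suite.

## Differential GO-term analysis

For two conditions (consecutive days within a treatment; the two treatments
within a day), each condition's samples are pooled by the arithmetic mean,
and each term is tested on its smoothed share of the pooled library: with
pseudocount $\lambda = 1$ (Laplace),

$$\tilde p_c = \frac{x_c + \lambda}{N_c + \lambda}, \qquad
  \text{effect} = \log_2 \tilde p_b - \log_2 \tilde p_a,$$

with a two-sided two-proportion z-test (pooled variance) on the smoothed
proportions and Benjamini-Hochberg correction within each comparison;
terms with $q \le 0.05$ are flagged. The reference web-service
implementation of this style of analysis is not reproducible bit-for-bit;
this package fixes a transparent test with the same decision rule
($q \le 0.05$), configurable $\lambda$ and $\alpha$, and verifies its
operating characteristics directly: null calibration and power for a
planted 2x shift are acceptance-tested rather than assumed. PSMs are not
propagated up the GO hierarchy before testing — a documented divergence
from DAG-aware tools. Only prokaryote-rooted lineages (Bacteria, Archaea)
enter by default, excluding host and feed-algae contamination. For each
significant term, the per-taxon share of its PSMs is reported per condition
(shares sum to 1).

## The synthetic-data generator

Because the deposited raw data require a cluster-scale annotation and
search pipeline, validation uses a generator that reproduces the
*statistical structure* the analysis assumes, with known ground truth:

* **Design**: 25 mixed Kingdom-through-Class taxa; 2 treatments x 4 days;
  one metagenome library per condition; 2 tanks per treatment per day in
  the proteome layer, each with 3 technical runs (16 biological samples,
  48 runs).
* **Trajectories**: per-taxon proportions are piecewise-constant over days
  with seeded bloom-like jumps (30% of taxa jump per step, log-scale SD
  0.5). Jumps are shared between treatments, with a small
  treatment-specific perturbation (log-scale SD 0.08), so community change
  is dominated by time and the treatment effect is weak — the structure the
  emulated experiment reported.
* **Coupling**: reads are multinomial at the read-layer proportions $p$;
  PSMs are multinomial at $q_t = p_t a_t / \sum_u p_u a_u$, where $a_t$ are
  per-taxon activity multipliers (default: Deltaproteobacteria 4;
  Alphaproteobacteria, Actinobacteria, Cyanobacteria 2; Betaproteobacteria
  0.4; Cytophagia 0.35; Gammaproteobacteria and Flavobacteriia 0.6; all
  others 1). $a_t \equiv 1$ makes the layers concordant by construction.
* **Within-taxon structure**: reads are drawn at protein-gene resolution
  with within-taxon weights $s_i$ (taxon margins remain exactly multinomial
  at $p$, and a GO-level read table falls out of the same draw); PSMs are
  apportioned to proteins proportional to $L_i s_i$, so NSAF's length
  correction recovers $s_i$. Each sample's PSM total is split multinomially
  across its technical runs.
* **Evidence scores**: well-supported proteins get probabilities in
  $[0.93, 1]$ and pooled unique peptides $\ge 2$; each taxon also carries
  two low-evidence proteins holding 2% of its expression, with probabilities
  and unique-peptide counts that mostly fail the filter. Real low-probability
  identifications are low-abundance, so this keeps the evidence filter
  approximately expression-neutral while giving it a nontrivial test
  surface.
* **Dropout**: designated taxa (default: three rare groups) are structural
  zeros in the proteome layer, exercising the presence/absence
  classification; dropout in the read layer is supported but off by
  default.

Default library sizes are $10^6$ reads per metagenome library and
$2 \times 10^4$ PSMs per proteomics sample — desk-scale stand-ins chosen so
multinomial sampling error sits well below the effect sizes of interest;
the recovery tests that need tighter Monte-Carlo error raise the PSM depth
to $10^6$. Sampling is multinomial, not Dirichlet-multinomial: real
libraries are overdispersed, but the multinomial keeps every oracle
closed-form ($q$ exactly computable, totals exactly conserved). What
passing tests therefore show is that the estimators are correct *under the
assumed sampling model*; they do not show robustness to overdispersion,
compositional zeros beyond the structural-dropout mechanism, or annotation
error, none of which the generator emulates.

With ~25 taxa the simulated Shannon index sits near 2.6 rather than the
~5 reported for datasets resolved into hundreds of finer-grained groups;
the index scales with $\ln k$, so this is a direct consequence of the
class-level feature space, not a calibration target.

## Numerical and design choices

* Ties in ANOSIM ranks use average ranks; permutation comparisons use a
  $10^{-12}$ slack so ties at the observed statistic count as "as extreme".
* `temporalDeltas` errors on duplicated days within a series rather than
  guessing an order.
* All-zero libraries, all-zero sample pairs (Bray-Curtis), zero-length
  proteins, conflicting length annotations and groups of size 1 (ANOSIM)
  are errors, not warnings.
* TSV output renders floats with 6 significant digits and whole numbers
  exactly; with a fixed seed the entire pipeline is byte-reproducible,
  which the acceptance suite checks with file checksums.
* Writing then reading a count table reproduces labels and counts exactly
  for raw (integer) counts and to rendering precision for averaged tables.
* Random number use is localized: every sampler takes a seed and restores
  the caller's RNG state, so results never depend on call order.

## Problem sizes used by the test and acceptance suites

Unit tests run on toy fixtures (tens of features). Property checks use:
500 simulated null datasets for ANOSIM calibration; 1,000 random series for
the telescoping identity; 20 paired simulations at $10^6$ reads and PSMs
for multiplier recovery (tolerance 0.1 on the recovered log2 bias); 200
datasets at totals $10^4$ for GO-test calibration and power. These sizes
were chosen so Monte-Carlo standard errors are several times smaller than
the asserted tolerances.

## Limitations

* The GO test treats terms independently; PSM multi-assignment induces
  positive dependence between overlapping terms, which BH tolerates but
  does not exploit.
* Activity bias is descriptive, not causal: protein detectability varies
  between taxa for reasons other than activity (extraction efficiency,
  database completeness).
* The generator does not simulate peptide sequences, spectra, annotation
  error, or overdispersed counts (a Dirichlet option is the natural
  extension).
* Concordance regressions zero-fill features absent from one layer; with
  many structural zeros the fit mixes detection and abundance effects.
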