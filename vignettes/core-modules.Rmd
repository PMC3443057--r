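---
title: "Identifying mutated core modules: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying mutated core modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Somatic driver mutations in cancer are individually rare: across a cohort,
the same pathway can be disabled in different patients through different
member genes, so no single gene recurs often enough to be distinguished from
passenger mutations by frequency alone. `coremod` operationalizes a
module-level view: a driver disrupts the functional module around it, the
disruption shows up as coordinated differential expression between two
pathological conditions, and that expression signal is *reproducible* in a
way single-gene statistics are not. Candidate driver-bearing modules ("core
modules") are therefore defined by the conjunction of two independent
pieces of evidence:

* the module ranks among the top *K* for a multi-gene differential
  expression statistic, and
* the module carries significantly more mutated genes than expected.

### Stage 1 — GO-constrained co-expression networks

Gene sets (GMT; curated GO-style collections) are intersected with the
genes measured on the platform; sets with fewer than `min_size` surviving
genes are dropped. Within each such *GO cluster*, only protein-interaction
edges with **both** endpoints in the cluster are retained — the inter-GO
cut. Multi-functional genes may appear in several clusters; clusters are
analysed independently. Each retained edge is weighted by
$S_{ij} = |\mathrm{cor}(x_i, x_j)|$ over **all** samples of the dataset
(both conditions pooled; Pearson by default, Spearman selectable). Pooling
is an assumption: the networks are built before, and independently of, the
condition comparison. Zero-variance genes make the correlation undefined;
such edges are floored at $10^{-6}$ rather than dropped, so the interaction
topology is preserved.

### Stage 2 — size-capped weighted Girvan–Newman partitioning

The divisive betweenness algorithm treats inter-module edges as traffic
bottlenecks. Our edge score is the classical *unweighted* shortest-path
edge betweenness divided by the edge's co-expression weight: weakly
co-expressed bridges are removed first. (The alternative reading —
Dijkstra betweenness on lengths $1/S_{ij}$ — is available via
`mode = "dijkstra"`.) After each removal all scores are recomputed. The
classical modularity-based stopping rule is deliberately **not** used;
instead any connected component that falls below `size_limit` (default 20)
genes is frozen as a module and excluded from further cutting, and
single-gene components are discarded. Components already under the cap are
emitted untouched. Ties in the betweenness score are broken toward the
lexicographically smallest (from, to) edge, which makes partitions fully
deterministic. The freeze-below-limit rule is our algorithmic reading of a
procedure described only loosely in the source method ("a size limit of
less than 20"); it guarantees every module has $2 \le |M| < 20$ genes and
that modules from one network are pairwise disjoint.

### Stage 3 — the module differential-expression statistic

Per gene, a two-sample Welch $t$ score is computed between the two
conditions (pooled-variance option available). Per module,
$\mathrm{SDS} = \sum_{i \in M} T_i^2$ is referred to the upper tail of
$\chi^2(n)$ with $n = |M|$, and modules are ranked by this p-value
ascending (ties: larger SDS, then module id). The top $K$ (default 100)
are the top-ranked modules (TRMs).

**Exact-null standardization.** The $\chi^2(n)$ reference assumes the
per-gene scores are standard normal under the null. A Welch $t$ with
$\nu$ degrees of freedom is only asymptotically normal; its square has mean
$\nu/(\nu-2) > 1$, so sums of squared raw $t$ scores are slightly
overdispersed and the module p-values are anticonservative. The effect is
small (sup-CDF distance $\approx 0.012$ at 50 samples per class) but
measurable: a Kolmogorov–Smirnov check on 2000 null modules rejected at
$\alpha = 0.01$ roughly 7× more often than nominal. The scoring pipeline
therefore maps each $t$ to its exact null quantile,
$z = \Phi^{-1}(F_{t_\nu}(T))$, before squaring (the same device as
`limma::zscoreT`). This is sign- and order-preserving, coincides with the
raw score asymptotically, and makes the stated $\chi^2(n)$ reference exact
at any sample size; with it the KS rejection rate returns to nominal. The
raw statistic remains available (`gene_t_scores(standardize = FALSE)`, the
function-level default) for exact comparability with the original method.

The single-gene comparator (TRGs) ranks genes by two-sided $t$-test
p-value; standardization does not change that ranking.

### Stage 4 — mutation enrichment and core modules

Each module is tested for excess mutated genes with a one-sided (greater)
Fisher exact test on the 2×2 table (in module vs not) × (mutated vs not).
The **universe** is the union of all GO-network genes of the dataset — the
genes that could have entered a module — rather than the whole genome; a
genome-wide universe would overstate enrichment for every module. The raw
$p \le 0.05$ cutoff defines mutated modules (MMs), uncorrected as is
conventional for this screen (a Benjamini–Hochberg option exists, off by
default). Core modules are MMs that are also TRMs. The MM-enrichment score
is (MM fraction among TRMs) / (MM fraction among non-TRMs).

## Downstream analyses

* **Reproducibility.** A split-half trial divides samples into two halves
  (stratified by class by default — unstratified splitting is a flag — the
  source protocol says only "randomly split"), runs the full pipeline
  through TRM selection on each half, and reports the Jaccard overlap of
  TRM genes plus a Fisher test of overlap significance against the gene
  universe. Label-permuted trials (TRM_P) and equally sized top-t-test
  gene lists (TRG) provide the two controls; the expected qualitative
  ordering on signal-bearing data is TRM > TRM_P > TRG.
* **Topology.** Density $\bar k/(N-1)$, centralization
  $\frac{N}{N-2}(\frac{\max k}{N-1} - \mathrm{density})$, heterogeneity
  $\mathrm{var}(k)/\bar k$ (population variance by default; the degree
  sequence is complete, not a sample), mean local clustering over nodes
  with degree ≥ 2 (the coefficient is undefined below that; the count of
  excluded nodes is reported), and closeness = 1 / (summed shortest-path
  distance) computed **within a node's connected component** — excluding,
  not infinitely penalizing, other components, the convention of standard
  network-analysis tooling. Isolated nodes get closeness 0.
* **N score.** Per mutated gene and cancer type: 1 if the gene appears in
  the core modules of all of that type's datasets, 1/2 if in exactly one
  of a two-dataset type, 0 otherwise, summed over types. Types with more
  than two datasets are rejected rather than guessed at. Genes whose
  observed N is not separated from its label-permutation null (one-sample
  Wilcoxon, $p < 0.01$) are "unstable"; stable genes split at $N > 1$ into
  general vs type-specific candidates, and a one-sided iterative Grubbs
  test ($\alpha = 0.05$, critical value from the $t$ closed form, removal
  capped at 20% of values — `ceiling`, so small cohorts can still flag
  one) marks the outliers.
* **Phylogeny.** Network relatedness between two mutated-gene networks is
  $R = N_0/N_1$: qualifying unordered node pairs across the two networks
  over qualifying pairs within their union, a pair qualifying when its
  shortest-path distance in the full reference interactome is ≤ the cutoff
  (0, 1 or 2; distance 0 ⇔ shared node). At the default cutoff 0 this is
  exactly the Jaccard index of the node sets. The source description
  ("count of the shortest path") is ambiguous between counting paths and
  counting node pairs; pair counting is adopted because it reduces cleanly
  to Jaccard at cutoff 0 and keeps $R \in [0,1]$, and this interpretation
  is recorded as ours, not as established fact. $D = 1 - R$ feeds standard
  Saitou–Nei neighbor joining (`ape::nj`); negative branch lengths are
  clamped to zero with the deficit moved to the sister branch.

## The synthetic world

`synthetic_spec()` describes everything the generator emits; its defaults
are fixed once and state a realistic desk-scale microarray study:

| parameter | default | why |
|---|---|---|
| `n_genes` | 4000 | measured genes that are also GO-annotated |
| `n_per_class` | 25 | cohort sizes of the motivating datasets (≈ 29 vs 26) |
| `n_noise_sets`, size ~ N(30, 5), min 10 | 200 | curated GO collections: hundreds of sets, tens of genes each |
| `n_planted`, `planted_size` | 5 × 8 | rare true modules among abundant noise |
| `delta` | 2 | log-scale condition shift in planted genes |
| `rho` | 0.6 | within-module co-expression (single latent factor, exact pairwise correlation) |
| `p_in` / `within_set_edge_p` / `background_edge_p` | 0.8 / 0.15 / 0.001 | dense planted modules; moderately wired gene sets; interactome-scale background (≈ 30k edges over 6.5k nodes) |
| `mutation_rate` × `mutation_multiplier` | 0.1 × 5 | mutation catalogs covering ~10% of network genes, 5× excess in planted modules |

Expression is multivariate normal (planted blocks get the latent factor and
the shift in condition B; background genes are i.i.d. standard normal);
mutations are per-gene Bernoulli, matching the per-condition *catalog*
format of the real inputs. The generator does **not** emulate probe-level
artifacts, batch effects, heavy-tailed noise, correlated background genes,
or annotation bias — so a green pipeline-recovery test establishes that the
machinery finds planted signal of the stated kind at the stated strength,
not that it is robust to microarray pathology. A planted module counts as
recovered when at least half of its genes land in a single core module
(partition boundaries legitimately absorb neighbours from the host set).
Multi-dataset layouts reuse one gene pool, gene-set collection and
interactome; each cancer type (1 or 2 datasets) owns private planted
modules, and designated type pairs share one, which is what makes the
neighbor-joining tree pair them.

## Numerical and degenerate-input choices

* Missing expression values: k-nearest-neighbour imputation (k = 10 by
  default, the cited imputer's convention), Euclidean distance on
  co-observed samples rescaled to the full sample count; genes missing
  everywhere are an error, ≥ 50% missing a warning.
* Probe collapsing: arithmetic mean per gene and sample; unmapped probes
  dropped. Case-sensitive symbols by default; upper-casing is opt-in.
* Zero-variance genes in both classes with equal means: $T = 0$ with a
  warning; with unequal means: ±∞ (the module containing them is maximally
  significant, which is the honest limit).
* `fisher_p` boundary cases: no module gene mutated, or every universe
  gene mutated, give p = 1.
* Ratios with empty denominators (`mm_enrichment_score`,
  `mutated_gene_fraction_ratio`, relatedness with an empty union) return
  `Inf`/`NaN`/`NA` markers with warnings instead of failing.
* All stochastic stages take explicit seeds; identical configuration and
  seeds reproduce every output byte-for-byte, and the run manifest records
  the configuration.

## Known limitations

* The betweenness recomputation loop is exact, not incremental; very large
  dense GO networks (hundreds of nodes) partition slowly. Real collections
  rarely produce such clusters after the inter-GO cut.
* The χ²(n) module reference ignores within-module correlation under the
  null as the original method does; co-expressed null modules are
  anticonservative by construction. The permutation controls, not the
  nominal p-values, carry the reproducibility claims.
* Relatedness path counting follows the pair-counting interpretation
  described above; results at cutoffs 1–2 are not comparable to a
  path-counting implementation.
* Acceptance-scale statements about reproducibility orderings are tested
  at reduced replicate counts (handfuls of split trials, 20 seeds) to stay
  inside a desk-scale compute budget; they are statements about means
  under the stated world.
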