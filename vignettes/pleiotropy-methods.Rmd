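---
title: "Methods: quantifying cross-domain gene pleiotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cross-domain gene pleiotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscope)
```

## The problem

Pleiotropy — one gene affecting several independent traits — can be counted
in two very different data domains. In the Mendelian-trait domain, a gene's
phenotype annotations (Human Phenotype Ontology for humans, Mammalian
Phenotype ontology for mice) are propagated to upper-level ontology terms
and counted. In the complex-trait domain, GWAS summary statistics yield
lead SNPs, each assigned to a gene, and the gene's count of associated
*trait clusters* is its degree of pleiotropy. pleioscope implements both
estimators, the NP/ST/MP/HP classification built on them, and the
downstream comparisons: bipartite network modularity, functional-feature
contrasts, selection-signal aggregation and gene-set enrichment. Because
the real resources (HPO, MGD, pan-UKB, FinnGen, GTEx, gnomAD, selection
scans) are large external downloads, the package ships a synthetic-data
generator that emulates their statistical structure with planted ground
truth; every pipeline stage is validated against what was planted.

## Degree of pleiotropy in ontology data

An annotation to term $t$ counts toward every upper-level term (direct
child of the ontology root) reachable from $t$ through `is_a` edges,
reflexively: an annotation *to* an upper-level term counts as that term.
When an explicit upper-level mapping table is supplied it takes precedence
over DAG traversal, matching the official term mappings distributed with
the MP ontology. The mortality/aging term `MP:0010768` is excluded *after*
propagation by default because of its strong annotation bias; the excluded
set is a parameter. The degree of pleiotropy is the size of the resulting
upper-level term set; genes in the universe without annotations get degree
0. Cross-ontology translation (HPO terms to MP) is consumed as a provided
translation table, never computed — no published algorithm exists for it —
and raw pre-propagation term counts are reported alongside
(`n_raw_terms`) so both scales are visible.

## NP/ST/MP/HP classes

Genes split into: NP (degree 0), ST (degree 1), HP (degree at or above the
cutoff) and MP (the rest). The cutoff is the smallest integer at or above
the 75th percentile (linear-interpolation quantile) of degrees among genes
with degree $\ge 1$, floored at 2. Two choices here were genuinely open:

* **Quartile universe.** The percentile is computed over annotated genes
  only. Including the degree-0 mass would drag the cutoff to 0–1 in sparse
  GWAS datasets, where most genes have no association, making HP
  meaningless.
* **Cutoff inclusivity.** HP means degree $\ge$ cutoff (configurable).
  With sparse GWAS degrees the cutoff can equal 2, leaving MP empty; the
  degenerate partition is permitted and reported rather than hidden.

## GWAS trait processing

Traits pass a heritability filter (z-score of the $h^2$ estimate strictly
above 2.32, i.e. $P(h^2{=}0) < 0.01$); duplicate encodings of one trait
keep the maximum-heritability entry. Lead SNPs come from a greedy
distance-window clump: repeatedly take the smallest-p variant at
$p \le 5\times10^{-8}$ and remove everything within 250 kb on the same
chromosome. This replaces LD-based clumping, which needs a genotype
reference panel; an optional per-chromosome $r^2$ matrix reinstates
LD-aware removal ($r^2 \ge 0.1$). Each lead is assigned the closest gene
(distance 0 inside the interval, otherwise the nearer interval endpoint;
ties resolve to the lexicographically smaller gene id for determinism), or
alternatively all genes within a 100 kb window.

Trait similarity is the *reconstituted phenotypic correlation* $r_p$: the
Pearson correlation of $z = \beta/\mathrm{se}$ over shared null variants.
A variant counts as null when $|z| < 4$ in both traits. The conventional
threshold for "null" in correlation-from-summary-statistics estimators is
2, but truncating a bivariate normal at $\pm 2$ attenuates the estimate
severely (a true $\rho = 0.8$ measures as about 0.74, $\rho = 0.6$ as
0.52); at $\pm 4$ the attenuation is below 0.001 while genuinely
associated variants (the planted leads have $|z| \approx 12$) are still
excluded. The threshold is a parameter for users who prefer the stricter
convention. Traits are clustered by average-linkage agglomeration on
$d = 1 - r_p$ with the tree cut at $d = 0.8$; missing $r_p$ (too few
shared variants, floor 50) imputes $d = 1$. Linkage and cut height are
explicit configuration knobs — no published values exist for them — and a
precomputed correlation matrix can be supplied to bypass estimation
entirely. A gene is associated with a cluster when it is the assigned gene
for a lead SNP in at least one trait of the cluster; row sums of the
binary gene-by-cluster matrix are the GWAS degrees.

## Network modularity

The gene-by-cluster (or gene-by-term) matrix becomes a bipartite graph,
one edge per nonzero entry; isolated declared nodes are dropped with a
logged count, since they cannot influence edge-based modularity.
Modularity is the standard Newman–Girvan
$Q = \sum_c \left( e_c/m - (d_c/2m)^2 \right)$ on the graph treated as
undirected (the bipartite-specific variant of Barber would change the null
model; the general formula matches the general-purpose community toolkits
used in this field). Communities come from agglomerative greedy
maximization — merge the community pair with the largest
$\Delta Q = e_{ab}/m - d_a d_b / 2m^2$ while any merge strictly improves
$Q$, ties broken by the smallest community-index pair — followed by a
deterministic single-node reassignment sweep alternated with further
merges until $Q$ stops improving. The sweep exists because plain
agglomeration is known to stall in shallow local optima on small dense
graphs; on bipartite motifs of up to 8 nodes the refined greedy matches
the exhaustive optimum in the test suite. It remains a heuristic: on dense
unstructured graphs (e.g. Erdős–Rényi bipartite at density 0.5) it can
still terminate below the global maximum, a basin shared by the standard
fast-greedy implementations.

The null model preserves both degree sequences exactly: checkerboard
swaps pick two edges $(g_1,t_1), (g_2,t_2)$ with $(g_1,t_2)$ and
$(g_2,t_1)$ absent and swap them; $10\,|E|$ attempted swaps per shuffle,
100 shuffles, empirical
$p = (1 + \#\{Q_\text{null} \ge Q_\text{obs}\}) / (1 + 100)$. The swap
count and the mandatory seed are reproducibility choices; the shuffle
returns its input with a warning when no valid swap exists (complete
bipartite graphs).

## Functional features and selection signals

Expression breadth counts tissues at **five or more** TPM (boundary
inclusive); group contrasts use the two-sided Wilcoxon–Mann–Whitney test
with Benjamini–Hochberg adjustment over all class pairs and features
requested in one call (one BH family per invocation — the family
composition is echoed in the output). Proportions (e.g. pLI strictly
above 0.9) use the 2×2 chi-squared test without continuity correction
(large-sample counts; correction configurable, Fisher fallback on
zero-margin tables) and Wilson 95% intervals.

Per-SNP selection scores aggregate to genes as $n$ (SNPs in the interval)
and $x$ (maximum absolute score). Significance of a maximum iHS is
$p(x\,|\,n) = 1 - \Phi(x)^n$, computed in log space as
$-\mathrm{expm1}(n \log \Phi(x))$ for stability at large $n$. The formula
treats each SNP's iHS as standard normal; because $x$ is a maximum of
*absolute* values, the folded-normal variant $1 - (2\Phi(x)-1)^n$ is the
statistically stricter choice and is available via `folded = TRUE`, but
the plain-CDF form is the default as the field's printed convention. Genes
with $n = 0$ carry no evidence and are excluded from the BH family rather
than assigned $p = 1$ (their count is reported); BH is applied per dataset
per run. Hard cutoffs are strict: $|iHS| > 4$, DRC150 $> 0.0025$, and the
combined constraint-plus-sweep flag requires LOEUF strictly below 0.6 and
BH-adjusted $p < 0.05$.

Length-matched enrichment guards against gene length confounding both the
flags (longer genes harbor more SNPs, hence larger maxima) and the target
set: the universe is split into 10 length-quantile bins and each of the
random draws matches the target's bin histogram exactly, sampling without
replacement within bins. Length is the gene interval's `end - start`; in
locus mode every locus has the same length ($2 \times$ flank), so matching
is only meaningful in gene mode.

## Gene sets

Over-representation of HP genes is the upper-tail hypergeometric test
against the analysis universe with BH across the collection — the discrete
HP gene list makes ranked enrichment unnecessary. The non-redundant
pathway selection follows the published greedy procedure: order by
residual gene count, take the largest, remove its genes everywhere, and
repeat while any *residual* set still has strictly more than 25 genes
(the filter applies to post-removal sizes — the procedure is defined on
"the remaining genes"). Ranking across datasets uses the minimum HP
fraction per set; the >500-gene size filter counts genes after
intersecting each set with the dataset's universe, and a set must pass it
in every dataset it is ranked over (sets missing from a dataset are
dropped with a log message).

## The synthetic-data generator

`sim_config()` fixes the study conditions; every generator is
deterministic under the seed. Defaults, and what they emulate:

| parameter | default | emulates |
|---|---|---|
| `n_genes`, `n_upper`, `n_leaves` | 1000, 12, 60 | genome-scale gene set over a 3-level ontology with diamonds |
| `exponent` | 2.5 | the left-skewed (L-shaped) degree distribution; truncated discrete power law on $1..U$ |
| `np_fraction` | 0.30 | unannotated gene mass, mid-range between the sparse GWAS (~60%) and dense ontology (~6–12%) domains |
| `n_traits`, `n_blocks` | 24, 4 | trait panel with block-correlated z-scores |
| `rho_within`, `rho_between` | 0.8, 0.1 | strong within-block, weak between-block phenotypic correlation |
| `n_snps` | 10 000 | shared null variants per trait, enough for $r_p$ to converge within ±0.05 |
| `causal_per_block`, `n_domains`, `pool_factor` | 8, 2, 0.75 | blocks share undersized causal pools within a domain, never across — this yields a skewed cluster-degree distribution (most causal genes hit one cluster) and plants modular bipartite structure |
| `sweep_fraction`, `delta` | 0.05, 3 | recent selective sweeps: SNPs inside sweep genes get $|iHS|$ shifted by $\delta$, DRC150 pushed over 0.0025 |
| `feature_slope`, `feature_sd` | 1.5, 1 | features increase (LOEUF decreases) in $\log(1+\text{degree})$; slope 0 switches all effects off |
| genome | 2 chromosomes, genes 2–10 kb, gaps 2–10 kb, track SNP every ~500 bp | a toy coordinate system that still exercises every interval code path |

Annotations realize each gene's planted degree *exactly*: the gene is
annotated to its chosen upper-level terms directly plus leaf terms whose
ancestor sets stay inside the chosen set, so propagation recovers the
planted degree with no tolerance. Planted GWAS leads sit inside their
causal gene with $|z| \approx 12$, far past the clumping threshold.

What the generator does **not** emulate: linkage disequilibrium (variants
are independent, so distance-window clumping is exact here in a way it is
not on real data), ascertainment bias in ontology annotation depth,
overlapping genes and isoforms, population structure in the selection
scans, and correlated noise between features. Passing tests therefore
demonstrate the estimators' correctness and calibration under clean
planted structure, not robustness to those real-data pathologies.

## Numerical and procedural choices

* Coordinates: BED intervals 0-based half-open, SNP positions 1-based;
  `bed_to_point()` is the single conversion utility.
* All tie-breaks (equal p, equal distance, equal residual size, equal
  $\Delta Q$) are lexicographic / smallest-index, making every stage
  deterministic under a seed.
* Quantiles use R's default linear-interpolation type 7.
* The modularity permutation and length-matched draws take mandatory
  seeds; stage generators derive per-stage seeds as small fixed offsets
  from the master seed (kept well below $2^{31}$).
* Degenerate inputs: all-zero incidence matrices, empty annotation files,
  sub-4-gene positive-degree sets, and non-symmetric distance matrices are
  hard errors; degenerate comparison groups are skipped with a log.

## Problem sizes

The test suite and the acceptance script run the pipeline end-to-end at
1000 genes / 24 traits / 10⁴ variants for the estimation checks and
200–400 genes for the repeated (multi-seed) power and determinism checks;
the Monte-Carlo oracle for $p(x\,|\,n)$ uses $10^6$ draws. These sizes
were chosen so each statistical property is measured with comfortable
margin (e.g. MC standard errors an order of magnitude below the tested
differences) while the whole suite stays fast enough to run routinely.

## Known limitations

* Greedy modularity is a heuristic (see above); exact optima are only
  guaranteed where the tests enumerate partitions exhaustively.
* $p(x\,|\,n)$ assumes independent standard-normal scores; with real LD
  the effective $n$ is smaller and the default (unfolded) formula is
  anticonservative for maxima of absolute values. The folded variant and
  the empirical length-matched test are the built-in mitigations.
* Distance-window clumping without an LD matrix can split one association
  locus into several leads on real data.
* The >25 and >500 gene-set filters and the trait-cluster cut height are
  conventions, not estimated quantities; conclusions that depend on them
  should be checked across a range (all are parameters).
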