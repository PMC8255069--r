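---
title: "Methods: co-expression modules and association rules for gene function prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules and association rules for gene function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexrules)
```

`coexrules` implements a guilt-by-association workflow for bulk RNA-seq
count matrices: genes are screened for differential expression, organised
into weighted co-expression modules, summarised with network centralities,
binarised into over/under-expression transactions, mined for association
rules, and finally unannotated genes are assigned a putative category from
the annotated genes they co-mine with. The motivating application is insect
chemosensation — small antennal RNA-seq designs (three treatments ×
three replicates) in which uncharacterised genes consistently co-expressed
with odorant receptors, gustatory receptors, ionotropic receptors and
odorant-binding proteins are flagged as candidate chemosensory genes.

This vignette records the models, the defaults and the design decisions a
maintainer would want to know, in the order the pipeline runs them.

## The synthetic count model

Real antennal data cannot be bundled, so every stage is validated against
`simulate_counts()`, which emits a count matrix plus the ground truth that
generated it. The model is deliberately the simplest one that gives every
downstream stage something recoverable:

* Per-gene baselines are log-normal: `log mu_g ~ N(baseline_log_mean,
  baseline_log_sd^2)` (defaults `log(150)`, 1 — desk-scale depth, not a
  sequencing-run depth).
* Biological variation is a per-gene, per-sample Gaussian `z` on the
  natural-log scale with standard deviation `bio_log_sd` (default 1).
* Each planted module shares a latent factor across samples. Gene `g` in a
  module has loading `lambda_g = sqrt(within_module_cor) * u_g` with
  `u_g ~ U(0.9, 1.1)` (capped at 0.995), and
  `z_g = lambda_g f + sqrt(1 - lambda_g^2) e_g`. The factor `f` is
  standardised across samples so the realised within-module correlation
  tracks the target rather than the factor's sampled variance; the loading
  spread makes connectivities vary smoothly across module genes instead of
  producing a spike in the degree distribution.
* Differentially expressed genes get their mean multiplied by
  `2^de_log2fc` (random sign) in the attractant samples.
* Planted co-regulated ("rule") groups follow a shared on/off profile:
  `ceiling(n_samples / 2)` randomly chosen "on" samples sit
  `2^rule_group_log2fc` above baseline with only mild noise. The on-block
  size matches the upper bin of a two-bin equal-frequency split, so the
  whole group binarises to 1 in the same samples — the structure rule
  mining is supposed to find.
* Per-sample library-size factors are log-normal (`sd` 0.1), and counts
  are drawn negative-binomially with dispersion `nb_dispersion`
  (variance `mu + phi mu^2`; default `phi = 0.05`).

What the generator does *not* emulate: read-level artefacts (mapping,
rRNA contamination), count–dispersion trends, outlier samples, batch
effects, or correlated module factors. Tests passing on this generator
demonstrate that the algorithms recover the structure they were designed
for; they are not evidence about messier real data.

For module-recovery experiments the simulations use a deeper, cleaner
setting (`baseline_log_mean = log(500)`, `nb_dispersion = 0.02`): with a
within-module correlation target of 0.7, technical noise must stay small
relative to the unit biological variance or the realised count-scale
correlation drifts well below its target (negative-binomial noise adds
`phi + 1/mu` to the log-scale variance, attenuating correlations by
roughly `1 / (1 + phi + 1/mu)`).

## Filtering, normalisation and the differential-expression stand-in

Genes with counts below 10 in *more than* 90% of samples are removed
(`filter_low_counts()`; the 90% boundary itself is kept, and the filter is
idempotent). Normalisation is median-of-ratios: sample factor `s_j` is the
median over genes with positive geometric mean of `c_gj / gm_g`
(`size_factors()`). Expression for everything downstream is
`log2(c_gj / s_j + 1)`.

The DE engine is an intentionally simple stand-in, not a reimplementation
of a negative-binomial GLM with dispersion shrinkage: the log2 fold change
is the ratio of group mean normalised counts with pseudocount 0.5, and the
p-value is a two-sample Welch t-test on `log2(norm + 1)` (pseudocount 1),
adjusted by Benjamini–Hochberg (`stats::p.adjust`, cross-checked in the
tests against the step-up definition). Selection is strict on the FDR
(`p_adjusted < 0.05`) and inclusive on the fold change
(`|log2FC| >= log2(2)`). This is adequate for pipeline semantics and
parameter recovery on synthetic data — everything downstream consumes only
the selected gene set — but it has less power and different error
behaviour than a count-model test on real data. Genes with zero variance
in both groups get p = 1 when the group means agree (and 0 otherwise);
all-zero genes report a fold change of 0.

## Weighted co-expression

The network is unsigned: similarity `s_ij = |cor(x_i, x_j)|` (Pearson;
constant genes are dropped with a warning rather than propagating `NaN`),
adjacency `a_ij = s_ij^beta`. The scale-free fit index bins connectivity
`k_i = sum_j a_ij` into 10 equal-width bins *on the raw k scale*,
regresses `log10 p(k)` on `log10 mean(k)` per bin, and returns
`-sign(slope) R^2`. Binning on the raw scale (rather than on `log k`)
matters in practice: at high powers most genes have near-zero
connectivity, and log-scale bins isolate that mass so completely that the
regression never fits well, which destabilises power selection.
`pick_soft_threshold()` returns the smallest power in 1..20 whose fit
reaches 0.8, falling back to the best-fitting power, and always returns
the full table for audit.

Topological overlap is the standard unsigned form with self-adjacency
removed,

$$\mathrm{TOM}_{ij} = \frac{\sum_{u} a_{iu}a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}},$$

with unit diagonal, and `1 - TOM` is the clustering dissimilarity for
average-linkage hierarchical clustering (`stats::hclust`).

### Module detection

Module detection is a height-scanning static cut (`cut_modules()`): static
cuts are evaluated at every merge height up to
`cut_height_quantile * max(height)` (default 0.99) and the *lowest* cut
producing the largest number of branches with at least `min_module_size`
(default 30) genes wins. A single fixed near-maximal cut is unreliable on
small-sample data: correlation noise makes unrelated genes chain together
just below the top of the dendrogram, so any one height either swallows
the background into giant mixed clusters or shreds the modules. Scanning
finds the regime where the tight module branches exist and leaves the
chaining regime above the cut. A tree whose merge heights are all equal
(no structure) is treated as one candidate module.

Two standard refinements follow. `merge_close_modules()` merges modules
whose eigengene dissimilarity `1 - cor(ME_i, ME_j)` is below 0.25
(closest pair first, eigengenes recomputed after each merge; idempotent at
a fixed cut). `assign_by_membership()` then lets unassigned genes join the
module with their highest absolute eigengene correlation (kME) when it
reaches 0.6, iterating until stable. The 0.6 default keeps background
genes out (for 20 samples, a null correlation exceeds 0.6 in absolute
value only a few percent of the time per module) while re-capturing module
genes trimmed off the branch cores by the cut.

Eigengenes are the first right-singular vector of the row-standardised
module submatrix, signed to correlate positively with the module's mean
profile; when that mean is exactly zero (perfectly anticorrelated genes)
the sign is anchored on the first sizeable component so the output stays
deterministic. Module labels are size-ranked integers with the
conventional colour aliases (1 = turquoise, 2 = blue, 3 = brown, ...).

Under the recovery conditions used in the tests (four planted 50-gene
modules, 300 background genes, 20 samples, correlation target 0.7, power
chosen by `pick_soft_threshold()`), the full stage reaches a mean adjusted
Rand index of about 0.85–0.93 against the planted labels over ten seeds.

## Network metrics

`build_network()` thresholds TOM (or adjacency) weights at 0.2 by default
— the matrices-to-graph step is otherwise underdetermined, so the
threshold is exposed and the edge list/GraphML exports let users match any
external viewer. Centralities (`centrality_table()`, computed via igraph)
use unweighted shortest paths by default, matching common network-analyzer
behaviour; a weighted option (`1/weight` as length) exists behind a flag.
Betweenness is normalised by `(n-1)(n-2)/2`; closeness is
`(reachable - 1) / sum(distance)` per connected component with isolated
nodes at 0; the clustering coefficient is neighbourhood edge density with
nodes of degree < 2 at 0. All three are cross-checked in the tests against
a brute-force oracle that counts shortest paths by matrix powers.
`filter_by_degree()` is single-pass by default (degrees computed once on
the input graph, matching the plain reading of "filter out genes with
degree below 5"); the iterative k-core variant is a flag. `hub_table()`
ranks by degree, then betweenness, then gene id, with the hub threshold a
parameter (default 8).

## Equal-frequency discretisation

`equal_frequency_bins()` implements the five-step procedure: sort, split
into `k` contiguous groups with sizes differing by at most one, and place
each boundary at the midpoint between the maximum of one group and the
minimum of the next. Two conventions had to be fixed where the procedure
is underdetermined:

* When `n mod k != 0` the extra elements go to the **upper** bins. With
  nine samples and two bins this gives every gene five over-expressed
  samples, so a single item can reach support 5/9 >= 0.5 — the convention
  under which mining at support 0.5 on a nine-sample design can produce
  rules at all (the opposite convention caps every item at 4/9).
* Tie blocks that would straddle a boundary are absorbed into the lower
  bin and later cut points shift; if the ties exhaust the remaining
  values, the gene has no valid `k`-bin split and is dropped with a
  warning.

The procedure depends only on ranks, so any strictly increasing transform
of a gene's values yields identical labels. With `k = 2`, label 1 means
over-expressed; transactions are the per-sample sets of over-expressed
genes (under-expression is absence, as in market-basket analysis).

## Association rule mining

`apriori()` is a from-scratch level-wise miner: frequent single items,
then candidates joined from frequent `k`-itemsets sharing a
`(k-1)`-prefix and pruned unless every `k`-subset is frequent. Support is
thresholded on exact transaction counts
(`count >= ceiling(min_support * |D|)`), avoiding floating-point wobble at
thresholds like 0.5. The default maximum itemset size is 5 (four
antecedent items plus one consequent), configurable. `generate_rules()`
emits `X => Z\X` for every frequent `Z` and non-empty proper subset `X`
when `supp(Z)/supp(X)` reaches the confidence threshold, with lift
`confidence / supp(Y)`; rules are ordered by lift, support, then text, so
outputs are diffable. `filter_rules()` keeps `lift >= 2` (inclusive).

### A hard bound worth knowing

The default thresholds interact arithmetically: since
`lift = confidence / supp(Y) <= 1 / supp(Y)` and
`supp(Y) >= supp(X ∪ Y)`, any rule with support at least 0.5 has lift at
most 2, with equality only when the rule support is *exactly* 0.5 and
confidence is 1. On an odd number of transactions support exactly 0.5 is
unattainable, so **no rule on a nine-sample design can satisfy support
>= 0.5 and lift >= 2 simultaneously**; the best achievable is support
5/9, confidence 1, lift 1.8. The pipeline therefore reproduces the
pre-lift mining behaviour on nine samples (perfectly co-binarised groups
yield confidence-1 rules), and the lift filter at 2 then empties the rule
set. The thresholds are all exposed as parameters; with nine samples a
lift threshold of 1.8 or below (or an even sample count) is required for
any rule to survive. The acceptance suite asserts the joint-threshold
behaviour as specified and documents the failure rather than loosening
either threshold.

## Function prediction

`predict_functions()` formalises guilt-by-association as majority voting:
antecedent and consequent membership count symmetrically; for each
unannotated gene in any (lift-filtered) rule, each annotated partner
counts once per rule; the predicted category is the majority, ties are
reported as ambiguous with all tied categories listed, and genes whose
rules contain no annotated partner are excluded. There is no probabilistic
confidence score — the evidence reported is the partner and rule counts,
which make every prediction re-derivable from its supporting rules.

## Determinism and numerics

All simulation functions take explicit seeds and use an isolated RNG
stream (`withr::with_seed`); the analysis stages are deterministic given
their inputs, and `run_pipeline()` writes byte-identical artifacts on
reruns (the manifest records parameters, input checksum and per-stage
record counts, and deliberately no timestamp). Threshold comparisons that
the procedures define as inclusive (`lift >= 2`, confidence, support
counts) are guarded with 1e-9..1e-12 epsilons; the BH step is `stats::p.adjust`;
eigengene signs are fixed as described above. Validation problem sizes —
500-gene/20-sample recovery runs, 100-database mining oracles, 50 random
graphs up to 30 nodes, 200 null replicates — were chosen so the whole
suite runs in about a minute on one CPU while keeping Monte-Carlo margins
comfortable.

## Known limitations

* The DE stand-in is not a count-model test; on real overdispersed data
  its p-values are only approximate.
* The static height-scanning cut with kME assignment approximates, but is
  not, the adaptive hybrid tree-cut algorithm; extremely unbalanced or
  nested module structures will favour the latter.
* The unsigned network cannot distinguish activation from repression;
  signed variants are out of scope.
* Rule mining on nine samples supports only coarse support values
  (multiples of 1/9); see the lift bound above before tightening
  thresholds.
* Guilt-by-association transfers co-regulation, not mechanism; the
  predicted categories are hypotheses for bench validation, not
  annotations.
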