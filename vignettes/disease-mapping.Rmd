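---
title: "Consensus disease maps from multi-dimensional association data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus disease maps from multi-dimensional association data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diseaseMapper)
```

## The problem

Diseases are conventionally grouped by the affected organ system and by broad
etiological categories, which hides mechanistic relationships between
phenotypically unrelated conditions. `diseaseMapper` instead maps
disease-to-disease similarity from several *data dimensions*: bipartite
association layers linking diseases to genes, pathways, medicating drugs,
symptoms, and chemical exposures. Each layer carries a different and partly
complementary signal; the package's job is to turn the layers into one robust
consensus distance map and to interrogate that map (clusters, embeddings,
enriched features, neighborhoods, comparison to the ICD-10 coding hierarchy).

## The model and the procedure

**Input representation.** Every dimension is an unweighted bipartite edge
list, converted to a binary incidence matrix (diseases in rows, features in
columns, lexicographic order everywhere so tie-breaking is deterministic).
Two preprocessing steps reduce the noise that uneven research coverage
creates: per dimension, diseases whose feature count falls strictly below the
first quartile (type-7 quantile) of the per-disease count distribution are
removed, and the analysis set is then the intersection of the disease sets of
all dimensions, optionally restricted to diseases that have a display name.
Quartile ties are retained; the coverage summary (Q1/median/mean/Q3) is
reported on the pre-filter counts, which is the interpretation we adopt for
the summary table since the quartile itself must be computed on the
unfiltered distribution.

**Six metrics per dimension.** Pairwise disease distances are computed under
six metrics on the binary feature profiles: Euclidean and Hamming (raw counts
of differing features, each matrix then divided by its own maximum so the
largest entry is exactly 1; an all-identical matrix stays all-zero rather
than dividing 0/0), and four similarity coefficients converted to distances
as `1 - s`: cosine on binary vectors (`|A∩B|/sqrt(|A||B|)`, the Ochiai
coefficient), Jaccard (`|A∩B|/|A∪B|`), Sørensen–Dice (`2|A∩B|/(|A|+|B|)`)
and overlap (`|A∩B|/min(|A|,|B|)`). Since
`overlap ≥ dice ≥ jaccard` as similarities, the induced distances order the
other way — a property the test suite checks on random set pairs. On binary
data the raw Euclidean value is exactly the square root of the Hamming
count.

**Ipsen–Mikhailov (IM) distance.** To decide *how* to fuse a family of
distance matrices, their mutual IM spectral distances are computed. Each
matrix is read as a weighted graph adjacency; the Laplacian
`L = diag(rowSums) - W` has eigenvalues `λ_i` whose square roots are the
vibrational frequencies `ω_i` (the trivial zero mode is dropped; additional
zero modes of disconnected graphs are kept). The spectral density is a sum of
Lorentzians of half-width `γ`,

$$\rho(\omega) = K \sum_i \frac{\gamma}{(\omega-\omega_i)^2 + \gamma^2},$$

with `K` computed in closed form so that the density integrates to 1 on
`[0, ∞)` (each term integrates to `π/2 + atan(ω_i/γ)`). The distance between
two matrices is the L2 norm of the density difference. `γ` is calibrated per
disease-set size `n` so that the distance between the empty and the complete
graph equals exactly 1; the calibration exploits the closed-form endpoint
spectra (all zeros vs. `n−1` frequencies at `√n`), needs no
eigendecomposition, and is unique because the distance is strictly
decreasing in `γ`. One calibrated `γ` is reused for every pairwise
comparison within a family.

**Stepwise consensus.** The family of matrices (six metrics within a
dimension, or the six dimension-level matrices) is clustered by ward.D2 on
the IM distances, and the matrices are then averaged *along the dendrogram*:
at every internal node the two child matrices are averaged elementwise with
weight 1/2 each. The root is the consensus. We formalize "averaging
according to branching points" as this unweighted pairwise mean (not a
leaf-count-weighted mean): the arithmetic mean of the two branches is the
literal reading, and the resulting unequal effective leaf weights
(`2^-depth`, summing to 1) are surfaced in the consensus object's provenance
so the convex combination is fully auditable. A consequence worth knowing:
a family member that joins the dendrogram last (an outlier layer) receives
effective weight 1/2 — late mergers are *up*-weighted, not down-weighted.
Every consensus entry is therefore a convex combination of the input
entries, which bounds it by the elementwise min/max envelope and makes the
reconstruction from recorded weights exact to machine precision.

**Clustering, model selection, embedding.** Diseases are clustered on the
final consensus map with ward.D2 (distances are not pre-squared; the squares
live inside the Lance–Williams recurrence, which is the `ward.D2`
convention). The tree is cut into `k = 2 … 250` clusters (capped at `n−1`)
and the Dunn index — minimum between-cluster distance over maximum cluster
diameter — is computed per cut. Local maxima are flagged plateau-aware: a
maximal run of equal values strictly above both neighbors; boundary runs do
not qualify. The suggested `k` is the smallest `k` of the first flagged run,
i.e. the most parsimonious clustering that is locally optimal; because the
Dunn curve typically increases with `k` overall, this choice is a reported
suggestion and is always user-overridable. For visualization, classical
(Torgerson) MDS embeds the map in 2-D; negative eigenvalues, which occur
because consensus distances need not be Euclidean-embeddable, are clipped
with a warning. Cluster-level plots should slice rows from the full-map
embedding rather than re-embed subsets, so coordinates remain comparable.

**Enrichment and queries.** Features that characterize a cluster are found
by one-vs-all Fisher exact tests on the 2×2 table (associated / not) ×
(in cluster / out of cluster), one-sided toward over-representation, with
Bonferroni correction by (number of clusters) × (number of features tested
in that dimension) and a 0.05 significance threshold. Direct pairwise
cluster contrasts and two-sided group-vs-group contrasts (e.g. cancer vs.
non-cancer clusters) use the same exact machinery; pairwise contrasts are
reported at the nominal level, with the correction available separately.
The sample odds ratio uses a Haldane 0.5 correction only when a zero cell
occurs, and the correction is flagged in the output. Disease-centric
queries return top-k neighborhoods (lexicographic tie-breaking, ties at the
cutoff flagged), features shared exclusively by a disease pair after
subtracting the feature sets of excluded diseases, and feature rarity
counts over a dimension's full filtered disease universe.

**ICD-10 comparison.** Disease relatedness under the ICD-10 coding system is
modeled by a level similarity: codes share level 1 if the chapter letter
matches, level 2 if the 3-character category matches, level 3 if the full
subcategory matches; similarity is the deepest shared level divided by 3 and
distance is `1 − s`. The published weighting this stands in for is not
reproduced in our sources, so the rule is deliberately isolated behind
`icd10Similarity()` where a different variant can be dropped in. The ICD
matrix joins the dimension matrices in an IM family comparison after all
matrices are restricted to the mapped diseases. One structural caveat the
package documents and tests rather than hides: the IM distance depends only
on the Laplacian *spectrum*, so it is invariant under relabeling the
diseases — permuting which disease carries which code leaves the IM value
unchanged. The ICD comparison therefore measures whether the *shape* of the
coding-derived map differs from the data-driven maps, not whether individual
diseases sit in matching positions.

## The synthetic-data generator

Real disease–feature layers cannot be redistributed with the package, so the
generator plants the statistical structure the method assumes and lets every
stage be validated end to end:

* `nClusters` disease groups; within a group, each namespace's signature
  feature pool is linked with probability `pIn` (default 0.9), everything
  else with `pOut` (default 0.05) scaled by a power-law popularity weight
  (`rank^-1`, normalized to mean 1, capped at probability 1), which creates
  hub features linked to most diseases next to a long tail of rare ones;
* per-dimension disease dropout (`coverage`, default 0.9) so the six layers
  overlap only partially, as real layers do;
* a pathway layer derived deterministically from the gene layer (a disease
  links a pathway iff it links at least one member gene), reproducing the
  redundancy between gene- and pathway-level views;
* defaults of 60 diseases and 3 clusters — small enough that the whole
  pipeline runs in seconds, large enough that the planted partition is
  recoverable only by actually combining the layers.

What the generator does **not** emulate: real nosology, calibrated degree
distributions of curated databases, weighted or directional associations,
and correlated dropout (in real data, missingness concentrates on poorly
studied diseases rather than being uniform). Passing the recovery tests
therefore demonstrates the pipeline's correctness and internal consistency,
not the biological validity of any particular real-data map. In the
degenerate regime (`pIn = 1`, `pOut = 0`, full coverage) within-cluster
Jaccard distances are exactly 0 and between-cluster distances exactly 1,
which pins down the construction.

Publication-count tables for the correlation reports are simulated through a
Gaussian copula: the latent Pearson correlation `2 sin(πs/6)` yields a
Spearman correlation of approximately `s` against the association degrees,
exactly 1 when `s = 1` (the counts are then a monotone transform of the
degrees with the same tie pattern).

## Numerical choices

* **Quadrature.** IM distances integrate the squared density difference on
  `[0, max ω + 10γ]` by adaptive quadrature (absolute tolerance 1e-8, 2000
  subdivisions) with a 20,001-point trapezoid fallback; the normalization
  constant is always analytic. Calibration solves for `γ` by `uniroot` on an
  auto-expanded bracket to 1e-8.
* **Adjacency interpretation.** A distance matrix is passed verbatim as the
  weighted adjacency by default (this replicates feeding a distance matrix
  directly to a graph-spectral routine); a `"similarity"` option uses
  `1 − D` off-diagonal instead. All structural properties tested hold under
  either; the choice is recorded in the output metadata.
* **Determinism.** Disease and feature orderings are lexicographic (C-locale
  radix sort); cluster ids are renumbered by first appearance; merge ties
  follow the deterministic `hclust` index convention. With exactly tied
  merge heights a dendrogram cut between the tied merges is inherently
  ambiguous — the permutation-invariance guarantees hold for tie-free
  inputs.
* **Degenerate inputs.** All-zero distance matrices embed at the origin and
  stay all-zero under Euclidean/Hamming normalization; all-singleton
  clusterings give a Dunn index of `+Inf` with a warning; features absent
  from every disease are skipped in enrichment with a warning.
* **Problem sizes.** The shipped tests and the acceptance script run the
  full chain at 60 diseases × 5 seeds, IM calibration up to n = 502,
  exhaustive Fisher enumeration up to N = 12, and oracle comparisons on
  graphs up to n = 50 — sizes chosen so the whole validation suite executes
  in about a minute while still exercising every code path at the scale the
  mathematics changes (e.g. the 502-disease calibration).

## Known limitations

* The stepwise-averaging weights depend on the IM dendrogram topology; small
  IM perturbations near a merge tie can flip the schedule and hence the leaf
  weights (the consensus matrix itself moves continuously except at such
  flips).
* The Dunn-based `k` suggestion picks the first local maximum; on data
  without clear separation the curve can be monotone and the scan then
  yields no suggestion — the cut must be chosen by the analyst.
* ICD comparison is shape-level only (spectral invariance, above), and the
  level-based code similarity is a stand-in for a published weighting.
* Identifier matching is exact-string only; terminology normalization is out
  of scope.
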