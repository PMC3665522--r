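---
title: "Cross-species domain hotspots: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species domain hotspots: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainHotspots)
```

## The problem

Point mutations with known phenotypic consequences — human disease variants,
yeast alleles with scored phenotypes — are sparse at the level of any one
gene, but protein domains recur across many genes and across species.
Projecting each mutation from protein coordinates onto the match columns of
the domain models that align to its protein pools evidence across genes and
organisms: if phenotypically relevant mutations hit the same domain column
far more often than uniform placement predicts, that column is a *domain
hotspot*, and a hotspot found in one species can flag the homologous column
in the other species even when the genes involved share no orthology.
This package implements that pipeline end to end — mapping, clustering
statistics, conservation scoring, hotspot de-redundification, cross-species
linking, relatability classification and disease–phenotype co-occurrence —
plus a seeded synthetic-data generator so every stage is testable without
external databases.

## The clustering statistic

For one domain model with $L$ match columns carrying $n$ mapped mutations,
the per-column counts $X_1,\dots,X_L$ are compared against uniform placement.
Writing $F$ for the CDF of $\mathrm{Binomial}(n, 1/L)$, the score of a column
with count $c$ is

$$ S(c, n, L) \;=\; -\log_{10}\!\bigl(1 - F(c-1)^{\,L}\bigr), $$

the $-\log_{10}$ probability that the *maximum* of $L$ independent
$\mathrm{Binomial}(n, 1/L)$ counts reaches $c$. Modelling choices worth
making explicit:

* **The iid-binomial construction is an approximation.** The true null is
  multinomial (counts sum to $n$ and are negatively correlated); treating the
  $L$ counts as independent binomials is the standard order-statistic
  approximation. The test suite checks both sides: exact agreement with the
  formula by independent pmf summation, and Monte-Carlo agreement with the
  simulated distribution of the iid maximum.
* **Ties.** Because the score depends on a column only through its count,
  columns with equal counts automatically receive equal scores — the $m$-way
  tie rule falls out of the construction rather than being patched on.
* **Thresholds.** Hotspots are called at scores $\ge 1.6$, $1.3$ and $1.0$,
  i.e. $p \le 0.025$, $0.05$ and $0.10$ on Fisher's scale of evidence.
  Comparisons are inclusive at every boundary in this package (score
  thresholds, the E-value cut-off, the conservation threshold).
* **Degenerate inputs.** Columns with zero mutations score 0 (hotspot calling
  only ever inspects mutated or feature-backed columns), $n = 0$ scores 0,
  and a single-column domain ($L = 1$) always scores 0 because its maximum is
  deterministically $n$.

**Discreteness.** $S$ is a step function of the integer count $c$, so the
null exceedance probability of a fixed threshold jumps between attainable
values rather than equalling the nominal $p$:

```{r discreteness}
dsScore(3, 20, 100)   # count 3 of n=20 over L=100: below the 1.3 threshold
dsScore(4, 20, 100)   # count 4 clears it comfortably
```

With $n = 20$, $L = 100$, a column needs count $\ge 4$ to clear 1.3, and the
null probability of that event is about $5\times10^{-3}$ — well below the
nominal 0.05, while count $\ge 3$ would occur with probability near 0.10.
Fixed-threshold calibration statements should therefore always be read
against the attainable steps, not the nominal level; this is a property of
the statistic itself, visible in the package's own null simulations.

**Numerics.** The tail is evaluated in log space: the upper tail
$S_F = P(X \ge c)$ comes from `pbinom(..., log.p = TRUE)`; for moderate
tails $1 - F^L$ is computed as `-expm1(L * log1p(-S_F))`, and for
$S_F < 10^{-12}$ as $L \cdot S_F$ (relative error below $L S_F / 2$),
avoiding the catastrophic cancellation of the naive form. Scores are capped
at 300, the representable $-\log_{10}$ floor.

## Feature-based scores

CDD-style curated site annotations (binding sites, active sites, ...) group
columns into functional features. The feature-based score distributes, within
each feature, the largest position-based score to every column of that
feature; unannotated columns keep their position-based score, and a column in
several features takes the maximum (ties broken to the alphabetically first
feature). Each column remembers its *arg-max source column* — the column
whose mutation set backs the score — with ties broken to the smallest column,
so downstream de-redundification keys on a well-defined mutation set. This
variant deliberately trades positional precision for cross-species
flexibility: two species can hit different columns of the same annotated
site and still be related.

## Mapping mutations to domain coordinates

* Hits (profile-HMM-style global alignments, supplied as input) are kept at
  E-value $\le 0.001$, boundary inclusive.
* A protein position aligned to a match column maps there; a position inside
  an insertion maps to the **last match column before the gap**. An insertion
  before the first match column has no such column; the mutation is dropped
  with a log line (the rule is otherwise undefined there).
* Each gene contributes exactly one representative protein: the longest
  Swiss-Prot entry, else the longest RefSeq entry, else the longest overall
  (for sources without that distinction); equal lengths break to the
  lexicographically smallest protein id so the choice is deterministic.
* A mutation is distributed to **every** filtered hit overlapping its
  position — redundant domain copies included, by design — but contributes at
  most once per (domain, column). Two hits of the same repeat domain are
  distinct alignments, so a mutation may legitimately occupy two columns of
  one domain. Distinct mutation records at the same protein position count
  separately: the statistic counts mutations, not sites.

## Conservation

Column conservation uses Shannon entropy of the 20 amino-acid frequencies
with the natural logarithm, $H_j = -\sum_i p_{ij} \ln p_{ij}$ (the AL2CO
convention; frequencies arrive precomputed, unweighted). The global
threshold is the mean plus one **population** (divide-by-$N$) standard
deviation over all columns of all supplied profiles — the mean-plus-one-SD
rule does not itself fix the SD convention, so the choice is recorded in the
threshold object and in output metadata to keep it auditable — and a column
is conserved iff
$H_j \le$ threshold, inclusive.

## De-redundification, linking, relatability, co-occurrence

* **Groups.** Hotspot calls sharing an identical underlying mutation set
  (the sorted mutation-id key) collapse into one group; the group count is
  the non-redundant hotspot count. The representative domain of a group is
  chosen by ordering accessions case-insensitively ascending and preferring
  hierarchy roots, then feature-annotated domains, then the first outright.
  For multi-species hotspots the representative is chosen among domains
  shared by both species when possible.
* **Linking.** A position-kind group links to the other species when any
  member (domain, column) carries at least one of that species' mutations; a
  feature-kind group links when any column of the same feature on a member
  domain does. The accompanying enrichment p-value uses a right-sided Fisher
  test whose rows are the scoring species' mutated (domain, column) sites
  split by hotspot status and whose columns are presence of an other-species
  mutation — the construction is an interpretive choice (the source analyses
  do not specify one) and is documented here rather than asserted as
  canonical.
* **Relatability.** Each mutation is classified by two booleans — maps into
  a domain shared by both species' proteomes; sits on a gene with a
  cross-species ortholog — into `both`, `domain_only`, `ortholog_only`,
  `neither`. The four classes partition the dataset by construction.
* **Co-occurrence.** Overlap events are (human mutation, yeast mutation)
  pairs localised at the same (domain accession, column). To avoid
  redundancy inflation, no mutation is counted twice as overlapping one
  other-species label: events are deduplicated greedily in deterministic id
  order on the (human mutation, phenotype) and (yeast mutation, disease)
  keys. Each observed label pair is tested right-sided on
  (a, b, c, d) = (pair co-occurrences, disease with other phenotypes,
  phenotype with other diseases, remainder). The Fisher tail itself is exact
  hypergeometric (`stats::phyper`), cross-checked in the tests against
  explicit enumeration.

## The synthetic generator

`scenarioConfig()` / `generateScenario()` produce a complete two-species
dataset with a ground-truth ledger. What it emulates, and the defaults:

| Parameter | Default | Why |
|---|---|---|
| `nSuperfamilies`, `redundancyFactor` | 8, 3 | enough independent domains for non-degenerate margins; redundant identical-mapping copies with exactly one hierarchy root exercise de-redundification |
| `domainLengthRange` | 60–150 | typical domain-model lengths |
| `nProteinsPerSpecies`, `nMutationsPerSpecies` | 30, 300 | desk scale: large enough for planted clusters to be unambiguous, small enough for test budgets |
| `hotspotPlan` | 3 clusters (yeast, human, both) at 5–8% of mutations | planted positional structure recoverable at the 1.6 threshold |
| `featureCoverage`, `featureSizeRange` | 0.25, 3–10 | curated-site coverage in the 10–40% range seen in annotated domain families |
| `orthologFraction` | 0.20 | matches the ~20% of yeast genes with a human ortholog |
| `sharedDomainFraction` | 0.87 | matches the ~87% of yeast domains also found in human |
| `cooccurrencePlan` | one pair, 6 overlaps | a planted disease–phenotype pair that should top the co-occurrence ranking |
| `offDomainFraction` | 0.25 | ~75% of phenotypic mutations fall inside domain regions in real data; off-domain mutations are also what make the `ortholog_only` and `neither` relatability classes attainable |
| `conservedColumnFraction` | 0.6 | real domain models are majority-conserved (that is what makes them domains); low-entropy columns draw a single dominant residue (Dirichlet with one large concentration), variable columns draw near-uniform (Dirichlet $\alpha = 2$), so the mean-plus-SD rule separates the two modes instead of degenerately flagging every column |

Draws are sub-streamed per generation stage from the single seed, so adding
a stage never perturbs earlier draws and the same seed is byte-identical
forever. Yeast-like proteins are single-domain and human-like proteins carry
1–3 domains — cosmetic realism. Alignment maps include random insertions
(probability 0.08 after each column, length 1–3) so the gap rule is always
exercised, and ~10% of proteins get a decoy hit above the E-value cut-off so
filtering is always exercised.

What the generator does **not** emulate: real protein sequences, HMMER score
distributions, disease ontologies, or correlated mutation processes. Passing
tests on this synthetic structure demonstrate the pipeline's correctness and
calibration under its stated null, not biological conclusions about real
mutation databases.

## Problem sizes used by the tests and acceptance script

The suite verifies the score against independent pmf summation over the full
grid $n \le 25$, $L \le 12$; Monte-Carlo agreement at $n=20$, $L=10$ with
$10^6$ replicates; null calibration on 2,000 uniform domains at $L=100$,
$n=20$; planted-cluster recovery (40% of $n=50$ mutations at one column of
$L=100$) over 200 generator seeds, with the 120-fold redundancy collapse
checked at one seed; and Fisher exactness by exhaustive enumeration of all
2×2 tables up to total 40. These sizes are the package's chosen desk-scale
study conditions; all are recomputed from scratch on every run.

## Known limitations

* The score is the iid-binomial approximation to the multinomial maximum;
  exact multinomial tail probabilities exist here only as test oracles.
* No multiplicity correction across domains is applied — thresholds are
  fixed Fisher-scale levels, matching the method's design.
* Entropy weighting and gap handling of full AL2CO are out of scope;
  frequencies are consumed as given.
* Absolute hotspot counts from real OMIM/Swiss-Prot/SGD/CDD snapshots are
  not reproducible here by design; the package's claims are about the
  machinery, verified on synthetic ground truth.
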