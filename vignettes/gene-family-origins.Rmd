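---
title: "Dating, classifying and screening novel gene families on a species tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating, classifying and screening novel gene families on a species tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genovmap)
```

## The problem

Given orthogroups (clusters of genes across species descended from one
ancestral gene) and a rooted species tree, we want to know *when* each
family arose, *how* it arose, and *what happened to it afterwards*.
`genovmap` implements that workflow in four analytic stages plus a
simulator that generates inputs with known ground truth:

1. **Gain mapping.** Each family's node of origin is the most recent
   common ancestor (MRCA) of all species carrying at least one copy —
   the parsimonious assumption that a family observed in a set of
   species was present in their common ancestor and arose on the branch
   leading to it.
2. **Origin classification.** Clade-specific families are labelled
   `duplication_divergence`, `hgt` or `de_novo_candidate` from
   taxon-partitioned homology evidence and protein-domain annotation.
3. **Retention and copy-number screening.** Families gained at a focal
   node are screened for retention across the clade and for
   significantly elevated copy number with an Anderson–Darling →
   Kruskal–Wallis → Dunn cascade.
4. **Microsynteny.** One-to-one orthology and integration-site
   conservation are tested with flanking marker genes.

## Gain mapping by MRCA parsimony

`mrca_node()` folds pairwise lowest-common-ancestor queries (ascend to
equal depth, then climb together) over the presence set;
`assign_gains()` applies it to every family. Two conventions matter:

* **Gains sit on nodes.** A gain "at node X" is equivalent to a gain on
  the branch leading to X; we report the node.
* **Presence filter.** Families present in fewer than three species are
  excluded before mapping (`filter_min_species()`, default
  `min_species = 3`, i.e. "present in greater than two species").
  Single-species families would otherwise map to leaves; if the filter
  is relaxed, leaf assignments are permitted and are visibly
  species-specific in the output.

MRCA dating has a one-sided error structure that the simulator makes
explicit: **gene loss can never make an inferred gain too ancient**.
Losing species from a presence set can only pull the MRCA *down* into
the true gain subtree. With per-branch loss probability `q = 0` the
recovery is exact; with `q > 0` the inferred node is always within the
true gain node's subtree, and the exact-recovery rate decays with `q`.
Conversely, incomplete outgroup annotation inflates apparent novelty,
which is why `rescue_against_alternative_annotation()` demotes
candidates with a passing hit against an alternative outgroup
re-annotation (e-value ≤ 1e-5, identity strictly above 25%, query and
subject coverage ≥ 60%).

## Origin classification

The decision table, in precedence order:

| evidence | label |
|---|---|
| ≥1 passing metazoan hit OR ≥1 known domain | `duplication_divergence` |
| else ≥1 passing non-metazoan hit | `hgt` |
| else | `de_novo_candidate` |

Metazoan evidence *vetoes* HGT: a horizontal-transfer candidate is a
family present in the focal clade and in non-metazoan proteomes but
absent from other animals, so rule (1) is evaluated before rule (2). A
protein domain alone counts as duplication evidence by default (a
domain implies descent from a pre-existing gene); this is the
`domain_as_duplication` flag, because domain-only evidence with zero
sequence hits is a judgement call, and both behaviours are supported.
Hit counting is any-member: evidence from any member gene counts for
the whole orthogroup.

Two deliberately different identity operators are in use and are kept
apart in the API:

* the screening/filtering rule uses **strictly above** 25%
  (`filter_hits(..., identity_strict = TRUE)`), and
* reciprocal-similarity linking of homologous orthogroups
  (`link_orthogroups()`) uses **equal to or above** 25%.

Coverage is always `>=` and e-value always `<=`; the 60% coverage
boundary is inclusive — a documented convention, since the boundary
semantics at exactly 60% are not dictated by the method. Hits with
query coverage below 45% still obey the numeric thresholds but are
annotated partial in the evidence columns, as low-coverage matches are
the classic signature of spurious (partial-domain) homology.

## Retention and copy-number screening

`copy_matrix()` builds the family × species integer matrix for the
focal clade, **including zero cells for absent species**: the grand
mean is then "mean gene copies per family per species", the quantity
the screening is calibrated on (≈ 1.16 in the data regime the defaults
emulate); excluding zeros is available but changes the meaning of the
mean. `retention()` flags families present in ≥ 75% of focal species
(inclusive threshold).

The outlier cascade (`dunn_flag()`):

1. **Anderson–Darling** on the pooled cells (default; per-family means
   are an alternative the interface does not encourage, since pooled
   cells are what the later rank tests see). Copy counts are
   right-skewed with a point mass at 0/1, so normality is essentially
   always rejected — the check documents why the cascade is
   rank-based. Fewer than 8 observations or a constant vector are
   errors, not verdicts.
2. **Kruskal–Wallis** across families (tie-corrected H, chi-square
   reference, `df = k − 1`).
3. **Dunn's post hoc**, gated on Kruskal–Wallis significance
   (`require_kw = TRUE`). The primary scheme is **one-vs-rest**: each
   family's cells against the pooled cells of all other families, with
   z computed from a single joint ranking with tie correction. The
   method asks "does this family deviate from the rest?", which
   one-vs-rest matches directly and at linear cost; all-pairs is
   available (`scheme = "all_pairs"`, flagging families significantly
   above more than half of the others). P-values are
   Benjamini–Hochberg adjusted by default (Bonferroni/Holm via
   `adjust`), and flagging is **one-sided (elevated only)** by default
   — expansion is the question — with `two_sided_flag` to widen it.

Calibration properties (checked by the test suite at fixed seeds):
under an i.i.d. null copy law across 50 families × 99 species the
Kruskal–Wallis rejection rate at α = 0.05 sits within 0.05 ± 0.02 over
1,000 replicates, and a single family with a tripled mean copy number
is flagged in ≥ 95% of 200 replicates with false flags at most at the
α level after adjustment.

One caveat the simulator exposes: when copy counts are generated *on
the tree* (shared loss/duplication history), cells within a family are
phylogenetically correlated, the effective between-family heterogeneity
is real, and the cascade flags many families. That is a property of the
rank tests (which assume exchangeable cells), not a bug; flags on real
data should be read as "copy-number distribution differs", with the
phylogeny in mind. Phylogenetically corrected models (PGLS and
relatives) are out of scope.

## Microsynteny and introns

`marker_context()` takes the two nearest genes per side of a target
(coordinate order, strand recorded but ignored — strand carries no
conservation signal in this scheme). `compare_synteny()` counts markers
whose homologue (same orthogroup — table membership is the
deterministic stand-in for manual sequence search) lies within a
10-gene window of the other species' target; the shared count is the
minimum of the two directions, making the score symmetric, and a
neighbourhood is called conserved at ≥ 2 of 4 shared markers. Both the
window and the 2-of-4 rule are conventions that make a visual judgement
reproducible; they are surfaced in the output rather than hidden.
`intron_summary()` reports per-gene intron counts (exon count of the
longest transcript minus one — the transcript choice is a convention,
flagged in output) and per-subfamily medians.

## The simulator

`simulate_families()` plants one ancestral copy at a sampled gain node;
along every descendant branch each extant copy survives with
probability `1 − q` and each survivor spawns `Poisson(λ)` duplicates.
Defaults emulate the intended data regime: a 115-leaf tree (99-leaf
focal clade + 16 outgroups, `sim_species_tree()`), 500 families,
`q = 0.1`, `λ = 0.02`, and planted origin-mode proportions
(82% duplication / 1% HGT / 17% de novo) drawn with largest-remainder
exactness. `simulate_hits()` emits class-conditional evidence such that
noise-free tables round-trip the planted labels exactly through
`classify_origin()`; `hit_noise` injects boundary-straddling records
(identity near 25, coverage near 60) that exercise the filter's
operator semantics. `simulate_gene_orders()` embeds a target between
two orthologous markers per side and applies `Poisson(rate × n)`
position swaps per species. All generators take a mandatory seed and
are byte-deterministic on disk (`write_sim_dataset()`).

What the simulator does *not* emulate — and therefore what passing
tests do not establish about real data: sequence-level evolution (no
alignments, no realistic identity decay with distance), annotation
error beyond the alternative-annotation toggle, orthology-clustering
mistakes (families are simulated as correctly clustered), and
phylogenetically realistic rate variation across branches. Recovery
rates on simulated data are upper bounds for real data.

## Numerical and design choices

* Coordinates are 1-based inclusive; coverage from coordinates is
  `(end − start + 1)/length × 100` and agrees with directly supplied
  coverage within rounding.
* Internal nodes without newick labels get deterministic preorder
  labels `N1…Nk` (root = `N1`), so gain maps are reproducible across
  runs and machines.
* Subject taxonomy comes from an explicit subject → class map file;
  nothing is inferred from identifiers and no network lookups occur.
* Ties in ranks use midranks everywhere, with the standard
  `Σ(t³ − t)` corrections in both H and the Dunn variance.
* The problem sizes used by the packaged property checks (200 trees ×
  100 presence sets; 500 simulated families on 115 leaves; 1,000 null
  replicates of 50 × 99; 200 power replicates) were chosen to make the
  Monte-Carlo error small relative to the bands being checked.

## Limitations

Dollo or maximum-likelihood ancestral-state reconstruction of losses is
deliberately absent — gain dating is MRCA-only, so repeated loss
biases gains toward the recent side (never the ancient side).
Gene-tree/species-tree reconciliation, HGT donor inference from gene
trees, structure-based homology validation and enrichment analyses are
out of scope; their *outputs* can be consumed where relevant (e.g.
hit tables from any search tool), but this package does not produce
them.
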