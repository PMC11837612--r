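# genovmap

Dating, classifying and screening novel gene families on a species
phylogeny.

Comparative genomicists who have clustered genes into orthogroups (e.g.
with OrthoFinder) and built a rooted species tree often want to know,
for each family: when did it arise, how did it arise, and did it expand
afterwards? `genovmap` answers those questions from tabular inputs —
an `Orthogroups.tsv` membership table, a newick tree, BLAST-style hit
tables, Pfam-style domain annotations and GFF3 gene models — without
running any aligner or search tool itself.

## What it computes

**Gain mapping (phylostratigraphy).** For a family present in species
set *S*, the node of origin is assigned parsimoniously as
MRCA(*S*): the most recent node whose leaf descendants contain *S*.
Families present in fewer than 3 species are excluded. Gene loss can
only make an MRCA-dated gain *too recent*, never too ancient; the
package's simulator quantifies that one-sided error.

**Origin classification.** Each clade-specific family is labelled by a
precedence rule over filtered homology evidence (e-value ≤ 1e-5,
identity strictly > 25%, query and subject coverage ≥ 60%):

1. passing hit in other metazoans, or a known protein domain →
   `duplication_divergence`;
2. else a passing non-metazoan hit → `hgt` (metazoan evidence vetoes
   transfer);
3. else → `de_novo_candidate`.

**Retention & copy-number expansion.** On the family × species copy
matrix (zeros included), retention = fraction of species with ≥ 1 copy
(retained at ≥ 0.75), and expanded families are flagged by an
Anderson–Darling → Kruskal–Wallis → Dunn one-vs-rest cascade with
Benjamini–Hochberg adjustment, elevated side only.

**Microsynteny.** Two flanking marker genes per side of a target are
compared across species through orthogroup membership; a neighbourhood
is conserved when ≥ 2 of 4 markers have homologues within a 10-gene
window of the other species' target.

**Simulator.** `simulate_families()` evolves families by gain at a
node, per-branch per-copy loss (prob. `q`) and Poisson(λ) duplication,
emitting both pipeline-ready input files and ground truth, so every
stage is testable end to end.

## Worked example

The `analysis/` directory is a five-stage narrative workflow over the
package. Stage 1 simulates a 115-species dataset (99-species focal
clade + 16 outgroups, 500 families gained at the focal stem with loss
`q = 0.1` and duplication `λ = 0.02`); stages 2–5 analyse it.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_gains.R
```

prints

```
orthogroups: 500 | retained: 484 | excluded (<3 species): 16
gains at the focal-clade node N2 : 391
gain-node recovery: exact 80.8%, within true subtree 100.0%
```

Reading: of 500 simulated families, 484 survive in ≥ 3 species; 391
still map to the true focal node, and *every* inferred gain lies
within the true gain subtree — loss pulled ~19% of assignments to a
more recent node but never made one too ancient.

```sh
Rscript analysis/03_classify.R
```

```
focal-node families classified: 391
     de_novo_candidate duplication_divergence                    hgt
                    67                    319                      5
planted-label recovery: 100.0%
```

With noise-free evidence the decision table recovers every planted
origin mode. Stages 4 and 5 screen retention/copy number
(Anderson–Darling A² = 4831, p < 1e-20: strongly non-normal,
right-skewed counts) and show mean shared-marker counts falling from
4.0 to 1.3 as the simulated rearrangement rate rises from 0 to 0.2.
All outputs are plain TSVs under `results/`.

Equivalently, `run_pipeline()` drives ingest → gains → classification
→ copy stats from one flat key = value config (`read_run_config()`)
and writes the same tables plus a count-reconciled run report.

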