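---
title: "Classifying drug repositioning cases and their triad networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying drug repositioning cases and their triad networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A repositioning case is a triple: a drug, its original indication, and the
secondary indication it was repurposed to, each indication annotated with a
top-level MeSH key (e.g. `C04` = Neoplasms) and each side carrying a set of
molecular targets. The package classifies every eligible case by a
step-wise, short-circuiting rule set:

1. **Disease-centric** — the two indications share their top-level MeSH
   key. Targets are deliberately not examined for these cases: the rule
   mirrors a curation workflow in which same-class repositionings are
   resolved first, so a disease-centric case may carry empty target sets.
2. **Target-centric** — distinct keys, but a protein-target identifier
   occurs on both sides; or some cross-identifier pair of targets is
   orthologous, operationalised as global-alignment sequence identity
   *strictly* above 30%.
3. **Drug-centric** — the residual: distinct disease class and distinct,
   non-homologous targets.

The underlying assumptions are worth making explicit. Using only the
3-character root of the MeSH tree is a coarse notion of disease similarity:
it treats all neoplasms as "the same disease class" and two nervous-system
conditions as interchangeable. The shared-identifier rule treats gene
symbols and UniProt accessions as opaque strings after uppercasing, so the
same protein under two naming schemes will *not* match (the curated corpus
uses one scheme per target consistently). Both choices trade subtlety for
reproducibility.

## Eligibility

Only small-molecule drugs acting on protein targets are classified. A case
is removed with reason `non_small_molecule` (checked first, so reports are
deterministic) or `non_protein_target`. Mixed target sets are resolved in
favour of the protein mechanism: a case is excluded only when a non-empty
target set contains no protein at all; otherwise non-protein members are
dropped and the case kept. The alternative (dropping any case containing a
non-protein member) would discard cases whose mechanism is carried by the
protein members — e.g. a ribosomal-protein inhibitor also annotated with an
rRNA species.

## The ortholog criterion

Identity is computed from an exact Needleman–Wunsch global alignment and
defined as `(n_identical + n_similar) / alignment_length`, where a
non-identical, gap-free column is *similar* when its BLOSUM62 score is
strictly positive, and gap columns count as neither. The decision is
strict: identity exactly 0.30 is not an ortholog call.

Parameter choices:

* **Substitution matrix** — the standard NCBI BLOSUM62 (packaged as plain
  text; no network access). "Similar = positive score" is the conventional
  reading of substitution matrices.
* **Gap model** — linear, default −8 per gap column. A linear model keeps
  the alignment space small enough for the test suite's exhaustive
  enumeration oracle, and the only downstream consumer is a coarse 30%
  threshold. Affine gaps and local alignment are deliberately out of scope.
* **Traceback ties** — diagonal preferred, then a gap in the second
  sequence, then a gap in the first; fixed so the aligned strings are
  reproducible. The score is tie-invariant.

### A twilight-zone caveat

The similarity-inclusive statistic does **not** behave like identical-only
percent identity on unrelated sequences. Under any reasonable linear gap
penalty, optimal global alignments of two *independent* random 200–300
residue sequences score 0.23–0.29 on this statistic — uniformly random
BLOSUM62 columns are positive ~17% of the time and the optimiser inflates
that — and roughly one pair in three crosses the 0.30 line at the default
gap penalty. The 30% homology cutoff is therefore only meaningful when the
aligner is pointed at *curated candidate* ortholog pairs, which is exactly
how the classifier uses it: alignment is attempted only for target pairs
whose sequences were supplied, mirroring a manual workflow. Feeding the
classifier sequences for arbitrary unrelated target pairs will produce
spurious target-centric calls; that is a property of the statistic, not a
bug, and it is the reason the synthetic generator verifies what it plants
(below).

## The packaged corpus

`rdd_corpus()` loads a curated table of 128 repositioning cases of
small-molecule drugs on protein targets, compiled from the public
Repurposed Drug Database merged with a molecular drug-target map: 76 cases
with a shared disease key (their target sets are empty, as targets were
never examined for them), 45 with a shared or orthologous target, and 7
residual drug-centric cases. Five of the target-centric cases are
cross-organism ortholog pairs (e.g. a fungal and a human cytochrome P450);
since the exact sequence versions behind the original identity values are
not recoverable, the package ships *synthetic stand-in* sequences
(`ortholog_sequences_synthetic.fasta`, so labelled) constructed to fall
clearly on the ortholog side of the threshold. Their individual identity
percentages are explicitly not reproduced — only the threshold side is
promised, and only that is asserted anywhere.

One transcription note: the source listing of disease-centric cases is
internally inconsistent (its groups enumerate 77 drugs while every headline
count says 76, and 76 + 45 + 7 = 128). The corpus resolves this by keeping
one of the two secretin entries (the diagnostic-use row) and dropping the
duplicate; no headline or per-group count used anywhere in the tests is
affected.

## Triad networks

For each class, `build_graph()` creates an undirected simple graph with one
node per drug, per target identifier, and per top-level MeSH key, and edges
drug–target, target–indication, and drug–indication per case, duplicates
collapsed. Indications are collapsed to root keys uniformly across all
three classes (the alternative — free-text indication nodes for the target-
and drug-centric graphs — is ambiguous and would make the three summaries
incomparable).

`summarize_network()` reports:

* node/edge counts and the percentage of both in the largest connected
  component;
* mean local clustering per node type, with degree-<2 nodes contributing 0
  (stated because conventions differ; excluding them would overstate
  clustering in sparse graphs);
* transitivity `3 × triangles / connected triples` (0 when no triples);
* the **effective diameter**: the 90th percentile of the shortest-path
  distance distribution over unordered distinct pairs of the largest
  component, with the percentile taken at rank `q(m−1)/100` and linear
  interpolation between the bracketing order statistics. The distance
  distribution is computed *exactly* (all-pairs BFS), unlike approximate
  neighbourhood-function routines used by some graph toolkits, so
  published diameters obtained with such routines may differ slightly from
  an exact recomputation;
* the small-world score `transitivity × n_nodes / effective_diameter`,
  which by construction always satisfies
  `small_world × effective_diameter = transitivity × n_nodes`. Node count
  is that of the whole graph, not the largest component — the worked
  example with published inputs (0.27, 51, 3.43 → 4.01) fixes that
  convention.

A type average is reported as `NA` when the graph has no node of the type
(the disease-centric graph built from the packaged corpus has no target
nodes, because those cases carry none).

## The synthetic generator

`generate_cases()` plants exactly the structure the classifier tests for,
with integer class counts obtained from fractional shares by
largest-remainder apportionment (deterministic, always summing to
`n_cases`):

* disease-centric cases: one key drawn, used on both sides;
* target-centric cases: two distinct keys; with probability
  `f_ortholog_within_target` (default 5/45, the corpus share) the case is a
  cross-organism ortholog pair — the second sequence derived from the first
  by point substitutions at `mutation_rate` (default 0.2; a substitution
  always changes the residue) — otherwise a shared identifier;
* drug-centric cases: two distinct keys and disjoint targets with
  independent random sequences, **rejection-sampled until the pair is
  genuinely non-homologous under the classifier's own criterion** (see the
  twilight-zone caveat: independent pairs land near the 0.30 line often
  enough that an unverified generator would mislabel its own plants). The
  realized identity of every sequence pair is recorded in the `labels`
  output.

Residues are drawn uniformly over the 20 standard amino acids; no
composition or domain structure is modelled, because the classifier only
consumes threshold crossings. Defaults restate the packaged corpus: 128
cases at 59/36/5% shares. Sequence length defaults to 300 — a typical
enzyme domain scale, and long enough that mutated pairs at the default rate
sit far above the threshold.

What a green planted-recovery test establishes: the rule set and the
alignment pipeline are wired correctly end to end. What it does not
establish: performance on real data with inconsistent identifier schemes,
missing sequence versions, multi-subunit target notations, or diseases
whose MeSH placement is debatable — none of which the generator emulates.

## Other conventions

* Percentages in classification summaries are integers rounded half-up
  (76/128 → 59%), with raw fractions reported alongside; 45/128 rounds to
  35% even though coarser renderings of the same corpus have quoted 36%.
  An empty corpus reports all counts and percentages as 0 with an `empty`
  flag rather than dividing by zero.
* `category_tally()` is defined only for disease-centric cases; the other
  classes have two distinct keys and no canonical "their" group.
* Structural coverage is an offline lookup against a user-supplied
  drug/target/structure snapshot table; results are reproducible only
  relative to a given snapshot, and no live structure database is queried.
* Multi-subunit shorthand identifiers (e.g. `GABR(+)`) are kept as single
  opaque identifiers rather than expanded into subunit sets; the corpus
  documents them as such.
* All randomness is seeded (`withr::with_seed`), and the generator is
  byte-reproducible under its seed.

## Known limitations

* The classifier is order-dependent by design (disease rule first), so
  overlaps between categories are invisible — a case that is both
  disease-centric and target-centric is reported as disease-centric only.
* The ortholog branch requires user-supplied sequences; without them only
  identical identifiers can fire rule 2, and with indiscriminate sequences
  it can overcall (twilight zone). It is a curation aid, not a homology
  search.
* No affine gaps, no local alignment, no multiple-sequence alignment, and
  no automated literature mining for target–indication evidence.
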