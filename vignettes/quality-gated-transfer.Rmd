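---
title: "Quality-gated homology transfer of disorder annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-gated homology transfer of disorder annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotransfer)
```

## The problem

Curated databases of intrinsically disordered proteins (IDPs) annotate
disorder and its associated functions — GO terms and terms from the
disorder ontology (IDPO) — at the level of sequence *regions*, each with
experimental support. Curation is slow, so only a few thousand proteins
carry such annotations. Orthologs of an annotated protein are likely to
share these features, which makes homology transfer attractive; but
disordered regions evolve quickly and align poorly, so a transfer based
on overall sequence similarity alone is unsafe. A family alignment can
look excellent globally while being incoherent exactly inside the
annotated region — or the reverse.

`orthotransfer` implements a transfer protocol that gates every
projection twice: the whole-family multiple sequence alignment (MSA)
must pass an identity filter and an alignment-quality score, and the
alignment restricted to each annotated region, re-filtered and
re-aligned on its own, must pass the same kind of gate. Only when both
hold is a region's term projected onto the orthologs that survived, with
coordinates mapped through the alignment into each ortholog's own
numbering.

## Pipeline

For each reference protein with annotated regions:

1. **Entry filters.** Only entries whose sequence is clean (no undefined
   `X` residues), structurally valid, and — when a canonical-sequence map
   is supplied — identical to the canonical database sequence are used.
2. **Reference clustering.** References are clustered greedily at a
   configurable percent identity (60 or 80 in the standard grid):
   sequences are visited longest-first and join the first cluster whose
   representative they match at or above the threshold, else found a new
   cluster. The representative (the longest member) is the family
   reference. Identity here is defined by global pairwise alignment —
   identical aligned pairs over the full alignment length — which is a
   reproducible contract independent of any clustering heuristic's
   word-based shortcuts.
3. **Ortholog sets.** Per-provider FASTA files
   (`<accession>.<provider>.fasta`) are merged at the accession level
   with provenance retained. Orthologs shorter than 30% or longer than
   130% of the reference are discarded. The lower bound is deliberately
   permissive; a `strict` mode with a 70% floor is available
   (`length_filter_mode`), because the permissive reading keeps
   fragments whose status is settled later by the identity filters
   anyway. Families left with no ortholog are dropped.
4. **Global gate.** The family is aligned (builtin aligner or an external
   one), rows below the global identity threshold are removed (the
   reference always stays), and the NorMD score of the remaining
   alignment must exceed the reliability cutoff.
5. **Region gate.** For each annotated region, the global alignment is
   chopped at the columns spanning the reference's region residues. The
   window subsequences are realigned, each row's identity to the
   reference *within the region* is measured, rows below the region
   threshold are dropped, survivors are realigned, and NorMD is computed
   on the result. Chop-only behavior (no realignment) is available as
   `realign_regions = FALSE`. Realigning before measuring identity
   avoids penalizing orthologs for artifacts of the global alignment;
   realigning again after filtering mirrors how a region alignment is
   actually judged once divergent rows are gone. A single pass is run —
   filtering and realignment do not iterate to convergence, since the
   second realignment of an already high-identity row set is stable in
   practice.
6. **Transfer.** A record is emitted per (region, surviving ortholog)
   only when *both* gates passed. The projected span is the first/last
   aligned residue of the ortholog inside the window, in its own
   numbering; orthologs with no residue in the window get no record —
   an annotation cannot be placed on nothing.

Overlapping reference regions are processed independently; regions with
identical spans but different terms are distinct records throughout.

## The NorMD score

NorMD is a normalized mean-distance objective for judging MSA quality.
The implementation here scores each alignment column by how tightly its
residues cluster in a continuous similarity space, then normalizes so
that the result is comparable across families of different size, length
and composition:

- Each residue type $a$ is a point $v_a \in \mathbb{R}^{20}$, its row of
  the substitution matrix (BLOSUM62 by default).
- For a column with residues $r_1 \dots r_k$ (gaps excluded), the
  consensus is $\bar{x} = \tfrac{1}{k}\sum_i v_{r_i}$ and the column
  score is $\tfrac{1}{k}\sum_i e^{-d_i/\sigma}$ with
  $d_i = \lVert v_{r_i} - \bar{x}\rVert$. The scale $\sigma$ is the mean
  pairwise distance between distinct residue points under the matrix, so
  that an unrelated residue earns roughly $e^{-1}$ credit; the
  normalization below makes the final score nearly insensitive to this
  choice.
- Gaps earn no column credit, and an affine gap cost (open 0.5, extend
  0.05 per event, averaged over rows) is subtracted from the summed
  column scores. The costs are small by design: the dominant gap penalty
  is the credit a gapped row fails to earn.
- The raw score is corrected by the expected score of unrelated
  sequences of the same residue composition and alignment length
  (computed from the composition's consensus point), and normalized by
  the maximal self-alignment score, which for this credit function is
  the mean ungapped sequence length.

An alignment of identical sequences scores exactly 1. Mutually random
sequences score near 0. Scores above 1 are legal and occur for gap-rich
but internally consistent alignments, where the alignment has more
high-credit columns than the average sequence has residues. Scores above
0.6 — a strict inequality, configurable — flag the alignment reliable;
at exactly 0.6 it is not. Degenerate alignments so gap-rich that the
composition-expected score reaches the self-alignment maximum return
`NA` with a warning rather than a misleading number.

The published reference implementation of NorMD was not available in
this environment, so the constants above are this package's documented
choices rather than values traced to that code; the
acceptance test compares against a `normd` executable whenever one
resolves on `PATH`. What the tests pin down everywhere is the behavior
that the gates rely on: exact row-permutation invariance, the
identical/random separation across alignment shapes, monotone
degradation under progressive residue scrambling, and ordering by family
identity.

Uniformly substituted synthetic families sit measurably lower on this
score than real families of equal identity, because real substitutions
are conservative in exactly the similarity space the score measures.
The generator therefore defaults to substitution-score-weighted
replacements (below).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `disprot_cluster_identity` | 80% | reference clustering threshold |
| `global_identity` | 60% | row filter on the family MSA |
| `region_identity` | 60% | row filter inside each region |
| `normd_min` | 0.6 | reliability cutoff, strict `>` |
| `length_filter_mode` | `literal` | ortholog length window `[0.30, 1.30]`×ref (`strict`: `[0.70, 1.30]`) |
| `realign_regions` | `TRUE` | realign region windows before/after filtering |
| `region_gate` | `TRUE` | `FALSE` quantifies what the gate rejects |

Identity to the reference is always computed over the *reference's*
non-gap columns: a deletion in the ortholog opposite a reference residue
is a mismatch, while an insertion opposite a reference gap is ignored.
The purpose of the statistic is fidelity to annotated reference
positions, and deletions remove exactly those positions. Ties anywhere
(clustering order, guide tree, traceback) are broken by fixed rules —
length descending, then lexicographic accession; match before gap — so
that every run is deterministic.

The builtin aligner is a classic progressive scheme: 3-mer cosine
distances, a UPGMA guide tree, and profile–profile merging by global
dynamic programming with affine gaps (BLOSUM62, open 10, extend 0.5).
It exists so that the package is fully deterministic and
self-contained at desk scale; external aligners (`mafft`,
`clustal-omega`), run with their defaults through subprocess adapters,
are the production path for large families, and the default
configuration uses the builtin aligner so that a fresh installation
works without any external binary.

## The synthetic-family generator

`simulate_family()` emulates a one-to-one ortholog set with exact
identity control, which is what every recovery and gating test needs —
not phylogenetic realism. The reference is drawn uniformly over the 20
residues; each ortholog applies exactly `round(L·(1−t/100))`
substitutions at uniformly sampled positions (never the same site twice,
never re-drawing the original residue), so realized identity equals the
target exactly when no indels are planted. Replacement residues are
drawn with probability proportional to $2^{M_{ab}/2}$ (BLOSUM62
half-bit odds) by default, emulating the conservative substitutions of
real ortholog divergence; a `uniform` mode exists for harsher stress
tests. Indels are Bernoulli events per residue (default rate 0.01) with
geometric lengths (mean 2), and by default never fall inside planted
regions so that ground-truth projected spans stay well-defined. Planted
regions can override identity within their window per ortholog, which is
how locally-diverged decoys — globally acceptable, regionally
incoherent — are constructed.

The default family has ten orthologs at 66–95% identity, most of them
high: the shape of a vertebrate ortholog set for a curated reference,
with some rows in each of the 60–80% and above-80% bands so that both
threshold settings of the standard grid bite. Generation is
deterministic given the seed, with per-family substreams derived by a
fixed integer hash, and the caller's RNG state is restored afterwards.

What the generator does **not** emulate: tree-structured evolution and
rate heterogeneity, compositional bias of real disordered regions
(low-complexity tracts), fragmentary database sequences, and alignment
ambiguity from repeats. Passing the recovery tests therefore shows the
machinery is correct under controlled divergence, not that real
families at the same nominal identity would pass the gates at the same
rate.

## Validation utilities

For alignments containing a second annotated protein,
`annotation_overlap()` reports the percentage of the reference region's
column window annotated in both proteins (same ontology namespace,
regions pooled per pair, with the best single region also reported).
The statistic is reference-normalized by design — swapping the proteins
changes the denominator — and the decile histogram
(`overlap_distribution()`) uses left-closed bins with 100% included in
the top bin. `classify_disorder_plddt()` calls a residue disordered when
its predicted-confidence (plDDT) value falls below 0.7, auto-rescaling
0–100-scaled vectors.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on generated
families of 6–10 orthologs with references of 150–240 residues, three
families per benchmark, and the full 2×2×2 threshold grid per aligner —
sizes chosen so a complete run takes well under a minute on one core
while still exercising both identity bands, both gates, indel coordinate
mapping, and the tricky-term flag. The greedy clusterer is quadratic in
the number of sequences with a full pairwise alignment per comparison;
for thousands of references an external word-based clustering tool
behind the same contract is the practical route.

Degenerate inputs are handled as data, not crashes: entries with
out-of-bounds regions are flagged invalid with a reason; families whose
ortholog files fail to parse are recorded in `failures` and skipped;
regions with fewer than two surviving rows are marked untransferable.
Terms in the IDPO:00024–IDPO:00034 range (modification display sites and
similar composition-dependent features) are flagged `tricky` in every
record but never suppressed — the flag is a review marker, not a filter.

## Known limitations

- NorMD constants are this package's own calibrated defaults (see
  above); absolute scores from other NorMD implementations may differ
  even where the reliability ranking agrees.
- The permissive literal length filter keeps short fragments whose
  rejection is deferred to the identity filters.
- No propagation of GO terms along the ontology graph, no taxonomy-level
  summaries, and no live ortholog-database retrieval: ortholog input is
  file-based by contract.
- Transfer confidence is exactly (identity, NorMD); no further scoring.
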