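---
title: "Annotating cluster-organized TCRmu loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating cluster-organized TCRmu loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trmloci)
```

## The problem

Marsupials and monotremes carry a third T-cell lineage whose receptor chain,
TCRmu, is encoded by the *TRM* locus. Unlike the translocon organization of
conventional TCR loci (`[(V)n-(D)n-(J)n-C]`), *TRM* is organized as a series
of self-contained clusters: `[V - D - J - Vj - C]` in marsupials, where Vj is
a germline-joined (pre-recombined) V exon, and `[V1 - D... - J1 - V2 - J2 - C]`
in the platypus, where the second V domain is assembled from V2 and J2 without
D segments. Characterizing such a locus means finding every gene segment,
grouping segments into clusters, deciding which clusters are partial, tracing
duplication patterns from upstream repeat elements, and assigning clusters to
sequence classes by nucleotide identity.

`trmloci` implements that workflow as composable functions plus a single
deterministic driver, `run_pipeline()`, and pairs it with a synthetic-locus
generator (`generate_locus()`) that plants a fully known locus so that every
stage can be validated against ground truth without touching a genome
database.

## Evidence model for gene segments

Segments are located by the three classical routes, used in combination:

* **Homology** (`find_homologous_segments()`): seed-and-extend local
  alignment of known V/Vj/C nucleotide sequences against both strands.
  Exact k-mer seeds (k = 11) on nearby diagonals delimit a window that is
  aligned with Smith-Waterman scoring (match +2, mismatch -3, gap open 5,
  extend 2). A candidate needs identity >= 0.70 over >= 0.60 of the query.
  Within a query family, the best-seeded query is aligned first and
  overlapping hits keep the best alignment; seeded regions backed by a
  single k-mer are ignored (random 11-mer matches are expected every few
  kilobases and never extend).
* **Conserved motifs**: V candidates are anchored by the framework-1
  cysteine, the tryptophan 10-20 codons later, and the framework-3 second
  cysteine 55-80 codons downstream (`v_landmarks()`); J segments by the
  `[FW]GxG` motif.
* **Recombination signal sequences** (`scan_rss()`): heptamer-spacer-nonamer
  motifs with 12 or 23 bp spacers (tolerance +-1). Scoring is
  consensus-weighted: the `CAC` heptamer anchor is obligatory; the remaining
  heptamer positions (`AGTG`) carry weights 3,2,1,1 and the nonamer
  (`ACAAAAACC`) weights 1,2,2,3,3,3,2,1,1, reflecting the functional
  importance of the anchor and the nonamer A-tract. A window's score is its
  matched weight over the total (25). The default reporting floor is 0.70.

Under this weight table the chance that a random position reaches a given
score can be computed exactly (each non-anchor position matches with
probability 1/4): about 1.4e-5 per position, strand and spacer length at
score 0.70, and about 1.8e-6 at 0.80. On a 100 kb locus that is roughly 17
stray hits at 0.70 but only ~2 at 0.80. Consequently the *scan* keeps the
inclusive 0.70 default (callers may want marginal RSSs), while the two
callers that would amplify stray hits into false gene segments demand 0.80:
J annotation (`annotate_j(min_rss_score = 0.80)`) and unconfirmed,
RSS-only D calls (`infer_d_segments(min_flank_score = 0.80)`).

### J segments

`annotate_j()` models the anatomy of a J segment explicitly: the coding
region starts immediately at the heptamer side of an RSS, carries the
`[FW]GxG` motif within 40 bp, is stop-free from the RSS boundary through the
motif in the motif's frame (a J must be translatable), and ends at a `GT`
splice donor within 30 bp of the motif. Each constraint holds for real J
segments and each removes most random motif coincidences; the residual
false-positive rate is what the planted-truth tests measure. Candidates that
fall inside homology candidates (V exons contain J-like motifs), inside a
convergent 12/12 flank-pair core, or across another 12-spacer RSS are
discarded as artefacts of D-region geometry.

### D segments

D segments are too short (~10-15 bp) for homology search. They are inferred
from two independent signals (`infer_d_segments()`):

1. **Junction templating.** Recombined V-D-J transcripts are anchored to
   their best germline V and J (`map_transcript()`, local alignment, anchor
   identity >= 0.85); the transcript residue between the anchors is the
   junction. Exact junction substrings of >= 6 bp matching the germline
   between the V and J are templated blocks. Exact matching, not alignment,
   is deliberate: it is what distinguishes templated (D) nucleotides from
   untemplated N additions.
2. **RSS flank pairs.** `pair_rss_for_d()` finds convergently oriented RSS
   pairs whose heptamers enclose a 3-40 bp core. The default layout expects
   12 bp spacers on both sides (IgH-like); a 12/23 configuration is
   supported via `rss.d_flank_layout`.

A D is reported when supported by two independent junctions, or by one
junction plus a flank pair (interval clipped to the RSS core), or by a
strong flank pair alone — the last flagged *unconfirmed*. The two-junction
rule is this package's confidence convention, exposed as
`junction.min_support`.

### Vj and V subtypes

A germline-joined Vj is detected structurally: a V-homologous candidate
whose 3' tail carries an in-frame `[FW]GxG` motif and which has **no**
downstream 23-RSS (nothing left to recombine). An ordinary V keeps its
downstream RSS, so a chance tail motif cannot misclassify it.

Platypus-style V subtyping follows the defining biology: a V with at least
one D candidate 3' of it before the next V/J/C is Vmu1. A V in cluster
context without such a D is Vmu2. For an isolated V the absence of D is
uninformative, so the call falls back to best reference identity (ties give
Vmu2 with a low-confidence flag).

### Pseudogenes

A V/Vj/C segment is flagged as a presumptive pseudogene when every reading
frame of its span contains a stop codon, or when its alignment to the best
homology query contains a frameshifting indel (gap length not divisible
by 3). This operationalizes the Psi marks of published locus maps, which do
not state explicit criteria.

## Cluster assembly and architecture calls

`assemble_clusters()` groups segments greedily 5' to 3': a cluster is a
maximal run of same-orientation segments with gaps <= `cluster.max_intra_gap`
(default 15 kb, chosen from the spans of published marsupial clusters)
containing exactly one C gene, which terminates the run in transcription
order. D cores are strand-symmetric (their convergent flanks look identical
on either strand), so a D adopts the strand of its nearest non-D neighbour
rather than carrying one of its own. Runs without a C are orphans; reports
tally single-segment groups separately as "singletons", which is how
interspersed platypus C and V genes are counted in the source maps.

Completeness (`call_completeness()`) compares the observed kind multiset
against the expected layout (`V,D,J,Vj,C` marsupial; `V,D,J,V,J,C`
platypus, i.e. two V and two J expected).

Upstream repeat elements — the footprint of repeat-mediated duplication —
are detected by comparing the 2 kb upstream flank (5' in cluster
orientation) of every cluster against every other (`find_upstream_repeats()`);
flank pairs sharing >= 80% identity over >= 500 bp mark copies of a shared
element. A shared-13-mer count prefilter (>= 10) skips unrelated pairs; at
the 80%-identity detection boundary two 1.5 kb copies still share ~80 such
13-mers, so the prefilter cannot mask a reportable pair.
`infer_duplication_pattern()` then reads the architecture: adjacent clusters
of different classes with a repeat before the first only form a tandem
pair; a cluster with its own repeat is a singlet duplication.

## Identity classification

Cluster classes are defined by nucleotide identity. V genes are compared
over the framework-1 through framework-3 span (first to second cysteine,
inclusive, from `extract_fr_region()`; pseudogenes lacking landmarks fall
back to the full span, flagged); C genes over their full span.
`global_identity()` uses Needleman-Wunsch with end gaps penalized
(match +1, mismatch -1, gap open 4, extend 1) and counts identity as
matches over all alignment columns, gap columns included — the convention
of pairwise-identity matrix tools. The external aligner used by such tools
is replaced by this self-contained scoring so results are deterministic.

`assign_classes()` gives each query the label of its best reference when
identity strictly exceeds 0.75 (reading the published "greater than 75%"
rule literally — a query at exactly 75.0% stays unassigned). Unassigned
queries are single-linkage clustered among themselves at the same
threshold; groups of two or more become `new-class-k`. This is how a
platypus-like family below 64% identity to every marsupial reference forms
its own class. Cluster labels are the majority over the cluster's V/Vj and
C assignments, with the V label winning conflicts (flagged); whether the
published rule used V genes, C genes or both is not stated, so both are
used with V priority.

## The synthetic locus generator

`generate_locus()` builds loci from a `locus_blueprint()`: one ancestral
cluster is constructed (V of 100 codons with landmarks at codons 22/36/96
and a 3' 23-RSS; D of 12 bp with 12-RSS flanks; J of 13 codons with the
motif at codons 3-6, a 5' RSS and a GT donor; Vj as the V body with a
joined J block; C of 150 stop-free codons), one archetype per class is
derived from it, and cluster copies are derived from archetypes.

Divergence is i.i.d. substitution. Archetypes sit at half the nominal
between-class divergence from the ancestor and copies at half the
within-class divergence from their archetype, so *pairwise* distances match
the nominal rates. Defaults are 10% within and 40% between class — the
regime of the published identity matrices (within-class pairs well above
the 75% rule, between-class pairs well below it). Mutation is
structure-aware: planted RSSs, landmark codons, the J motif and donors are
protected, and coding spans are mutated codon-wise with stop codons
reverted, so planted intact segments are never pseudogenes and every
planted RSS scores 1.0. V bodies exclude chance Cys/Trp codons so the
planted landmarks are unambiguous. Inter-cluster spacers default to
20-120 kb scaled by `scale = 0.1` (never below 2.5 kb, keeping one
cluster's flank window clear of its neighbour's repeat copy); upstream
repeat copies (1.5 kb at ~2% divergence) are planted per the duplication
mode. Interspersed singleton segments (platypus-style extra V and C genes)
are spaced >= 16 kb from anything else so they can never join a cluster.

`generate_junction_transcripts()` emits recombined V-D-J reads:
V (3' trimmed 0-3 bp) + N additions (0-4 bp) + D core (trimmed 0-2 bp per
side) + N additions + J (5' trimmed 0-2 bp) + the start of C, with ~70%
constructed productive (in frame and stop-free through the J motif). With
6 bp minimum templating and at most 2+2 bp of D trimming, every planted
12 bp D remains identifiable from its junctions.

What the generator does **not** emulate: isochore/GC structure (background
is uniform i.i.d.), genome-wide repeat families (only the planted upstream
elements), rate heterogeneity or codon models, leader exons and introns,
and sequencing error in transcripts. Passing the planted-truth suite
therefore demonstrates the pipeline's logic and its behaviour at the
published divergence regimes, not performance on raw vertebrate genomes,
where homology thresholds and the RSS floor would need tuning through the
exposed configuration.

`blueprint_mirror()` encodes the three published architectures used as
worked examples: the opossum (8 marsupial clusters, two partial lacking V
and D, tandem duplication), the Tasmanian devil (9 clusters; cluster 4
lacking V and D, clusters 8 and 9 lacking V; a mix of tandem pairs and
singlets), and the platypus (5 complete clusters plus 6 extra Vmu1-like and
2 Vmu2-like singleton V genes and 10 singleton C genes, giving 18 V and
15 C in total with 5 C in clusters).

## Determinism, ties and degenerate inputs

* The pipeline uses no random numbers: identical configuration and inputs
  give byte-identical outputs, and all generator randomness is seeded.
* Overlapping RSS hits resolve to the best score, then the spacer closest
  to canonical, then the leftmost; overlapping J candidates to the best
  supporting RSS.
* Alignment tie-breaking is delegated to the underlying dynamic-programming
  implementation, which is deterministic; scores (the tested quantity) are
  tie-free.
* Internal coordinates are 1-based inclusive — the GFF3/Bioconductor
  convention — so emission involves no coordinate shift.
* Empty inputs degrade softly: an empty annotation set yields a report with
  zero counts; a transcript that anchors to only one side is dropped with
  `NULL`; a segment run without C is an orphan cluster flagged as missing C.

## Problem sizes used in the validation suite

The test suite and acceptance script run entirely on synthetic loci at
`scale = 0.1` (inter-cluster spacers 2-12 kb, whole loci roughly 40-400 kb),
with 20 seeded replicates per layout for recovery statistics, 500 short
sequence pairs for exhaustive alignment-oracle comparisons, ten 10 kb
sequences for scanner-oracle comparisons, and 1000 simulated transcripts
for the productivity fraction. These sizes exercise every code path at full
fidelity; the algorithms themselves are linear-to-quadratic in locus length
and run on megabase inputs unchanged.

## Known limitations

* C segments are annotated by homology only; no conserved-motif model for
  C domains is included.
* Leader exons and V introns are not modelled; V coordinates are alignment
  footprints.
* Repeat elements are classified (`family_hint`) only when a user supplies
  a repeat library; otherwise they are reported as `unknown`.
* The duplication-pattern caller implements the repeat-sharing heuristic
  only; it does not reconstruct duplication history or date events.
* Real-genome analyses additionally depend on assembly quality and on
  thresholds that published annotations did not record; the configuration
  object exists precisely to make those choices explicit and reproducible.
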