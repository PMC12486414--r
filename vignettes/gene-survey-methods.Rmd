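---
title: "Methods: an environmental survey pipeline for functional genes"
author: "GeneSurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an environmental survey pipeline for functional genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeneSurvey)
```

## Scope and model

GeneSurvey implements a database-scale survey of a functional marker gene
— the design case is the copper nitrite reductase gene *nirK*, surveyed
across marine and other aquatic environments — as a chain of small,
separately testable operations:

1. **Ingest** — sequences (FASTA) are paired 1:1 with a metadata table
   (accession, domain, environmental source, optional taxonomy ranks).
   Sequences are uppercased and `U` is mapped to `T` on read, because
   public-database exports mix cases and alphabets. Eukaryota records are
   dropped with a logged count; the survey covers Bacteria and Archaea.
2. **Deduplication** — two records are duplicates when their normalized
   nucleotide strings are identical; the accession is not part of the
   key. The earliest record of each duplicate set survives, making the
   operation idempotent and order-preserving.
3. **Length filtering** — inclusive domain-specific floors, 400 bp for
   bacterial and 300 bp for archaeal records by default. Shorter
   amplicons carry too little signal for stable clustering at the
   species-level identity threshold.
4. **Greedy identity clustering** (CD-HIT style) at 87% identity.
5. **Consensus and window extraction** — each large cluster is aligned
   and summarized by a majority-rule consensus; consensus and individual
   sequences enter one master alignment from which the longest
   well-covered contiguous window is cut.
6. **OTU/archetype assignment** at 87% identity on the window region,
   followed by the niche statistics (single-source fractions, per-source
   and per-taxon percentage tables, rank–abundance curves).
7. **Phylogeny** — a neighbor-joining tree over OTU archetypes from
   Jukes–Cantor distances, written as Newick.

The 87% nucleotide identity threshold is the species-level cutoff
established for functional genes (originally calibrated on bacterial
*amoA*) and is the default for both clustering and OTU assignment; both
accept any threshold in (0, 1].

## Pairwise identity

Identity is computed from a global alignment with free end gaps
(overlap alignment): match +1 for an identical `A/C/G/T` pair, −1
otherwise (ambiguity codes and `N` never match — a conservative,
deterministic choice), −2 per internal gap position, terminal gaps free.
Identity is the number of identical aligned positions divided by the
length of the *shorter* sequence. This is the CD-HIT convention: a PCR
fragment nested inside a full-length gene scores as identical, which is
exactly the behavior a mixed whole-gene/amplicon survey needs.

Two numerical details make identity well defined:

* Among all score-optimal alignments, the reported match count is the
  *maximum* attainable one (a second lexicographic layer in the dynamic
  program). Identity therefore does not depend on traceback
  tie-breaking, and an independent re-implementation must agree exactly.
* The emitted alignment itself resolves ties deterministically
  (diagonal, then gap in the second sequence), so aligned output is
  reproducible too.

## Greedy clustering

Records are processed in descending length order (ties broken by
lexicographic accession, mirroring CD-HIT's deterministic sort). Each
record joins the first existing cluster whose representative it matches
at ≥ threshold, else founds a new cluster. Comparison is against
representatives only — CD-HIT semantics — which yields two checkable
invariants: every member is within the threshold of its representative,
and representatives of distinct clusters are pairwise below it. Because
processing is by descending length, the representative is always the
longest member. No k-mer prefilter is implemented; at package scales the
exact quadratic search is affordable and keeps the algorithm equal to
its all-pairs oracle in well-separated regimes.

Clusters with no aquatic-source member are removed (the survey's scope
is aquatic). Clusters with more than 2 members stay clusters; members of
smaller ones are released as individual sequences. `min_large = 3` is
exposed as a parameter because the two-versus-three boundary is a
convention, not a law.

## Consensus and the alignment window

Within-cluster alignment uses a center-star aligner: the center is the
member with maximal summed pairwise identity, every other member is
pairwise-aligned to it, and the pairwise alignments are merged under
"once a gap, always a gap". A progressive aligner with a guide tree
would be more accurate at low identity, but at ≥ 87% within-cluster
identity center-star is accurate, dependency-free and deterministic.
For the master alignment (many rows), the center defaults to the longest
sequence to avoid the quadratic center search.

The majority consensus emits, per column, the most frequent non-gap base
(ties alphabetical) and drops columns that are majority-gap (> 0.5), a
plurality rule equivalent in spirit to emboss `cons` defaults.

Window extraction resolves a bi-objective — the *longest* region where
the *greatest number* of rows overlap — as: fix a coverage floor
(`ceiling(min_coverage_fraction × n_rows)`, default 0.5), then take the
longest qualifying interval, breaking ties by higher coverage and then
leftmost start. A row covers an interval when it is non-gap at both
interval ends and has ≤ 10% internal gaps. Both knobs are exposed; the
floor-first reading is an interpretation, and the package documents it
as such rather than as inherited fact. Coordinates are 0-based
half-open internally; reports are 1-based inclusive.

Rows that fail the coverage rule for the chosen window are excluded and
logged — these are the "did not align in the window" sequences. Whole
clusters whose members cannot even be aligned to their own
representative (mean identity < 0.40) are set aside before consensus,
mirroring the removal of extremely divergent clusters from tree
building.

## OTU assignment and niche statistics

The archetype finder is a greedy maximal-coverage selection: repeatedly
pick the window sequence that matches the most still-unassigned window
sequences at ≥ threshold, assign them, and repeat. Ties prefer the
sequence standing for the larger source cluster, then the
lexicographically smaller id. The original probe-design algorithm this
step stands in for is not published in algorithmic detail; greedy set
cover is the natural concrete realization, it is exact in well-separated
regimes (verified against an exhaustive set-cover oracle in the tests),
and it guarantees the two invariants the statistics rely on: OTU
membership partitions the input, and every member is within the
threshold of its archetype.

Percentages are rounded half away from zero to one decimal — the
convention that reproduces every printed survey percentage — and every
percentage is a pure function of stored integer counts, so tables can be
re-derived exactly. In per-source tables an OTU contributes one count to
*every* distinct source among its members (multi-source OTUs appear
under several bars; the denominator is the number of OTU–source pairs,
so each table still sums to 100 ± rounding). A `majority` rule is
available as an alternative. A post-hoc `hypersaline` relabeling of
flagged `aquatic other` members supports the archaeal hypersaline split.
OTU taxonomy is the most specific rank label shared by at least half of
the classified members, else `unknown`.

## Phylogeny

Distances are Jukes–Cantor, `d = -(3/4)·ln(1 - (4/3)·p)`, with `p` the
mismatch fraction over pairwise-deleted gap columns; window sequences
are near-complete so pairwise deletion loses little. Saturated pairs
(`p ≥ 0.75`) are capped at a configurable maximum (default 5) with a
warning rather than returning infinities; fewer than two shared columns
is an error. Tree inference is standard neighbor joining (via `ape`),
which is deterministic, desk-scale and exact on additive matrices — the
package asserts that property rather than assuming it. Likelihood
inference was deliberately not reimplemented; the trees serve
clade-level structure, not branch-support claims. Negative NJ branch
lengths (a known artifact on noisy matrices) are clamped to zero.

## The synthetic survey generator

Because the original database snapshot cannot be re-downloaded
reproducibly, every stage is exercised on generated surveys with planted
truth. The generator emulates the *geometry* of the real compilation:

* families of related sequences: per-domain root → family ancestors
  (per-site substitution probability `between_family_divergence`) →
  members (`within_family_sub_rate`); substitutions pick uniformly among
  the three other bases, so expected pairwise within-family identity is
  `(1 − r)² + r²/3`, an arithmetic the tests verify empirically;
* two domains with different reference gene lengths (defaults 1105 bp
  bacterial-like, 1425 bp archaeal-like, matching the survey's reference
  genes);
* a fragment model (default: half of the members truncated to 400–800 bp
  windows) emulating the whole-genome/PCR-fragment length mix;
* exact duplicates appended at a configurable rate (default 5%);
* per-family source specificity: a family is single-source with
  probability `p` (default 0.75, the niche-specificity level the survey
  reports), else spans 2–3 sources, each realized by at least one
  member.

Defaults were chosen once, on these grounds: `within_family_sub_rate =
0.03` places within-family identity near 0.94, comfortably inside an 87%
cluster; `between_family_divergence = 0.15` places between-family
identity near 0.73 — below the threshold, yet alignable, as expected for
families of one gene. The well-separated regime used by the
clustering-oracle tests (0.45, between-family identity ≈ 0.37) is set
explicitly where those tests need it. One master seed drives everything;
per-family streams are split from it so regenerating one family does not
disturb the rest, and identical configurations are byte-reproducible.

`plantWindow()` builds alignments whose optimal window is known by
construction: `k = ceiling(floor × n_rows)` rows span exactly the
planted core gap-free, the remaining rows are strictly shorter fragments,
so no longer interval can reach the coverage floor and every qualifying
interval inside the core is shorter. This makes window extraction
testable against both the planted truth and an exhaustive-search oracle.

What the generator does *not* emulate: codon structure and GC bias,
indel processes (substitutions only by default — real length variation
is dominated by fragmentation, which the fragment model covers),
horizontal transfer histories, and database annotation noise. Passing
tests therefore demonstrate algorithmic correctness and statistical
recovery under controlled conditions, not robustness to every artifact
of real survey data.

## Problem sizes and degenerate inputs

The test and acceptance runs use desk-scale problem sizes chosen as the
package's own verification conditions: oracle-equivalence clustering on
~130 well-separated sequences of 300 bp; 50 random staggered layouts for
the window oracle; 40-family surveys for source-specificity recovery;
12-taxon additive matrices for NJ exactness; end-to-end runs of 6
families across both domains. All are deterministic under fixed seeds.

Degenerate inputs are defined rather than accidental: empty input to
deduplication returns empty; zero OTUs make the single-source fraction
an error (not `NaN`); a window request whose coverage floor no interval
meets errors with a suggestion to lower the floor; alignment of fewer
than two sequences, NJ on fewer than three taxa, and empty sequences in
the aligner are hard errors.

## Known limitations

* Center-star alignment degrades below ~50% identity; extremely
  divergent cluster sets are set aside rather than forced into the
  master alignment.
* The exact window search is quadratic in alignment columns; it is meant
  for consensus-level alignments (hundreds of rows, a few thousand
  columns), not raw-read scale.
* Greedy clustering depends on processing order by design (it mirrors
  CD-HIT); only in well-separated regimes is it provably equal to the
  order-free single-linkage partition.
* Taxonomy is taken from the metadata as-is; no lookup service is
  consulted.
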