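---
title: "Fosmid-bridged scaffolding: model, parameters and validation"
author: "fosbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fosmid-bridged scaffolding: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosbridge)
```

## The problem

Long-read whole-genome shotgun (WGS) assemblies of plant genomes break at
repeats, leaving hundreds of contigs. A genetic linkage map can order and
orient many of those contigs along chromosomes, but it fills no gaps, leaves
some contigs misordered, unoriented or unanchored, and cannot expose chimeric
contigs. Locally assembled fosmid contigs — sequences attributable to a ~40 kb
clone pool, so assembled from a tiny fraction of the genome's complexity —
can bridge the junctions between neighbouring WGS contigs. `fosbridge`
combines the two sources of information into chromosome-scale super-contigs
and validates the result against in-silico nicking-site (optical) maps.

## The overlap graph

Each WGS contig is a node with two independently connectable ends (LEFT and
RIGHT). A fosmid contig that carries qualifying sequence overlaps to the ends
of two different WGS contigs becomes an edge between those two node ends.
An overlap qualifies as a connection when

* alignment identity exceeds the round's threshold (99%, then 98%, then 97%),
* the matched length on the WGS contig exceeds 5 kb, and
* the overhang — unaligned WGS sequence between the aligned block and the
  nearer contig end — is below 1 kb.

Alignments that reach neither WGS contig end within the overhang limit are
*internal alignments*: they are rejected as connections but retained as
chimera evidence.

The score of an edge is the sum, over its two overlaps, of
`identity x matched_len`, so longer and cleaner overlaps dominate. (The
published description states which quantities the score depends on without a
closed form; this form is the package's choice.) The *weighted score* of a
pair of node ends is the sum of the scores of all edges joining them that
satisfy the current thresholds, recomputed as the graph changes. The *length*
of an edge is the fosmid sequence between its two overlap intervals; it is
negative when the two WGS contigs themselves share sequence across the
junction.

## The merge procedure

Merging proceeds in rounds of strictly decreasing identity:

1. anchored, map-adjacent pairs (order-index distance 1 on one linkage
   group) at 99% identity;
2. the same at 98%;
3. extension rounds admitting unanchored partners, at 98% and then 97%,
   repeated to a fixpoint;
4. chimera detection and splitting, after which the whole connection
   process is re-run on the updated contig set;
5. a final joining round for residual unanchored contigs.

Within a round the open end-pair with the best weighted score is merged
first. An end whose two best partners tie at the same weighted score is left
open (a conflict); in the unanchored rounds ties resolve to the shortest
edge, and remaining ties stay open. After each merge both ends are retired
and every edge incident to them is removed, which is what keeps the junction
set a union of simple paths — a cycle would require an end with two
junctions. When an unanchored contig joins a linkage group its edges to
contigs anchored on other groups are removed. Each contig is used at most
once across all super-contigs.

Ties beyond the rules above (equal weight and equal shortest edge) are
broken lexicographically by contig id so that runs are deterministic; the
merge journal records every event and the whole pipeline is replayable from
the same inputs.

## Chimera detection and splitting

A chimeric contig — the concatenation of two non-adjacent genomic regions —
is betrayed by its neighbours: the true neighbour of one of its halves
aligns terminally on its own sequence but *internally* on the chimera
(overlap above 5 kb, identity above 98%, both flanks of the aligned block
longer than 1 kb), and at least one fosmid contig connects the neighbour's
end and reaches the breakpoint. The breakpoint is the block edge where both
sequences continue but homology stops — the fusion point. Split pieces
longer than 30 kb re-enter the graph as new nodes; shorter pieces are
retired.

## Sequence emission

Walking a path, each junction is spliced on the fosmid's coordinate axis.
The left contig's aligned block ends at axis position `a2` with a WGS-side
overhang `h_L` (its last `h_L` bases extend past the block); the right
contig's block starts at `b1` with overhang `h_R`. The effective contig
boundaries are therefore `effA = a2 + h_L` and `effB = b1 - h_R`. When
`effB >= effA` the contigs are disjoint on the axis: both are emitted in
full with the fosmid segment `[effA, effB)` between them. Otherwise the
contigs overlap by `effA - effB` bases: the junction region is taken from
the fosmid (as far as it covers it) and the flanking contigs are trimmed to
meet it exactly, because the overlapping region of a WGS contig pair is
where assembly quality is weakest. Reverse complement is applied per
segment, and the fosmid is oriented to the path before splicing. The emitted
length always equals the segment lengths plus the signed junction gaps.

Pseudomolecules concatenate the super-contigs of one linkage group in map
order with 10 kb of `N` between consecutive super-contigs.

## Nick-map concordance

`digest()` records the start positions of the Nt.BspQI motif `GCTCTTC` on
both strands. `align_nickmaps()` chains matched site pairs by dynamic
programming: a chunk between matched pairs may skip up to `max_skip` sites
per map; its cost is a chi-square-like sizing term when the span difference
is within `max(3 * sigma * sqrt(skipped + 1), tol)` and a flat indel penalty
otherwise, so a genuine insertion or deletion stays inside one chain rather
than breaking it. Chain ends are free on both maps, which keeps the score
symmetric under query/ref exchange. The vendor's scoring is proprietary;
this model (defaults sigma = 500 bases, max_skip = 2) is standard
restriction-map alignment practice. Matched intervals whose span difference
reaches 1 kb become indel calls, classed 1–10 kb (mid) or >10 kb (large).
A connecting region is *covered* when an alignment has matched sites on both
of its flanks and *flagged* when it lies inside a called indel; the flagged
fraction of covered connections bounds the connection error rate.
`find_alternative_path()` re-walks the overlap graph between two flanking
contigs of at least 100 kb and returns the best-scored simple path whose
emitted length and nicking-site pattern match the reference map (path
enumeration capped at depth 8 and 10,000 paths).

The sizing jitter of real single-molecule maps means an isolated 1 kb call
from a single molecule is weak evidence; the round-trip validation here
perturbs clean digests with engineered deletions, which isolates the
caller's behaviour from molecule noise. Production use should require
multi-molecule support for mid-class calls.

## Genetic-map utilities

Markers are kept when the parents are homozygous and different and neither
parental genotype falls below 5% of the non-missing calls in the
population. Bin genotyping slides a 50-marker window (stride 1; a disjoint
mode is available via `step = window`) and calls each window by strict
majority of its non-missing genotypes; ties or windows more than half
missing are `unknown` and merge into the flanking bin with more support —
the voting rule is the package's choice, as is placing each breakpoint at
the midpoint between the flanking informative windows. On simulated
crossovers, breakpoints are recovered within ±50 markers at 2% genotype
noise.

## Fosmid pool read selection

Pool-wise read selection ranks reads by coverage x mean tag identity, where
a sequence tag counts only at 97% identity or better and only when aligned
in full length — except at read ends, where more than half the tag must
align. Coverage is the fraction of read bases covered by qualifying tags
(the scale-free reading of "coverage"). Reads are admitted in rank order
until the cumulative bases reach 20x the pool insert size; the boundary read
is admitted. Both the multiplier and the insert size are arguments, so
either reading of "20x" is available.

## The simulator and what it does (not) show

`simulate_genome()` builds a deterministic genome (GC ≈ 0.44) with telomere
arrays at every chromosome end, a diverged centromeric tandem array per
chromosome and dispersed LTR-like repeats. `shred_wgs()` tiles it into
contigs overlapping 5–15 kb at junctions, stores them in random orientation,
fuses a chosen fraction into cross-chromosome chimeras and injects
substitutions per copy. `simulate_fosmids()` guarantees (at any positive
junction bias) one fosmid across every junction, with the rest uniform;
`simulate_anchors()` perturbs order, orientation and membership;
`simulate_nickmaps()` jitters, drops and adds sites. Every output is a pure
function of the seed and parameters.

The default study conditions are two 2.5 Mb chromosomes, 60 WGS contigs and
300 fosmids; the noisy variant adds 5% chimeras, 0.5% substitutions per
contig copy (≈1% identity loss between overlapping copies), 10% unanchored
and 20% unoriented anchors. These sizes exercise every code path in minutes
on one CPU. The invariant-sweep tests use 2 x 250 kb genomes over 50 seeds
for the same reason.

The simulator emulates substitution-style divergence only: contigs and
fosmids have no insertions or deletions relative to the genome, which is
also the assumption of the built-in seeded overlap scanner
(`find_overlaps()` reports gap-free, diagonal alignments, trimmed to the
best-matching segment so internal overlaps — the chimera signature — are not
diluted by non-homologous flanks). Real long-read contigs carry indel
errors; for real data the pipeline accepts external PAF alignments, and
passing the synthetic suites therefore demonstrates the graph, merge,
split and emission logic, not the alignment of indel-rich sequence.
Coverage gaps (junctions spanned by no fosmid) are likewise exercised only
at `junction_bias = 0`; production genomes will leave some junctions
unbridged, which appear as multiple super-contigs per chromosome, as in the
published assembly.

## Numerical choices and degenerate inputs

All internal coordinates are 0-based half-open; AGP output is 1-based
inclusive. Identity is matches over alignment-block length. The scanner
seeds every `min_len/40` bases with 15-mers, votes per exact diagonal,
clusters diagonals within 50 bases and evaluates up to 64 diagonals per
cluster; seeds occurring more than 200 times in the index are skipped as
repeats. Contigs shorter than the fosmid floor (10 kb) are discarded as
fosmids; empty graphs emit one super-contig per contig; a genome aligned to
itself yields no PV; `circularize()` refuses terminal repeats spanning more
than half the contig (tandem duplication, not a circle) and normalizes the
circle to its lexicographically minimal rotation.
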