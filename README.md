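# fosbridge

Fosmid-bridged, genetic-map-anchored scaffolding of long-read genome
assemblies, with optical-map (nicking-site) validation.

## The problem

Long-read WGS assemblies of repeat-rich genomes stop at hundreds of contigs.
A genetic linkage map orders and orients many of them but fills no gaps and
hides chimeric contigs; optical maps validate long-range structure but
cannot place short contigs. `fosbridge` implements the integrative strategy
that closed the gap for a near-complete *indica* rice genome: locally
assembled fosmid contigs (each attributable to a ~40 kb clone pool) bridge
neighbouring WGS contigs on an overlap graph, the linkage map constrains
which bridges are credible, and in-silico nicking-site maps audit the
result. It is aimed at assembly groups who have WGS contigs, a marker-based
map, and localized (fosmid/pool or linked-read) contigs.

## The model

The overlap graph has WGS contigs as nodes — each with an independently
connectable LEFT and RIGHT end — and fosmid contigs as edges. A fosmid
overlap qualifies as a connection when identity > θ (θ = 0.99, 0.98, 0.97 in
successive rounds), matched length > 5 kb and overhang < 1 kb. An edge
joining overlaps *a*, *b* to two contig ends has

    score  = id_a · len_a + id_b · len_b
    length = gap on the fosmid between the two overlap intervals
             (negative when the WGS contigs themselves overlap)

and the weighted score of an end pair is the sum of its valid edges' scores.
Merging is iterative best-weight-first: map-adjacent anchored pairs at
θ = 0.99, then 0.98, then extension with unanchored contigs at 0.98 and
0.97; equal-weight conflicts leave the end open (or take the shortest edge
in the unanchored rounds); merged ends are retired so junctions always form
simple paths, and each contig is used once. Chimeric contigs — overlapped
*in the middle* (> 5 kb, > 98% identity, > 1 kb overhang, fosmid-supported)
by another contig's terminus — are split at the fusion point; pieces > 30 kb
re-enter the graph. Emitted super-contigs use WGS sequence everywhere except
negative-length junctions, where the overlapping region comes from the
fosmid; pseudomolecules join the super-contigs of each linkage group with
10 kb of N. Assemblies are audited by digesting with the Nt.BspQI motif
(GCTCTTC), aligning site maps by dynamic programming, calling 1–10 kb and
>10 kb indels, and searching the graph for alternative paths that match the
map through flagged regions.

## Worked example

Simulate a two-chromosome 5 Mb genome shredded into 60 contigs (5%
chimeras, 0.5% substitutions per contig copy, 10% of anchors dropped, 20%
unoriented), bridge it with 300 simulated fosmids, and score the result
against the known truth:

```r
library(fosbridge)
truth <- simulate_genome(seed = 1, n_chrom = 2, chrom_len = 2500000)
truth <- shred_wgs(truth, n_contigs = 60, chimera_rate = 0.05,
                   sub_error_rate = 0.005)
truth <- simulate_fosmids(truth, n = 300)
truth <- simulate_anchors(truth, unanchored_rate = 0.1, unoriented_rate = 0.2)

res <- run_pipeline(truth$wgs, truth$fosmids, truth$anchors)
length(res$supercontigs)
#> [1] 2
res$chimera_calls[, c("contig_id", "breakpoint", "partner", "overlap_len")]
#>   contig_id breakpoint partner overlap_len
#> 4   chim_01      93391 ctg_044       14776
#> 3   chim_02      89872 ctg_019       11060
#> 2   chim_03      91241 ctg_015        5335

ps <- build_pseudomolecules(res$supercontigs)
nchar(ps$sequences)
#>    chr1    chr2
#> 2500000 2500000
unlist(evaluate(res, truth, ps))
#>       order_accuracy orientation_accuracy   junction_precision
#>            1.0000000            1.0000000            1.0000000
#>      junction_recall        base_identity       chimera_recall
#>            1.0000000            0.9955624            1.0000000
#>       n_supercontigs
#>            2.0000000
```

Each chromosome comes back as a single super-contig of the correct length:
all three injected chimeras were split at their true fusion points (the
breakpoints are the lengths of the chimeras' first halves), every contig is
ordered and oriented as in the truth, and the emitted bases are > 99.5%
identical to the genome (the residue is the substitution noise carried by
the contigs themselves). With `chimera_rate = 0` and `sub_error_rate = 0`
the pseudomolecules are byte-identical to the simulated genome.

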