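---
title: "Calling RNAPII-mediated chromatin loops from in situ ChIA-PET data"
author: "chialoopr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling RNAPII-mediated chromatin loops from in situ ChIA-PET data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

ChIA-PET (chromatin interaction analysis with paired-end tags) couples
chromatin immunoprecipitation with proximity ligation: DNA fragments held
together in one chromatin complex — here, complexes containing RNA
polymerase II — are joined through a biotinylated double-stranded bridge
linker and sequenced as paired-end reads. Each read pair therefore reports
either two ends of one fragment (a ChIP-like binding signal) or the ends of
two different fragments (a chromatin contact). `chialoopr` implements the
complete processing path from raw reads to loop calls:

1. **Linker detection and trimming.** Both mates are scanned for the bridge
   linker; the sequence 5′ of the junction is the genomic tag. Pairs without
   a linker in either mate are discarded.
2. **Tag mapping.** Trimmed tags are mapped either by the built-in
   exact/unique matcher (synthetic genomes) or by an external aligner whose
   SAM output is consumed with a strict mapping-quality filter (MAPQ > 30).
3. **PET deduplication.** PCR duplicates are collapsed on the
   (chromosome, 5′ position, strand) signature of both tags.
4. **Classification.** Same-chromosome PETs with a 5′-to-5′ span below 8 kb
   are self-ligation (binding proxy); larger spans are inter-ligation
   (contacts); different chromosomes are trans.
5. **Clustering.** Inter-ligation PET ends are extended by 500 bp; PETs
   overlapping at both extended ends are merged transitively into PET
   clusters, whose PET count measures contact strength. Unmerged PETs are
   singletons.
6. **Loop filtering.** Clusters with at least 4 PETs, H3K27ac on both
   anchors, and an anchor distance below 1 Mb are loops, optionally
   annotated as promoter/enhancer pairs against a TSS set.
7. **Tracks.** All nonredundant PETs yield a binding-coverage bedGraph; the
   intra-chromosomal inter-ligation PETs (singletons included) yield a raw
   binned contact matrix.

A synthetic read generator plants loops with known anchors and PET counts,
plus configurable self-ligation, trans and intra-chromosomal noise, PCR
duplicates and base errors, so that every stage — and end-to-end loop
recovery — can be scored against ground truth.

# The bridge linker and read splitting

The linker duplex is 19 nt per strand: forward
`CGCGATATCTTATCTGACT` (the biotinylated dT base-calls as a plain T) and
reverse `GTCAGATAAGATATCGCGT`. A read may contain the linker in any of four
orientations (forward, reverse, and their reverse complements), so all four
queries are scanned at every offset.

Matching is pure Hamming distance: a full-length placement tolerates
`max_mismatches` (default 2) substitutions; a placement running off the
read's 3′ end counts as a partial match, must cover at least `min_overlap`
(default 10) bases, and tolerates proportionally fewer mismatches
(`floor(max_mismatches * overlap / 19)`). The best hit is the one with the
fewest mismatches; ties break to the smaller offset, then to query priority
(forward, reverse, forward-rc, reverse-rc).

Two properties of this rule are worth knowing:

* The four queries are not independent strings: `revcomp(reverse)` equals
  `"A"` followed by the first 18 bases of the forward sequence, a
  consequence of the duplex's single-base overhang. When the genomic base
  immediately 5′ of a forward junction happens to be `A`, the shifted
  variant matches exactly one base earlier and wins the tie. The trimmed tag
  is then one base shorter than the planted fragment. This is inherent to
  any per-offset best-match rule over these sequences, affects roughly a
  quarter of junctions, and is immaterial downstream (tags remain uniquely
  mappable; 5′ positions are unchanged).
* One-sided pairs are kept: if only one mate contains the linker, that mate
  is split and the other is used whole, provided both resulting tags reach
  `min_tag_len` (default 18 bp). The protocol guarantees a linker inside
  the ligation product but not inside both 150-bp windows of it.

When a read contains linker concatemers, only the sequence 5′ of the best
(first) hit is kept: the 5′ fragment is the only part unambiguously
assignable to one genomic locus.

# Mapping and deduplication

For synthetic genomes the package maps tags itself: a tag is accepted only
when it has exactly one exact occurrence genome-wide (both strands
searched), reported with MAPQ 60. This matcher is deterministic and
oracle-checkable; it is intentionally strict (no mismatches) because
simulated reads carry few errors and ambiguity is the property under test.
Real libraries should be aligned externally (e.g. `bwa mem` on the trimmed
tag FASTQs) and enter through `read_sam_pairs()`, which keeps only pairs
where both mates are primary, mapped, and have MAPQ strictly greater
than 30 — `mapping quality greater than 30` read verbatim, so MAPQ 31
passes and 30 does not.

Duplicates are removed at the PET level: two PETs are copies when both tags
agree on (chromosome, 5′ position, strand). Alignment spans are ignored,
matching the coordinate semantics of Picard MarkDuplicates without CIGAR
logic; PET-level removal is also order-independent, which makes reruns
byte-identical. The first-seen PET survives.

# Classification and the 8-kb boundary

The span of a same-chromosome PET is the absolute difference of the two
tags' 5′ positions — independent of read length and of which mate sequenced
which end (tags are stored in canonical genome order). Spans strictly below
8,000 bp are self-ligation; the complement, including a span of exactly
8,000, is inter-ligation, because the self-ligation class is defined
strictly ("fewer than 8 kb") and the boundary falls to the other side.
Interchromosomal PETs form the trans class; they are counted and exported
but never clustered, since the 1-Mb distance filter makes trans loops
impossible by construction.

# Clustering

Each tag occupies a reference interval derived from its 5′ position,
strand, and alignment span (a 50-bp default span is assumed when a PET
table arrives without spans). Both intervals of every inter-ligation PET
are extended by `anchor_extension` = 500 bp, clipped at chromosome bounds.
Two PETs are linked when their extended first intervals share at least 1 bp
AND their extended second intervals share at least 1 bp (half-open
semantics: abutting intervals do not overlap). Clusters are the connected
components of this link graph — transitive closure, not seed-greedy
merging, because closure is the only order-independent reading of "grouped
as a single PET cluster". Candidate links are found with interval trees
(`IRanges::findOverlaps`) and merged with union-find; the result provably
equals the brute-force O(n²) pairwise test, and the test suite asserts that
equality on random instances.

Reported anchors are the min-start/max-end hulls of the members'
*unextended* intervals: the extension is a merging device, not a coordinate
change, and tight anchors matter for the downstream peak-overlap filter.
Because anchors per PET are sorted, only the straight pairing (first anchor
with first anchor) can link two PETs; the crossed pairing cannot arise.
Given the 8-kb self-ligation cutoff, anchors of one cluster cannot overlap
as long as the extension stays below 4 kb; this is asserted, not assumed.

# Loop filters and annotation

The three filters run in a fixed order with per-filter rejection counts:
PET count ≥ 4 first ("clusters with PET counts less than four were
removed"), then H3K27ac presence on both anchors (≥ 1 bp overlap with any
peak — presence, not fraction), then anchor distance < 1 Mb. The filters
commute in outcome (the kept set is the intersection of three independent
predicates); only the attribution of rejections to filters depends on the
order. Anchor distance is measured midpoint-to-midpoint: the source
protocol does not fix an endpoint convention, and midpoints are symmetric
and stable when anchors widen. H3K27ac peaks are an input BED — the package
performs no ChIP-seq processing.

Annotation classes each anchor by precedence: promoter if it overlaps a
TSS ± 2 kb window (the promoter window is configurable; 2 kb per side is a
common operational definition), else enhancer if it overlaps an H3K27ac
peak, else other. The per-gene loop degree — the number of distinct distal
anchors connected to a gene's promoter — summarises promoter hubs such as
a TSS contacted by multiple distal enhancers.

`validate_outputs()` re-checks every emitted loop with a naive independent
implementation of the three predicates (plain arithmetic, no interval
library), so a regression in the pipeline cannot hide in shared code.

# Coverage and contact matrices

Binding coverage counts, per fixed-width bin (default 100 bp), the number
of tag intervals overlapping the bin, over *all* nonredundant PETs —
self-ligation PETs are the ChIP-fragment proxy, and inter-ligation tags
also mark binding. Peak calling on this track is out of scope; the track is
exported as bedGraph (zero bins suppressed) for external callers. Contact
matrices bin the two 5′ positions of each intra-chromosomal inter-ligation
PET (default 25 kb bins); canonical tag order makes the stored triangle
i ≤ j, and the total mass equals the contributing PET count exactly. Counts
are raw by design; normalisation belongs to dedicated tools.

# The simulator

`simulate_genome()` draws i.i.d. bases at a configurable GC fraction
(default 0.45, close to mouse). `simulate_library()` plants `n_loops`
loops: anchor 1 and anchor 2 are `anchor_width` = 500 bp windows separated
by 20–400 kb, and each loop receives `pets_per_loop` PETs (fixed, or
negative-binomial when a dispersion is set) with tag 1 drawn uniformly
inside anchor 1 (plus strand) and tag 2 inside anchor 2 (minus strand) —
the convergent geometry of a ligation product. Anchors are rejected and
resampled when they come within 2 × 500 bp + anchor width of any previously
placed anchor: distinct loops in real data occupy distinct loci, and
without the guard two planted loops could merge into one cluster, turning
the clean-recovery property into a coin flip.

Each mate concatenates tag-proximal genomic sequence, the linker (forward
in mate 1, reverse complement in mate 2), and carry-over sequence from the
partner fragment, truncated to 150 bp. Tag lengths are uniform on 40–90 bp
by default, so junctions fall inside both mates; configuring tags near the
read length produces one-sided and 3′-partial linker reads, which the tests
exploit. Nuisance reads are fractions of the total library: self-ligation
products (both tags from one fragment, 5′ span 399–7,998 bp; default 40%,
the dominant class in real libraries), trans contacts (5%), random
intra-chromosomal pairs (5%), and exact PCR copies of already-emitted pairs
(10% extra). Substitution errors (default 0.1% per base) are applied at
assembly; duplicates copy the post-error bytes, as PCR does. H3K27ac truth
peaks are anchors ± 250 bp for a configurable fraction of anchors, so
uncovered anchors become planted negatives for the peak filter.

What the simulator does **not** model, and what passing tests therefore do
not show about real data: AluI fragment-size structure (tag sampling is
uniform within anchors), base-quality profiles, chimeric mis-ligations
between complexes, mappability variation and repeats (the i.i.d. genome
makes 40-bp tags essentially always unique), and linker concatemers. The
pipeline's behaviour on those features is exercised only indirectly (e.g.
the concatemer policy via constructed fixtures).

# Determinism and numerical choices

All simulator randomness flows from one integer seed (genome and library
use distinct derived streams); the analysis stages contain no randomness,
so a configuration determines every output byte. Sorting uses
locale-independent radix order on chromosome names. Coordinates are 0-based
half-open everywhere in memory; BED/BEDPE pass through unchanged and SAM
positions are converted once on input. Degenerate inputs are legal where
biology allows them: a PET with identical tag coordinates (span 0), empty
libraries, empty cluster sets and empty loop files all flow through and
produce empty, well-formed outputs.

Problem sizes used by the tests and the reproduction script — 2 × 1 Mb
genomes, 10 loops × 6 PETs, 100-instance clustering oracles, 10⁵-PET dedup
tables — were chosen as the smallest scales at which every contract
(recovery, conservation, oracle equality) is non-trivially exercised.

# Known limitations

* The built-in matcher is exact-match only; real reads with errors in the
  tag must go through an external aligner and the SAM path.
* Cluster significance is count-based filtering only — no hypergeometric or
  FDR model; the protocol filters by count, not p-value.
* Trans PETs are reported but never clustered; trans-chromosomal hubs are
  out of reach by design.
* `score_recovery()` matches loops greedily one-to-one by midpoint
  distance; pathological many-to-one geometries could in principle be
  matched suboptimally, which matters only at slack values far above the
  anchor scale.
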