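# chialoopr

Processing pipeline for **RNA polymerase II in situ ChIA-PET** data:
from raw paired-end reads to RNAPII-mediated chromatin loops, with a
ground-truth read simulator for end-to-end verification.

## The problem

ChIA-PET joins DNA fragments that are held together in one chromatin
complex through a biotinylated **bridge linker**
(forward strand `CGCGATATCTTATCTGACT`, reverse strand
`GTCAGATAAGATATCGCGT`) and sequences the products as 2 × 150 bp read
pairs. Each pair is a paired-end tag (**PET**) and reports either two ends
of one fragment (a ChIP-like binding signal) or the ends of two fragments
bridged in the same complex (a chromatin contact). For libraries pulled
down on RNA polymerase II, the contacts are enhancer–promoter loops.

The pipeline implements the standard processing contract for such
libraries:

* detect and trim the bridge linker in every mate (four orientations,
  Hamming matching, 3′-partial hits allowed); keep only pairs with a linker;
* map the flanking tags (built-in exact/unique matcher for synthetic
  genomes, or any external aligner via SAM with MAPQ > 30);
* remove PCR duplicates on the (chrom, 5′ position, strand) signature of
  both tags;
* classify PETs by 5′-to-5′ span: **self-ligation** (same chromosome,
  span < 8 kb), **inter-ligation** (span ≥ 8 kb), **trans**;
* extend both ends of inter-ligation PETs by 500 bp and merge PETs that
  overlap at both extended ends into **PET clusters** (transitive closure);
  unmerged PETs are singletons;
* call **loops**: clusters with PET count ≥ 4, H3K27ac peaks on both
  anchors, and anchor distance < 1 Mb; annotate anchors as
  promoter/enhancer against a TSS set;
* export binding coverage (bedGraph) and a raw binned contact matrix (COO
  text).

A simulator (`sim_config()`, `simulate_library()`) generates libraries
with planted loops, self-ligation/trans/intra noise, PCR duplicates and
base errors, and records per-read truth labels, so recovery can be scored
exactly (`score_recovery()`).

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
library (2 × 1 Mb genome, 10 planted loops × 6 PETs, 40% self-ligation,
5% trans, 5% intra noise, 10% PCR duplicates, 0.1% base errors):

```sh
Rscript analysis/01_simulate_library.R
Rscript analysis/02_process_pets.R
Rscript analysis/03_call_loops.R
Rscript analysis/04_coverage_contacts.R
Rscript analysis/05_recovery_benchmark.R
```

Output of a run (`results/` holds the tables):

```
linker rate: 1.000 (132 of 132 pairs)
mapped PETs: 111 of 132 tag pairs (unmapped 21, multimapped 0)
nonredundant PETs: 101 (10 PCR duplicates removed)
        category  n   fraction
1  self_ligation 40 0.39603960
2 inter_ligation 55 0.54455446
3          trans  6 0.05940594

clusters: 10  singletons: 6
           filter  n
1       pet_count  6
2 h3k27ac_anchors  0
3 anchor_distance  0
4            kept 10
loops called: 10        # all of class promoter-enhancer

noisy library: precision 1.00 recall 1.00 (10 called / 10 truth)
depleted library (3 PETs/loop): loops called = 0
```

Reading this: every simulated pair carries a detectable linker; 21 pairs
are lost to the exact matcher because a substitution error fell inside a
tag; the 10 planted duplicates among the mapped pairs collapse in dedup;
the six singleton clusters (noise and under-clustered PETs) fail the
PET-count filter; the ten surviving clusters match the ten planted loops
exactly (precision = recall = 1 at 500-bp slack). Re-simulating with only
3 PETs per loop calls zero loops — the count filter is exact.

Equivalent one-call form:

```r
library(chialoopr)
res <- run_all("out", sim = sim_config(seed = 1))
res$recovery$precision   # 1
res$manifest             # per-stage counts, parameters, output hashes
```

## Layout

* `R/` — the package: formats I/O, linker processing, alignment adapter,
  classification, clustering, loop filtering, coverage/contacts,
  simulator, orchestration (`run_all()`, `validate_outputs()`).
* `analysis/` — numbered narrative drivers over the package.
* `tests/testthat/` — unit, property and acceptance tests (oracle
  equivalence against exhaustive scans and brute-force clustering).
* `vignettes/chialoopr-methods.Rmd` — the methods notes: model,
  parameters, simulator scope, design decisions, limitations.
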