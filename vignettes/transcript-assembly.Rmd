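---
title: "Assembling full-length transcripts from UMI and internal single-cell reads"
author: "umisplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling full-length transcripts from UMI and internal single-cell reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umisplice)
```

## The problem

Smart-seq3-style single-cell RNA-seq libraries contain two very different
kinds of reads. *UMI reads* carry a unique molecular identifier ligated to
the 5' end of the RNA: they are strand-specific, pile up near the
transcription start site, and are sparse along the rest of the molecule.
*Internal reads* come from fragmented cDNA: they cover the gene body almost
uniformly, like bulk RNA-seq, but have no UMI, no usable strand of their
own, and a markedly higher rate of intronic and intergenic contamination.
Assemblers that pool both kinds of reads indiscriminately inherit the worst
of both: contaminated splice graphs from internal reads and no way to
anchor transcript boundaries.

`umisplice` treats the two read classes asymmetrically at every stage:
internal reads supply coverage and junction evidence, while UMI reads
supply strand, locus credibility, and transcript start sites.

## Pipeline and model

`assemble_cell()` runs, in order:

1. **Classification and fragment building.** A read is a UMI read iff its
   UB tag is present and non-empty. Mates sharing a query name are merged
   into one *fragment*; blocks are unioned, junctions are taken from the
   N CIGAR operations. Fragment strand comes from the aligner's
   transcript-strand tag (XS) for spliced reads, from splice-site
   dinucleotides (GT..AG / CT..AC) when a genome is supplied, or — for UMI
   fragments only — from the first mate's orientation, relying on the FR
   specificity of UMI reads.
2. **PCR deduplication.** Fragments with identical chromosome, positions
   and CIGAR are one molecule; the first in coordinate order is kept.
   Upstream duplicate flags are honoured. Dedup is always per cell, never
   across cells.
3. **Locus formation and strand rescue.** Strand-resolved fragments are
   clustered into loci (spans merged when they overlap or sit within
   `cluster_gap` = 50 bp). Junction-free internal fragments with unknown
   strand inherit the strand of any UMI-supported locus within
   `nearby_window` = 100 bp; when loci on both strands qualify the fragment
   is counted on both. Loci with fewer than `min_umi_count` = 2 UMI
   fragments or a UMI fraction below `min_umi_ratio` = 0.05 are purged as
   likely internal-read contamination and reported, not assembled.
4. **Splice graph.** Junction endpoints define splice sites; each maximal
   covered run between sites becomes a vertex with mean per-base coverage
   `w_v` and UMI support `w_m` (the number of distinct post-dedup UMI
   fragments overlapping the vertex). Junction edges and read-through
   edges across abutting boundaries carry fragment counts `w_e`. A source
   feeds every vertex with no in-edge and every vertex with no out-edge
   drains into a sink, weighted by the number of fragments starting or
   ending there.
5. **Pruning.** Three rules, applied full → partial → isolated, each with
   simultaneous per-pass removal iterated to a fixed point (candidates are
   judged against the pass-start state, which makes the result independent
   of vertex enumeration order):
   * *Full intron retention*: a vertex immediately joint to its single
     predecessor and successor and skipped by a direct edge is removed when
     its coverage or flanking read-through weights are small relative to
     the skipping edge (factors `a1 = a2 = a3 = 0.25`) and its UMI support
     is at most `a4 = 1` — or, regardless of UMI support, when its coverage
     is at least `a5 = 5` times its strongest read-through edge, the
     signature of a PCR-amplified intron lariat.
   * *Partial intron retention*: a source-adjacent vertex reading through
     into a successor that also receives stronger competing in-edges (max
     weight `w'`) is a false alternative first exon; it is removed when its
     coverage or read-through weight is below `b1 = b2 = 0.2` times `w'`
     and its UMI support is at most `b3 = 1`. The sink-adjacent mirror
     handles false alternative last exons.
   * *Isolated vertices*: a vertex touching only source and sink is kept as
     a single-exon candidate only with UMI support of at least
     `single_exon_min_umi` = 2.
6. **Phase-preserving decomposition.** Each fragment maps to the ordered
   chain of surviving vertices it overlaps (its *phasing path*); fragments
   touching removed vertices or contradicting surviving edges are dropped.
   Chains are visited in decreasing multiplicity and, for each chain not
   yet contained in an emitted path, the source-to-sink path through it
   with maximum residual bottleneck is peeled off, with the bottleneck as
   abundance. Read coverage is not flow-conserved — UMI reads inflate
   5'-side weights — so a chain can find its shared edges already
   exhausted; it is then routed through the least-starved path and its own
   chain edges set the abundance. Remaining residual flow is peeled along
   unconstrained widest paths. Ties always resolve toward the vertex
   earlier in genomic coordinate, making the decomposition deterministic.
7. **First-exon anchoring and floors.** Because UMIs mark the RNA 5' end,
   a candidate transcript survives only when its 5'-terminal exon (first
   path vertex on `+`, last on `-`; support is the maximum `w_m` over the
   merged vertices) has at least `first_exon_min_umi` = 1 UMI fragments.
   Plumbing floors on predicted coverage (1.0) and length (150 bp) drop
   residual slivers; both can be disabled by setting them to 0.

`meta_assemble_cells()` pools all cells' deduplicated fragments into a
"super-cell", assembles it with the same pipeline, assigns each pooled
transcript to every cell whose fragments overlap at least 30% of its exons
(counted as exons by default, with an exonic-bases mode available; an exon
counts as supported from one aligned base),
and unions the assignments with each cell's own assembly, keyed by intron
chain for multi-exon and by exon interval for single-exon transcripts. On
key collisions the single-cell record wins, preserving its coverage.

## Evaluation

`evaluate_assembly()` follows the gffcompare convention: a multi-exon
prediction matches when its ordered intron chain is exactly that of a
same-chromosome, same-strand reference transcript; single-exon predictions
are excluded from both numerator and denominator. `adjusted_precision()`
implements coverage-ascending filtering: predictions are removed in
ascending predicted coverage (ties by coordinate) until the matching count
equals a baseline, allowing precision comparison at controlled
sensitivity.

## What the generator emulates — and what it does not

`simulate_dataset()` fabricates gene models and per-cell SAM alignments
with the read-class asymmetries the assembler targets: UMI fragments are
FR-oriented with probability 0.85 and start at geometrically decaying
offsets from the 5' end (rate 0.02, mean ≈ 50 bp); internal fragments are
50/50 FR/RF and tile the body on a 60 bp stratified grid, which guarantees
gap-free exon coverage; exact-copy PCR duplicates are injected at rate 0.1;
junction-free contaminants can be placed inside introns, and dedicated
modes inject read-through fragments that fully or partially cover an
intron, reproducing the retention artifacts the pruning rules remove.

Several properties are enforced structurally rather than left to chance,
because the package's recovery guarantees are stated for data that has
them: every transcript receives two FR UMI fragments anchored in its first
exon; every junction is crossed by at least five fragments (extra internal
fragments are centred on under-observed junctions); distinct molecules
never share an identical alignment (colliding draws are nudged by a few
bases, preserving their junction sets — identical alignments are, by
definition, the PCR duplicates); and multi-isoform loci differ in exactly
one alternative event (a skipped or mutually exclusive exon), so each
isoform owns at least one junction and junction phasing identifies it.

Real data are harsher in ways the generator deliberately does not model:
sequencing errors and soft-clipping, degraded or truncated molecules,
coverage dropout inside exons, overlapping genes, isoforms that differ
only in transcript ends, and shallow loci whose junctions are seen once.
Passing the packaged tests therefore demonstrates correctness of the
algorithmic contracts — classification, pruning inequalities, phasing
preservation, anchoring, union semantics, determinism — not performance on
arbitrary tissue data.

## Numerical and design choices

* Coordinates are 0-based half-open internally; conversion to 1-based
  closed happens only when reading/writing GTF and SAM.
* The pruning thresholds above are this package's own calibration, chosen
  permissive (a retention must be several-fold weaker than the evidence
  that skips it) and exposed in `ir_params()` / `locus_filter_params()`.
* Source/sink attachment: the source connects exactly to vertices with no
  in-edge (and the sink mirror). A rule that also attaches the source to
  any vertex where fragments begin was considered and rejected: internal
  reads begin everywhere, and in particular inside retention vertices,
  which would make every retention "source-adjacent" and structurally
  immune to the full-retention rule. The adopted rule matches the worked
  example the pruning rules are illustrated on, at the cost of not
  modelling alternative starts that begin flush inside read-through
  regions.
* The decomposition is a greedy stand-in for the phase-preserving
  decomposition family: it guarantees that every supported phasing chain is
  contained in some reported path and that reported paths are
  edge-consistent, but it does not minimise path count. The interface
  isolates it (`decompose_graph()`) so a different decomposition can be
  swapped in.
* "Nearby" in strand rescue is the distance between interval closest
  edges, 0 when overlapping. Both-strand assignments count at full weight
  on each strand.
* Whether dedup should act within or across read types is ambiguous; the
  duplicate key ignores the UB tag, so dedup acts across all fragments of
  a cell.
* Problem sizes in the packaged tests (50-locus single-cell datasets,
  1000 twelve-vertex graphs for the pruning cross-check, 5-cell
  meta-assemblies) were chosen as the smallest at which every contract is
  exercised with all locus archetypes present many times over.

## Known limitations

* Transcript ends are as observed: no TSS/TES refinement beyond UMI
  anchoring, and no recovery of transcripts whose start lies flush inside
  a read-through region of another isoform.
* No UMI sequence error correction; UB values are taken verbatim.
* Abundances are decomposition bottlenecks, not model-based estimates; use
  them for ranking (as the adjusted-precision procedure does), not as
  expression quantification.
* Annotation-free by design: the reference GTF is used only by the
  evaluation module.
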