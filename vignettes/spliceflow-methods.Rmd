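---
title: "Assembly of long-read transcripts by phasing-path-preserving splice graph decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly of long-read transcripts by phasing-path-preserving splice graph decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceflow)
```

## The model

spliceflow assembles transcripts from spliced long-read alignments one locus
at a time. A locus ("bundle") is a maximal single-linkage cluster of
alignments on one chromosome strand, chained while consecutive records start
within `bundle_gap` of the running end. Per bundle it builds a **splice
graph**: a DAG in genomic coordinate order whose internal vertices are
partial exons — the pieces of the covered genome cut at every splice
position, every inferred transcript boundary, and every zero-coverage gap —
and whose edges are junctions (weight = supporting reads), adjacencies
between abutting partial exons (weight = reads crossing the breakpoint), and
links from a virtual source *s* / to a virtual target *t*. Source/sink links
carry the count of reads whose alignment starts (ends) inside the vertex, so
every edge weight is in read units and a single path through a uniformly
covered locus can fit all of its edges exactly.

The defining constraint is the **phasing path**: the ordered chain of
partial exons covered by one read, kept whenever it spans more than two
vertices. A read covers terminal chain vertices possibly partially (long
reads are end-truncated) but must be junction-compatible: at each of its
introns the flanking segments must end/start exactly at the corresponding
vertex borders. Identical chains merge with summed support; a chain that is
a contiguous subsequence of a longer one remains its own constraint — it is
a weaker statement by a different molecule, not a duplicate.

### Decomposition

Decomposition produces weighted *s*–*t* paths meeting three objectives in
priority order: preserve every phasing path, fit the edge weights, keep the
path count small.

1. **Seeding.** Each *maximal* phasing chain (not a contiguous subsequence
   of another) is grown into a full *s*–*t* path by greedy extension: at the
   frontier vertex the incident edge of largest weight is taken, unless a
   phasing path running through the frontier forces the step; ties break to
   the lower vertex index. The seed contains its chain contiguously by
   construction, which is what makes preservation a structural guarantee
   rather than an optimization target. With no phasing paths at all (e.g. a
   locus of single-exon reads), the single maximum-bottleneck *s*–*t* path
   is seeded.
2. **Abundance fit.** Path abundances solve
   `min Σ_e |w_e − Σ_{p∋e} x_p|, x ≥ 0` as a linear program via the
   standard absolute-value split, using the simplex method (`boot::simplex`)
   — deterministic for fixed inputs. The L1 objective is the natural match
   for a linear-programming fit and is robust to a single aberrant edge.
3. **Peeling.** While some edge's positive residual is at least
   `peel_floor`, the maximum-bottleneck (by residual) *s*–*t* path through
   the largest-residual edge is added and the LP refit; edges whose
   bottleneck path is already a candidate are skipped for the next-largest.
   This terminates within one added path per edge and realizes "few paths"
   as a residual floor of one read: structure supported by less than one
   unexplained read never spawns a transcript.

Candidates below `min_transcript_coverage` are then dropped — unless the
drop would leave a phasing path uncovered, in which case its
highest-abundance covering candidate is retained. The reported
`l1_deviation` is the final LP objective before this filter.

We deliberately do not reproduce the iterative vertex-splitting
decomposition of the short-read predecessor of this approach; the contract
asserted throughout the test suite is the three objectives above, and the
seed/fit/peel realization satisfies it with far less machinery. One known
consequence: when greedy seed extension departs from the (unknown) true
path, a planted-weight graph may retain non-zero deviation even though some
candidate set could reach zero. The guarantees we do make — every phasing
path preserved; deviation zero whenever the weights are exactly realizable
by the seeded candidates; deviation never above the seeds-only fit — are the
ones tested, on 200 random planted graphs per run.

### Boundaries from read classes

Full-length reads (5′ primer + 3′ primer + polyA) anchor both transcript
ends; single-primer reads anchor one; internal reads none. A read with both
primers but no polyA is treated as 5′-anchored only: without the polyA
signal the 3′ end is not trusted. All boundary and splice positions of a
bundle are sorted together and scanned for maximal runs of same-type
boundary events, uninterrupted by any splice event or other-type boundary
and spaced at most `boundary_allowance` apart. A run of at least
`min_boundary_reads` yields one call — leftmost position for 5′ runs,
rightmost for 3′ (mirrored on the reverse strand) — which both cuts the
partial-exon segmentation at the call position (a boundary inside an exon
splits the vertex; the call then anchors the appropriate side) and links the
vertex to *s* or *t*. Vertices with no incoming (outgoing) edges always
receive *s* (*t*) links regardless of boundary support, so the graph stays
decomposable; boundary information adds structure, it never removes it.

### Alignment smoothing

Long-read errors are indel-dominated, so CIGAR operations are smoothed
before any position is extracted: insertions are invisible on the
reference; deletions of *any* length merge into the current segment
(counting toward coverage); `N` operations open a junction only at or above
`min_intron_size` — below it they merge like deletions, removing the false
junctions that aligners emit for long deletion errors. The intron filter on
`N` is the paper-facing control for spurious junctions; capping deletion
length as well would add a second, redundant knob, so we merge all `D` ops.
Records whose CIGAR begins or ends with a kept intron, or that contain an
empty segment between two kept introns, are rejected with a warning.
Alignments lacking a transcript-strand tag (`XS`, or `ts` relative to the
mapping strand) have unknown strand and are placed in both strand bundles,
so neither interpretation is lost at the cost of a possible duplicate.

### Clustering

Nearly redundant predictions — same junction count, every junction within a
summed donor+acceptor distance of `max_cluster_intron_distance` — are
single-linkage clustered per chromosome and strand (a sorted sliding window
over first donors makes this equivalent to all-pairs); each connected
component is replaced by its highest-abundance member (ties: longer span,
then leftmost, then lexicographic id), with abundance set to the component
sum and its end-exons extended to span the component. Single-exon
transcripts pass through: the similarity predicate is defined on splice
positions and is undefined without them.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_intron_size` | 50 | bp | smallest `N` op kept as a junction |
| `bundle_gap` | 50 | bp | locus chaining gap (exposed; loci in practice are separated by far more) |
| `min_mapping_quality` | 1 | — | drops unplaced/ambiguous primaries (255 = unavailable is kept) |
| `min_boundary_reads` | 3 | reads | concordant boundary reads required for a transcript-end call |
| `boundary_allowance` | 10 | bp | max spacing inside a boundary run; mirrors the clustering allowance |
| `max_cluster_intron_distance` | 10 | bp | per-junction `|Δdonor|+|Δacceptor|` clustering allowance |
| `min_transcript_coverage` | 1.0 | reads | abundance floor for reported transcripts |
| `peel_floor` | 1.0 | reads | smallest residual worth an extra path |

## The simulator

`simulate_reads()` emulates the data model the assembler is built for:
non-overlapping multi-isoform genes whose isoforms are exon-skipping
variants of a full chain (at least four exons whenever a skip variant
exists, so isoforms always share a junction and force branching splice
graphs); per-isoform read depth; length-dependent 5′/3′ truncation with a
logistic default centred at 2500 bp and scale 500 bp — full-length reads
become the minority beyond ~2.5 kb, reflecting incomplete cDNA synthesis;
and indels injected inside exon matches at `indel_rate` (default 0.01,
CCS-like) without moving the reference footprint, so the truth table stays
exact. Truncation determines the read class: nothing lost → full-length;
5′ lost → 3′-anchored; 3′ lost → 5′-anchored; both → internal. Reads are
emitted as pre-aligned SAM (flag 0, `SEQ *`, transcript strand in `XS` for
spliced reads only), keeping the pipeline aligner-free and text-only;
unspliced reads deliberately lack a strand tag and exercise the
both-strands path.

What the simulator does **not** model: substitution errors and quality
strings, alignment ambiguity and mapping error, strand-misassigned spliced
reads, overlapping genes, expression heterogeneity across isoforms,
internal priming artifacts. Passing the end-to-end tests therefore
demonstrates the algorithmic contract (graph construction, preservation,
fitting, clustering) under the stated error model — not robustness to every
artifact of real PacBio data.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout; conversion to 1-based
  inclusive happens only at the GTF boundary.
* The LP is solved with a generous iteration cap and `eps = 1e-9`;
  non-convergence is a hard error naming the locus, not a silent fallback.
* All tie-breaks are deterministic (lower vertex index, then lexicographic
  order); two runs on identical input produce byte-identical GTF.
* Empty input yields an empty assembly with a warning, exit status 0 at the
  CLI.
* Reads absent from the classification table are `NFL_INTERNAL` (no
  boundary claim) with a warning; conflicting duplicate classification rows
  are a hard error naming the read.
* Abundance is raw read support; no RPKM/TPM normalization is attempted.

## Test problem sizes

The property suites run on 200 random planted graphs of up to 7 internal
vertices and 4 phasing paths; end-to-end tests simulate 20 genes with 2–3
isoforms at depth 5, matching the conditions under which exact recovery is
the correct expectation. These sizes were chosen as the smallest at which
every code path (branching graphs, truncation classes, clustering, strand
duplication) is exercised.

## Known limitations

* Path-count minimality is heuristic (the exact problem is NP-hard); the
  bound is `maximal phasing paths + peel iterations ≤ maximal phasing paths
  + edges`.
* One prediction can match at most its own intron chain; one-to-many credit
  between predictions and references is resolved by counting each reference
  once.
* Unknown-strand single-exon loci are reported on both strands; downstream
  consumers wanting one copy should drop one strand or supply strand tags.
* The clustering consensus re-spans its component but is not re-quantified
  beyond abundance summation.
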