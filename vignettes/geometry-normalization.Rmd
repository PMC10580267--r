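---
title: "Fragment geometry, read normalization, and augmented references: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment geometry, read normalization, and augmented references: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screadkit)
```

This vignette records how the package's core procedures are defined, the
choices that were genuinely open when they were designed, and what the
synthetic-fixture-based validation does and does not demonstrate.

## The geometry language

A fragment geometry assigns every base of a read pair to a segment:
barcode (`b`), UMI (`u`), discard (`x`), biological (`r`), or a fixed
anchor sequence (`f[SEQ]`). Lengths are fixed (`b[16]`), ranged
(`b[9-10]`), or unbounded (`x:`). The grammar admits no whitespace and
anchors are uppercase A/C/G/T only, so a geometry string round-trips
bit-exactly through the command line and through manifests; rendering
always produces this minimal canonical form.

Three structural rules make matching decidable and deterministic:

* at most one unbounded segment per read, and only in last position;
* a range-length segment must be immediately followed by an anchor or be
  the last segment of its read — without a downstream anchor there is no
  evidence from which to infer where a variable-length segment ends;
* exactly reads 1 and 2 exist, and anchors are confined to read 1. The
  biological read passes through untouched, so an anchor there would
  serve no purpose; paired layouts cover the supported protocols.

A geometry is *complex* exactly when it contains a range or an anchor.
This predicate is what decides, downstream, whether reads must be
rewritten before mapping: mappers consume only simple layouts.

## Matching semantics and tie-breaking

`match_read()` walks each read left to right. The one place where
ambiguity can arise is a range segment `[lo, hi]` followed by an anchor
`S`: several lengths ℓ might place `S` correctly. The package always
takes the smallest such ℓ (leftmost anchor placement). This tie-break is
deterministic, cheap, and identical to the definition used by the
brute-force oracle in the test suite (enumerate all assignments, prefer
the lexicographically smallest), so the two can be compared verbatim.
Anchor matching is exact — zero mismatches, no indels. A tolerant
matcher would pass more corrupted reads at the cost of a fuzzier
contract and a harder-to-verify implementation; with exact matching,
every accepted extraction is provably consistent with the geometry.
Reads that fail yield one of three per-record statuses
(`anchor_not_found`, `read_too_short`, `length_out_of_range`) rather
than an error; only a structural mismatch between geometry and supplied
reads (wrong number of files) is treated as a usage error.

Degenerate inputs behave as follows: an unbounded discard may match zero
bases; an unbounded biological segment must match at least one (a mapper
cannot use an empty read); a terminal range whose remainder falls
outside `[lo, hi]` fails with `length_out_of_range` rather than being
clamped.

## Normalization layout and padding

Normalized technical reads are laid out as all barcode segments in input
order, then all UMI segments — a two-block layout every mapper supports
as `1{b[B]u[U]}2{r:}`, with `B` and `U` the sums of per-segment *maxima*.
Variable-length extractions are right-padded to their segment maximum
with the base `A`, and padded quality positions receive `I` (Phred 40 in
Sanger encoding), the conventional "high confidence" placeholder for
bases we inserted ourselves.

The pad base deserves emphasis: padding can alias distinct barcodes — a
9-mer followed by pad `A` is indistinguishable from a 10-mer that
genuinely ends in `A`. No fixed-length encoding of variable-length
barcodes avoids collisions without sentinels, and sentinel characters
are not valid nucleotides, so the package accepts the aliasing and
documents it; downstream permit-list barcode correction operates on the
padded space and absorbs it. This is a deliberate trade, not an
oversight.

## Streaming

`transform_stream()` reads synchronized FASTQ sources in bounded chunks
(default 5000 records), so memory use is independent of input size, and
writes to plain files, gzip files, or named pipes — the intended
deployment is a FIFO feeding a mapper directly, avoiding intermediate
disk. Failing fragments are dropped from *both* outputs; emitting
placeholders instead would poison the mapper with malformed technical
reads. Desynchronized inputs (diverging ids or unequal record counts)
abort with the offending record index: silently recycling records would
corrupt every downstream cell assignment. The conservation identity
`passed + Σ failures = total` is checked by tests on every run
configuration.

## Augmented references

All coordinates are 1-based closed intervals, the GTF convention, so a
substring `[s..e]` has length `e − s + 1` and no conversion happens at
any boundary. Spliced transcript sequences are exon concatenations in
genomic order, reverse-complemented as a whole for minus-strand
transcripts.

For the spliced+intron (splici) reference, each transcript's introns are
the gaps between its consecutive exons; each intron is extended by
`flank = read_length − flank_trim` bases on both sides, clamped to the
chromosome, and the union over the gene's transcripts is merged.
Abutting intervals (end + 1 == next start) merge as well as overlapping
ones: no read can distinguish two abutting flanked introns, so keeping
them separate would only create redundant records. Merged intervals are
named `gene-I`, `gene-I1`, `gene-I2`, … in ascending genomic order —
deterministic and collision-free. `flank_trim` defaults to 5 bases, the
established convention for this construction, and is exposed as a
parameter; the flank exists so that reads straddling an exon–intron
boundary by a few bases still map to the intron record.

Identical intron sequences are deduplicated *within* a gene only.
Cross-gene deduplication would make the t2g mapping ambiguous (one
sequence, two genes); within a gene the gene assignment is unchanged and
the duplicate is pure redundancy. Dropped-duplicate counts are recorded
in the reference metadata.

The spliced+unspliced (spliceu) reference instead emits one gene-body
sequence per gene spanning `[min exon start, max exon end]`, named
`gene-U`. Both constructions guarantee that reference record names and
t2g rows are in bijection, with statuses partitioning records into
spliced (`S`) and augmentation (`U`) — an invariant the writer enforces.

## Orchestration and templates

Command plans are pure functions of their inputs: the same configuration
and manifest always produce byte-identical argv, which makes plans
diffable and testable without running any external tool. The external
tools themselves (salmon, piscem, alevin-fry) are never reimplemented;
their command lines are assembled from argv templates shipped as
configuration data (`inst/extdata/argv_templates.json`), so flag drift
across tool releases is a data update, not a code change. The index
manifest is written atomically (temp file + rename) because a torn
manifest would silently break every later quantification run that
self-configures from it.

Workflow templates are a JSON dialect: nested parameters whose leaves
are values or the `__REQUIRED__` sentinel, `${params.path}`
interpolation (references among parameters are resolved in topological
order; cycles are rejected by path), and order-indexed commands. A full
templating *language* with functions and conditionals was deliberately
not adopted: the JSON dialect preserves the create → fill → execute
lifecycle and self-documenting required fields while remaining trivially
parseable and shareable. Resume semantics were an open choice — nothing
in the command records says whether a completed stage is safe to skip —
and the package uses per-command completion marker files: coarse, but
transparent and robust for long multi-tool runs. Deleting a marker
forces that command to re-run.

## What the synthetic fixtures emulate

The read generator plants known truth: barcodes drawn from per-segment
whitelists, uniform lengths over `[lo, hi]` for variable segments, and —
critically — whitelists built by rejection sampling to be *anchor-free*
(no anchor occurs inside a barcode, nor earlier than the true junction
in barcode+anchor). Under that condition, leftmost anchor placement
provably recovers the planted truth, so exact recovery separates engine
correctness from the inherent ambiguity of protocols whose barcodes may
contain the linker. Corruptions are planted explicitly (anchor mutation,
verified after mutation to admit no accidental placement; or truncation)
so failure accounting can be checked exactly, not statistically.

What the fixtures do *not* emulate: sequencing error models, quality
score structure, barcode frequency skew, expression realism, or barcodes
that legitimately contain the anchor. Passing the recovery and
accounting properties therefore demonstrates that the matcher implements
its contract exactly — not that any particular error rate will be
achieved on real data, where anchor-containing barcodes and sequencing
errors in the linker shift reads from recovered to dropped.

The toy genome generator lays out non-overlapping multi-exon genes with
mixed strands and random isoform subsets, and precomputes intron truth
with an independent base-marking oracle (mark every base covered by any
flanked intron, read off maximal runs). It does not emulate overlapping
genes, trans-splicing, or multi-chromosome annotations beyond what the
interval arithmetic is already generic over.

## Validation problem sizes

The shipped test suite and the acceptance script use: 500 fuzzed
geometries for grammar round-trip and classification; 1000
(geometry, read) instances for matcher–oracle agreement; 1000 synthetic
sci-RNA-seq3-style fragments each for exact recovery
(`corruption_rate = 0`) and corruption accounting
(`corruption_rate = 0.1`); and 200 random toy annotations × flanks
{0, 1, 2, 5} for the intron oracle. These sizes were chosen so that every
property is exercised across hundreds of independent random structures
while the whole suite completes in about a minute on one CPU.

## Known limitations

* Anchor matching tolerates no mismatches or indels; a single sequencing
  error in a linker drops the read.
* Padding aliases variable-length barcodes as described above.
* Barcode-substitution preprocessing (as required by split-seq-style
  protocols) is out of scope: the geometry language describes layout,
  not rewriting rules.
* Geometries are limited to two reads, and anchors to read 1.
* The workflow engine executes strictly in order-index sequence; there
  is no DAG parallelism.
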