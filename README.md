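# screadkit

Single-cell RNA-seq preprocessing utilities for libraries whose fragment
geometry — the positional layout of cell barcodes, UMIs, fixed linker
(anchor) sequences, and biological cDNA within a read pair — is more
complex than the fixed layouts that read mappers support natively.

The package is aimed at people building single-cell quantification
pipelines around mappers such as salmon and piscem and the alevin-fry
quantification tools: it prepares both the *reads* (normalizing complex
layouts into simple ones) and the *reference* (splici/spliceu augmented
transcriptomes) those tools consume, and it plans and orchestrates the
commands that tie them together.

## What it does

**Fragment-geometry description language.** A read pair's layout is
written as a compact string, e.g.

* `1{b[16]u[12]x:}2{r:}` — read 1 carries a 16 bp barcode, a 12 bp UMI,
  and the rest is discarded; read 2 is entirely biological. This is a
  *simple* geometry: every technical segment has a known position and a
  fixed length.
* `1{b[9-10]f[CAGAGC]u[8]b[10]}2{r:}` — a sci-RNA-seq3-style layout: a
  barcode of 9 *or* 10 bp whose end is located by the fixed linker
  `CAGAGC`, then an 8 bp UMI and a second 10 bp barcode. Variable lengths
  and anchors make this a *complex* geometry.

Segment kinds are `b` (barcode), `u` (UMI), `x` (discard), `r`
(biological) and `f[SEQ]` (anchor); lengths are fixed `[n]`, ranged
`[lo-hi]`, or unbounded `:`. A range-length segment must be followed by
an anchor or be last — otherwise its boundary would be undecidable.

**Matching and normalization.** `match_read()` applies left-to-right
cursor semantics: fixed segments consume exactly their length; a range
segment followed by anchor `S` consumes the smallest admissible length
after which `S` occurs verbatim (leftmost placement, exact match); a
terminal range consumes the remainder. `transform_stream()` runs this
over paired FASTQ files (gzip or named pipes) in bounded chunks and
rewrites each passing fragment into a fixed simple layout: all barcode
segments (right-padded to their maxima with `A`), then all UMI segments,
with biological sequence passed through — so a mapper only ever sees
`1{b[B]u[U]}2{r:}` with `(B, U)` given by `technical_lengths()`.
Fragments that fail (`anchor_not_found`, `read_too_short`,
`length_out_of_range`) are dropped from both output streams, keeping them
synchronized, and are tallied per reason.

**Augmented references.** From a genome FASTA and GTF annotation,
`build_splici()` produces the spliced-plus-intron reference: every
spliced transcript (t2g status `S`) plus, per gene, the union of its
per-transcript introns, each extended by `flank = read_length −
flank_trim` bases, merged, and emitted as `gene-I`, `gene-I1`, …
(status `U`). `build_spliceu()` instead emits one full gene-body sequence
per gene (`gene-U`). `write_reference()` writes the FASTA, the 3-column
transcript-to-gene table, and a JSON metadata sidecar.

**Orchestration.** `cmd_index()` builds and stages a reference, records
the chosen mapping backend (piscem iff `use_piscem`, salmon otherwise) in
an `index_info.json` manifest, and plans the indexer invocation.
`cmd_quant()` reads that manifest and assembles the full stage list
(`xform?` → `map` → `generate-permit-list` → `collate` → `quant`) with
fully resolved argv — backend and t2g location come from the manifest,
never from the user, and complex geometries are routed through an `xform`
stage so the mapper receives only the simplified description. Plans are
pure functions of their inputs and run through pluggable executors
(`shell_executor()`, `recording_executor()`).

**Workflow templates.** JSON templates with `${params.path}`
interpolation, a `__REQUIRED__` sentinel for user-supplied values, and
order-indexed commands (internal subcommands or arbitrary shell
programs) are instantiated with `instantiate_template()` and run with
`execute_workflow()`, with per-command completion markers enabling
`resume`.

**Synthetic fixtures.** `gen_reads()` emits reads with known
barcode/UMI truth (anchor-free whitelists make exact recovery a clean
property) and optional planted corruptions; `gen_toy_genome()` emits toy
genomes/annotations with oracle-verified intron truth; `gen_geometry()`
fuzzes the description language. All are deterministic under a seed.

## Worked example

```r
library(screadkit)

g <- parse_geometry("1{b[9-10]f[CAGAGC]u[8]b[10]}2{r:}")
g
#> <fragment_geometry> 1{b[9-10]f[CAGAGC]u[8]b[10]}2{r:} [complex]
#>   barcode: 20 bp, UMI: 8 bp

r1 <- paste0("GTCCTTGAC", "CAGAGC", "AAGGTCTC", "TCAGTATTCC")
m <- match_read(g, c(r1, "ACGTACGTACGTACGT"))
m
#> <match_result> status: ok
#>   read_index segment       kind              seq start end
#> 1          1       1    barcode        GTCCTTGAC     1   9
#> 2          1       3        umi         AAGGTCTC    16  23
#> 3          1       4    barcode       TCAGTATTCC    24  33
#> 4          2       1 biological ACGTACGTACGTACGT     1  16
```

The 9 bp first barcode was located by the `CAGAGC` linker. Normalizing
pads it to its 10 bp maximum with `A`, giving a constant 28 bp technical
read (20 bp barcode block + 8 bp UMI):

```r
fx <- gen_reads(g, n = 1000, seed = 42, corruption_rate = 0.1,
                out_dir = "demo")
stats <- transform_stream(g, c(fx$files$r1, fx$files$r2),
                          out_tech = "demo/tech.fastq",
                          out_bio  = "demo/bio.fastq")
stats
#> <transform_stats> total: 1000, passed: 900
#>   failed (anchor_not_found): 100
render_geometry(simplified_geometry(g))
#> [1] "1{b[20]u[8]}2{r:}"
```

Exactly the 100 reads whose anchor was corrupted are dropped (from both
outputs), and the mapper-facing geometry is the simple 20+8 layout.
On the reference side:

```r
genome <- c(chr1 = "ACGTACGTACGTACGTACGT")
models <- load_annotation("toy.gtf")  # t1: exons 1-5 and 11-15 of gene g1
ref <- build_splici(genome, models, read_length = 7, flank_trim = 5)
as.character(ref$records)
#>           t1         g1-I
#> "ACGTAGTACG"  "TACGTACGT"
ref$t2g
#>    seq_name gene_id status
#> t1       t1      g1      S
#> 1      g1-I      g1      U
```

The intron 6–10 was extended by `flank = 7 − 5 = 2` on each side to
4–12 and emitted as `g1-I` with status `U`.

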