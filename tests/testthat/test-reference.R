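toy_model <- function(transcript_id = "t1", gene_id = "g1", strand = "+",
                      starts = c(1L, 11L), ends = c(5L, 15L),
                      chrom = "chr1") {
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand,
                 exons = data.frame(start = starts, end = ends)),
            class = "transcript_model")
}

toy_genome <- c(chr1 = "ACGTACGTACGTACGTACGT")

test_that("GTF loading builds sorted transcript models in both dialects", {
  td <- withr::local_tempdir()
  gtf <- file.path(td, "toy.gtf")
  writeLines(c(
    "# a comment",
    'chr1\ttoy\texon\t11\t15\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\texon\t1\t5\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\ttoy\texon\t2\t6\t.\t-\t.\tgene_id=g2; transcript_id=t2",
    'chr1\ttoy\tgene\t1\t15\t.\t+\t.\tgene_id "g1";'), gtf)
  models <- load_annotation(gtf)
  expect_length(models, 2L)
  # exons given out of order come back sorted
  expect_equal(models$t1$exons, data.frame(start = c(1L, 11L),
                                           end = c(5L, 15L)))
  expect_identical(models$t2$gene_id, "g2")  # key=value dialect
  expect_identical(models$t2$strand, "-")
})

test_that("GTF loading rejects malformed input with line numbers", {
  td <- withr::local_tempdir()
  gtf <- file.path(td, "bad.gtf")
  writeLines(c(
    'chr1\ttoy\texon\t1\t5\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "not a gtf line"), gtf)
  expect_error(load_annotation(gtf), "line 2")

  writeLines('chr1\ttoy\texon\t9\t5\t.\t+\t.\tgene_id "g"; transcript_id "t";',
             gtf)
  expect_error(load_annotation(gtf), "line 1")

  writeLines('chr1\ttoy\texon\t1\t5\t.\t+\t.\ttranscript_id "t1";', gtf)
  expect_error(load_annotation(gtf), "gene_id.*t1")

  # one transcript on two strands
  writeLines(c(
    'chr1\ttoy\texon\t1\t5\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\texon\t11\t15\t.\t-\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  expect_error(load_annotation(gtf), "strand")

  # overlapping exons: rejected by default, merged when strict = FALSE
  writeLines(c(
    'chr1\ttoy\texon\t1\t6\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\texon\t4\t9\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  expect_error(load_annotation(gtf), "overlap")
  merged <- load_annotation(gtf, strict = FALSE)
  expect_equal(merged$t1$exons, data.frame(start = 1L, end = 9L))
})

test_that("spliced extraction concatenates exons and honours strand", {
  expect_identical(extract_spliced(toy_model(), toy_genome), "ACGTAGTACG")
  expect_identical(extract_spliced(toy_model(strand = "-"), toy_genome),
                   "CGTACTACGT")
  expect_identical(
    extract_spliced(toy_model(starts = 1L, ends = 4L), toy_genome), "ACGT")
  expect_error(
    extract_spliced(toy_model(starts = 1L, ends = 50L), toy_genome),
    "past the end")
})

test_that("intron collapsing flanks, clamps, merges, and labels", {
  gi <- gene_introns(list(toy_model()), flank = 2, chrom_len = 20)
  expect_equal(gi[, c("start", "end", "label")],
               data.frame(start = 4L, end = 12L, label = "g1-I"))

  # two isoforms, overlapping flanked introns merge
  m2 <- toy_model("t2", starts = c(1L, 13L), ends = c(7L, 18L))
  gi2 <- gene_introns(list(toy_model(), m2), flank = 1, chrom_len = 20)
  expect_equal(gi2$start, 5L)
  expect_equal(gi2$end, 13L)

  # single-exon gene has no introns
  expect_equal(nrow(gene_introns(list(toy_model(starts = 1L, ends = 9L)),
                                 flank = 2, chrom_len = 20)), 0L)

  # flanks clamp at the chromosome ends
  gi3 <- gene_introns(list(toy_model()), flank = 50, chrom_len = 20)
  expect_equal(c(gi3$start, gi3$end), c(1L, 20L))

  # disjoint introns get -I, -I1, ... in genomic order
  m3 <- toy_model("t3", starts = c(1L, 8L, 16L), ends = c(4L, 12L, 20L))
  gi4 <- gene_introns(list(m3), flank = 0, chrom_len = 20)
  expect_identical(gi4$label, c("g1-I", "g1-I1"))
})

test_that("gene_introns matches the base-marking oracle on random genes", {
  for (seed in 1:25) {
    tg <- gen_toy_genome(seed = 1000L + seed, n_genes = 3L,
                         isoforms_per_gene = 3L)
    for (gene in split(unclass(tg$models),
                       vapply(tg$models, `[[`, character(1), "gene_id"))) {
      for (flank in c(0L, 1L, 2L, 5L)) {
        got <- gene_introns(gene, flank, tg$chrom_len)
        want <- tg$truth[[gene[[1L]]$gene_id]][[as.character(flank)]]
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
      }
    }
  }
})

test_that("splici worked example and invariants", {
  models <- structure(list(t1 = toy_model()), class = "transcript_models")
  ref <- build_splici(toy_genome, models, read_length = 7, flank_trim = 5)
  expect_identical(as.character(ref$records),
                   c(t1 = "ACGTAGTACG", "g1-I" = "TACGTACGT"))
  expect_equal(ref$t2g,
               data.frame(seq_name = c("t1", "g1-I"),
                          gene_id = c("g1", "g1"), status = c("S", "U")),
               ignore_attr = TRUE)
  expect_equal(ref$metadata$flank, 2L)

  # flank_trim == read_length gives the bare intron
  ref0 <- build_splici(toy_genome, models, read_length = 7, flank_trim = 7)
  expect_identical(as.character(ref0$records)[["g1-I"]], "CGTAC")

  expect_error(build_splici(toy_genome, models, read_length = 5,
                            flank_trim = 6), "flank_trim")

  # single-exon genes contribute no U rows
  m1 <- structure(list(t1 = toy_model(starts = 1L, ends = 9L)),
                  class = "transcript_models")
  expect_true(all(build_splici(toy_genome, m1, 7, 5)$t2g$status == "S"))
})

test_that("spliceu emits one gene-body record per gene", {
  models <- structure(list(t1 = toy_model()), class = "transcript_models")
  ref <- build_spliceu(toy_genome, models)
  expect_identical(as.character(ref$records)[["g1-U"]], "ACGTACGTACGTACG")
  expect_identical(ref$t2g$status, c("S", "U"))

  two <- structure(list(t1 = toy_model(),
                        t2 = toy_model("t2", "g2", starts = 16L, ends = 19L)),
                   class = "transcript_models")
  ref2 <- build_spliceu(toy_genome, two)
  expect_equal(sum(ref2$t2g$status == "U"), 2L)
  # a single-transcript gene body can equal its transcript; both are kept
  expect_identical(as.character(ref2$records)[["t2"]],
                   as.character(ref2$records)[["g2-U"]])
})

test_that("written references round-trip with a t2g bijection", {
  td <- withr::local_tempdir()
  tg <- gen_toy_genome(seed = 77L, n_genes = 4L, isoforms_per_gene = 2L)
  ref <- build_splici(tg$genome, tg$models, read_length = 10)
  paths <- write_reference(ref, td)
  fa <- Biostrings::readDNAStringSet(paths$fasta)
  t2g <- utils::read.table(paths$t2g, sep = "\t",
                           col.names = c("seq_name", "gene_id", "status"))
  expect_identical(names(fa), t2g$seq_name)     # bijection
  expect_equal(length(fa), nrow(ref$t2g))
  expect_setequal(unique(t2g$status), c("S", "U"))
  expect_true(all(t2g$seq_name[t2g$status == "S"] %in% names(tg$models)))
  meta <- jsonlite::read_json(paths$metadata)
  expect_identical(meta$ref_type, "splici")
  expect_equal(meta$flank_trim, 5L)
})

test_that("flipping strand annotations reverse-complements every record", {
  tg <- gen_toy_genome(seed = 31L, n_genes = 3L, isoforms_per_gene = 2L)
  flipped <- structure(lapply(unclass(tg$models), function(m) {
    m$strand <- if (m$strand == "+") "-" else "+"
    m
  }), class = "transcript_models")

  for (build in list(
    function(m) build_splici(tg$genome, m, read_length = 8),
    function(m) build_spliceu(tg$genome, m))) {
    ref <- build(tg$models)
    ref_f <- build(flipped)
    expect_identical(names(ref$records), names(ref_f$records))
    expect_identical(
      unname(as.character(Biostrings::reverseComplement(ref_f$records))),
      unname(as.character(ref$records)))
  }
})
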