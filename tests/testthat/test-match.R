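test_that("cursor matching handles anchored variable-length barcodes", {
  g <- parse_geometry("1{b[2-3]f[AC]u[2]b[2]}")
  m <- match_read(g, "GGACTTCA")
  expect_identical(m$status, "ok")
  expect_identical(m$extractions$seq, c("GG", "TT", "CA"))
  expect_identical(m$extractions$kind, c("barcode", "umi", "barcode"))

  expect_identical(match_read(g, "GGGGGGGG")$status, "anchor_not_found")
  expect_identical(match_read(parse_geometry("1{b[4]u[2]}"), "ACGTA")$status,
                   "read_too_short")
  expect_identical(match_read(parse_geometry("1{b[2]r[4-6]}"),
                              "GGACGTACGT")$status, "length_out_of_range")
  # leftmost anchor placement wins
  m2 <- match_read(parse_geometry("1{b[2-4]f[AC]u[1]}"), "GGACACT")
  expect_identical(m2$extractions$seq[1L], "GG")
  # structural mismatch is a usage error, not a per-read status
  expect_error(match_read(parse_geometry("1{b[4]}2{r:}"), "ACGT"),
               "sequence")
})

test_that("normalization pads variable extractions into a fixed layout", {
  g <- parse_geometry("1{b[2-3]f[AC]u[2]b[2]}")
  m <- match_read(g, "GGACTTCA")
  np <- normalize_pair(g, m, quals = "FGHIJKLM", record_id = "r1")
  expect_identical(np$tech_seq, "GGACATT")  # b1 "GG"+pad A, b2 "CA", umi "TT"
  expect_identical(np$tech_qual, "FGILMJK")  # b1 "FG"+pad 'I', b2 "LM", umi "JK"
  expect_identical(np$record_id, "r1")

  # all-fixed geometry: the first 28 bases pass through unchanged
  g10x <- parse_geometry("1{b[16]u[12]x:}")
  r1 <- paste0(paste(rep("ACGT", 8), collapse = ""), "TTTT")
  m10 <- match_read(g10x, r1)
  np10 <- normalize_pair(g10x, m10, quals = strrep("H", nchar(r1)))
  expect_identical(np10$tech_seq, substr(r1, 1, 28))

  # geometry without UMI
  gnu <- parse_geometry("1{b[8]x:}")
  mnu <- match_read(gnu, "ACGTACGTAAAA")
  expect_identical(nchar(normalize_pair(gnu, mnu, "IIIIIIIIIIII")$tech_seq),
                   8L)

  expect_error(normalize_pair(g, match_read(g, "GGGGGGGG"), "HHHHHHHH"),
               "ok")
})

test_that("simplified geometry collapses to a barcode+UMI layout", {
  expect_identical(
    render_geometry(simplified_geometry(
      parse_geometry("1{b[9-10]f[CAGAGC]u[8]b[10]}2{r:}"))),
    "1{b[20]u[8]}2{r:}")
  expect_identical(
    render_geometry(simplified_geometry(
      parse_geometry("1{b[16]u[12]x:}2{r:}"))),
    "1{b[16]u[12]x:}2{r:}")
  expect_identical(
    render_geometry(simplified_geometry(parse_geometry("1{u[8]b[4]}2{r:}"))),
    "1{b[4]u[8]}2{r:}")
})

test_that("match_read agrees with the brute-force enumeration oracle", {
  instances <- gen_match_instances(200, seed = 71L)
  for (inst in instances) {
    got <- match_read(inst$g, inst$seqs)
    want <- oracle_match(inst$g, inst$seqs)
    expect_identical(got$status, want$status,
                     info = paste(render_geometry(inst$g),
                                  paste(inst$seqs, collapse = " / ")))
    if (got$status == "ok") {
      expect_identical(got$extractions[, c("read_index", "kind", "seq")],
                       want$extractions[, c("read_index", "kind", "seq")],
                       info = render_geometry(inst$g))
    }
  }
})

test_that("streaming transform conserves counts and preserves pairing", {
  td <- withr::local_tempdir()
  g <- parse_geometry(SCI_GEOM)
  rr <- gen_reads(g, n = 300, seed = 5L, corruption_rate = 0.1,
                  out_dir = td)
  out1 <- file.path(td, "tech.fq")
  out2 <- file.path(td, "bio.fq")
  st <- transform_stream(g, c(rr$files$r1, rr$files$r2), out1, out2,
                         chunk_size = 64L,
                         stats_path = file.path(td, "stats.json"))
  expect_equal(st$total, 300L)
  expect_equal(st$passed + Reduce(`+`, st$failed_by_reason), st$total)
  expect_equal(st$passed, 270L)
  expect_equal(st$failed_by_reason$anchor_not_found, 30L)

  tech <- readLines(out1)
  bio <- readLines(out2)
  # identical ids in identical order, failures dropped from both sides
  expect_identical(tech[seq(1, length(tech), 4)],
                   bio[seq(1, length(bio), 4)])
  expect_identical(sub("^@", "", tech[seq(1, length(tech), 4)]),
                   rr$truth$record_id[is.na(rr$truth$reason)])
  # constant technical read length = barcode_total + umi_total
  expect_true(all(nchar(tech[seq(2, length(tech), 4)]) ==
                    sum(technical_lengths(g))))
  # stats JSON schema
  js <- jsonlite::read_json(file.path(td, "stats.json"))
  expect_equal(js$total, 300L)
  expect_equal(js$failed$anchor_not_found, 30L)
})

test_that("streaming transform handles gzip, empty input, and desync", {
  td <- withr::local_tempdir()
  g <- parse_geometry("1{b[4]u[2]x:}2{r:}")
  rr <- gen_reads(g, n = 40, seed = 9L, out_dir = td)
  # gzip the inputs and outputs
  for (f in c(rr$files$r1, rr$files$r2)) {
    con <- gzfile(paste0(f, ".gz"), "w")
    writeLines(readLines(f), con)
    close(con)
  }
  st <- transform_stream(g, paste0(c(rr$files$r1, rr$files$r2), ".gz"),
                         file.path(td, "t.fq.gz"), file.path(td, "b.fq.gz"),
                         chunk_size = 7L)
  expect_equal(st$passed, 40L)
  expect_equal(length(readLines(file.path(td, "t.fq.gz"))), 160L)

  # empty input
  e1 <- file.path(td, "e1.fq"); e2 <- file.path(td, "e2.fq")
  file.create(e1, e2)
  st0 <- transform_stream(g, c(e1, e2), file.path(td, "et.fq"),
                          file.path(td, "eb.fq"))
  expect_equal(st0$total, 0L)
  expect_equal(st0$passed, 0L)

  # desynchronized ids are fatal and report a record index
  r2_lines <- readLines(rr$files$r2)
  r2_lines[1L] <- "@somethingelse"
  bad2 <- file.path(td, "bad2.fq")
  writeLines(r2_lines, bad2)
  expect_error(
    transform_stream(g, c(rr$files$r1, bad2), file.path(td, "x.fq"),
                     file.path(td, "y.fq")),
    "record 1")
  # unequal record counts are fatal
  writeLines(readLines(rr$files$r2)[1:36], bad2)
  expect_error(
    transform_stream(g, c(rr$files$r1, bad2), file.path(td, "x.fq"),
                     file.path(td, "y.fq")),
    "desynchronized")
})

test_that("in-process consumer receives every passing record", {
  g <- parse_geometry("1{b[4]u[2]x:}2{r:}")
  td <- withr::local_tempdir()
  rr <- gen_reads(g, n = 25, seed = 3L, out_dir = td)
  seen <- list()
  st <- transform_stream(g, c(rr$files$r1, rr$files$r2),
                         consumer = function(df) {
                           seen[[length(seen) + 1L]] <<- df
                         }, chunk_size = 10L)
  all_df <- do.call(rbind, seen)
  expect_equal(nrow(all_df), 25L)
  expect_identical(all_df$record_id, rr$truth$record_id)
  expect_identical(all_df$bio_seq, rr$truth$bio)
})
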