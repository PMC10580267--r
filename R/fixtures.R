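# Synthetic fixtures: geometry fuzzing, reads with known barcode/UMI
# truth (optionally with planted corruptions), and toy genomes with known
# intron structure. Everything is deterministic under the given seed, and
# the truth tables are sufficient to verify downstream behaviour without
# any external data.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

rand_bases <- function(n) {
  if (n == 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_quals <- function(n) {
  if (n == 0L) return("")
  pool <- strsplit("#$%&'()*+,-./0123456789:;<=>?@ABCDEFGHI", "")[[1L]]
  paste0(sample(pool, n, replace = TRUE), collapse = "")
}

#' Generate random valid fragment geometries
#'
#' A grammar fuzzer: builds random valid geometry ASTs (fixed,
#' range+anchor, standalone-anchor, terminal-range and unbounded segments
#' over one or two reads) and renders them. Each row records whether a
#' range or anchor segment was planted, i.e. the ground-truth complexity
#' class.
#'
#' @param n Number of geometries.
#' @param seed RNG seed.
#' @return A data.frame with columns `text` (canonical geometry string)
#'   and `complex` (logical ground truth).
#' @export
gen_geometry <- function(n, seed) {
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      has_cx <- FALSE
      segs <- list()
      n_units <- sample(1:4, 1L)
      for (u in seq_len(n_units)) {
        type <- sample(c("fixed_b", "fixed_u", "fixed_x", "range_anchor",
                         "anchor"), 1L,
                       prob = c(0.3, 0.25, 0.1, 0.25, 0.1))
        if (type == "fixed_b") {
          segs[[length(segs) + 1L]] <-
            geom_segment("barcode", len_fixed(sample(4:16, 1L)))
        } else if (type == "fixed_u") {
          segs[[length(segs) + 1L]] <-
            geom_segment("umi", len_fixed(sample(4:12, 1L)))
        } else if (type == "fixed_x") {
          segs[[length(segs) + 1L]] <-
            geom_segment("discard", len_fixed(sample(1:8, 1L)))
        } else if (type == "range_anchor") {
          lo <- sample(3:9, 1L)
          kind <- sample(c("barcode", "umi"), 1L, prob = c(0.8, 0.2))
          segs[[length(segs) + 1L]] <-
            geom_segment(kind, len_range(lo, lo + sample(1:3, 1L)))
          segs[[length(segs) + 1L]] <-
            geom_segment("anchor", anchor_seq = rand_bases(sample(4:6, 1L)))
          has_cx <- TRUE
        } else {
          segs[[length(segs) + 1L]] <-
            geom_segment("anchor", anchor_seq = rand_bases(sample(4:6, 1L)))
          has_cx <- TRUE
        }
      }
      tail_type <- sample(c("none", "unbounded_x", "unbounded_r",
                            "terminal_range"), 1L,
                          prob = c(0.35, 0.25, 0.25, 0.15))
      if (tail_type == "unbounded_x") {
        segs[[length(segs) + 1L]] <- geom_segment("discard", len_unbounded())
      } else if (tail_type == "unbounded_r") {
        segs[[length(segs) + 1L]] <-
          geom_segment("biological", len_unbounded())
      } else if (tail_type == "terminal_range") {
        lo <- sample(2:8, 1L)
        segs[[length(segs) + 1L]] <-
          geom_segment("biological", len_range(lo, lo + sample(2:6, 1L)))
        has_cx <- TRUE
      }
      reads <- list(list(read_index = 1L, segments = segs))
      if (stats::runif(1) < 0.8) {
        r2 <- list(geom_segment("biological", len_unbounded()))
        if (stats::runif(1) < 0.3) {
          r2 <- c(list(geom_segment("discard", len_fixed(sample(1:6, 1L)))),
                  r2)
        }
        reads[[2L]] <- list(read_index = 2L, segments = r2)
      }
      g <- structure(list(reads = reads), class = "fragment_geometry")
      validate_geometry(g)
      out[[i]] <- data.frame(text = render_geometry(g), complex = has_cx,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

anchor_free <- function(bc, following_anchor, all_anchors) {
  for (a in all_anchors) {
    if (grepl(a, bc, fixed = TRUE)) return(FALSE)
  }
  if (!is.null(following_anchor)) {
    joined <- paste0(bc, following_anchor)
    first <- regexpr(following_anchor, joined, fixed = TRUE)
    if (first != nchar(bc) + 1L) return(FALSE)
  }
  TRUE
}

segment_draw_length <- function(ls) {
  switch(ls$variant,
    fixed = ls$n,
    range = sample(ls$lo:ls$hi, 1L),
    stop("cannot draw a length for an unbounded segment"))
}

make_whitelist <- function(ls, size, following_anchor, all_anchors,
                           max_tries = 10000L) {
  wl <- character(0)
  tries <- 0L
  while (length(wl) < size) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "could not build an anchor-free whitelist of size %d in %d tries",
        size, max_tries))
    }
    cand <- rand_bases(segment_draw_length(ls))
    if (cand %in% wl) next
    if (!anchor_free(cand, following_anchor, all_anchors)) next
    wl <- c(wl, cand)
  }
  wl
}

read1_corruption_mode <- function(segs) {
  # How to plant a corruption in read 1 and which failure it must cause.
  if (any(vapply(segs, function(s) s$kind == "anchor", logical(1)))) {
    return(list(kind = "anchor_mut", reason = "anchor_not_found"))
  }
  s1 <- segs[[1L]]
  if (s1$length$variant == "fixed") {
    return(list(kind = "truncate", reason = "read_too_short",
                keep = s1$length$n - 1L))
  }
  if (s1$length$variant == "range") {
    return(list(kind = "truncate", reason = "length_out_of_range",
                keep = s1$length$lo - 1L))
  }
  if (s1$kind == "biological") {
    return(list(kind = "truncate", reason = "read_too_short", keep = 0L))
  }
  stop("this geometry admits no plantable corruption")
}

mutate_first_anchor <- function(seq1, segs, anchor_offset, var_len) {
  # Mutate one base of the first anchor of read 1 so that no admissible
  # placement of that anchor survives; returns the corrupted sequence.
  # `anchor_offset` is the 1-based start of the anchor in seq1; `var_len`
  # the drawn length of a preceding range segment (NA if none).
  ai <- which(vapply(segs, function(s) s$kind == "anchor", logical(1)))[1L]
  anchor <- segs[[ai]]$anchor_seq
  scan_starts <- if (!is.na(var_len)) {
    ls <- segs[[ai - 1L]]$length
    cursor0 <- anchor_offset - var_len
    cursor0 + ls$lo:ls$hi
  } else {
    anchor_offset
  }
  for (attempt in 1:100) {
    pos <- anchor_offset + sample.int(nchar(anchor), 1L) - 1L
    old_b <- substr(seq1, pos, pos)
    new_b <- sample(setdiff(c("A", "C", "G", "T"), old_b), 1L)
    cand <- paste0(substr(seq1, 1L, pos - 1L), new_b,
                   substr(seq1, pos + 1L, nchar(seq1)))
    hit <- any(vapply(scan_starts, function(p) {
      p >= 1L && substr(cand, p, p + nchar(anchor) - 1L) == anchor
    }, logical(1)))
    if (!hit) return(cand)
  }
  stop("could not plant an anchor corruption")
}

#' Generate reads with known barcode/UMI truth
#'
#' Emits `n` fragments conforming to `g`, together with a truth table of
#' every planted barcode, UMI and biological sequence. Barcodes are drawn
#' from per-segment whitelists built by rejection sampling to be
#' *anchor-free*: no anchor of the geometry occurs inside a barcode, and
#' for a variable-length barcode followed by an anchor the anchor's first
#' occurrence within barcode+anchor is exactly at the true junction — so
#' leftmost anchor placement recovers the truth exactly. Variable segment
#' lengths are drawn uniformly over `[lo, hi]`. A fraction
#' `corruption_rate` of reads is corrupted (anchor mutation where the
#' geometry has an anchor, truncation otherwise) and the planted failure
#' reason is recorded in the truth table.
#'
#' @param g A valid `fragment_geometry` with bounded technical segments.
#' @param n Number of fragments.
#' @param seed RNG seed; the same seed yields byte-identical output.
#' @param whitelist_size Barcodes per barcode segment.
#' @param corruption_rate Fraction of reads to corrupt (0 plants none).
#' @param bio_length Length of unbounded biological segments, in bases.
#' @param out_dir If given, per-read FASTQ files (`reads_R<i>.fastq`) and
#'   `truth.tsv` are written there.
#' @return List with `truth` (data.frame: `record_id`, `barcodes` and
#'   `umis` (`;`-joined per segment), `bio`, `expected_tech` — the padded
#'   technical read a correct normalizer must emit, `NA` for corrupted
#'   records — and `reason`), `seqs` and `quals` (per-read character
#'   vectors), `whitelists`, and `files` when `out_dir` is given.
#' @export
gen_reads <- function(g, n, seed, whitelist_size = 32L,
                      corruption_rate = 0, bio_length = 50L,
                      out_dir = NULL) {
  validate_geometry(g)
  with_seed(seed, {
    all_anchors <- unlist(lapply(g$reads, function(r) {
      unlist(lapply(r$segments, function(s) {
        if (s$kind == "anchor") s$anchor_seq
      }))
    }))

    whitelists <- list()
    for (ri in seq_along(g$reads)) {
      segs <- g$reads[[ri]]$segments
      for (si in seq_along(segs)) {
        s <- segs[[si]]
        if (s$kind != "barcode") next
        if (s$length$variant == "unbounded") {
          stop("cannot generate reads for an unbounded barcode segment")
        }
        follow <- if (si < length(segs) && segs[[si + 1L]]$kind == "anchor") {
          segs[[si + 1L]]$anchor_seq
        }
        whitelists[[sprintf("r%d_s%d", g$reads[[ri]]$read_index, si)]] <-
          make_whitelist(s$length, whitelist_size, follow, all_anchors)
      }
    }

    n_corrupt <- round(corruption_rate * n)
    corrupt_idx <- if (n_corrupt > 0L) sort(sample.int(n, n_corrupt))
                   else integer(0)
    corruption <- if (n_corrupt > 0L) {
      read1_corruption_mode(g$reads[[1L]]$segments)
    }

    seqs <- rep(list(character(n)), length(g$reads))
    quals <- rep(list(character(n)), length(g$reads))
    rows <- vector("list", n)

    for (i in seq_len(n)) {
      barcodes <- character(0)
      padded_bc <- character(0)
      umis <- character(0)
      padded_umi <- character(0)
      bio <- character(0)
      anchor1_offset <- NA_integer_
      anchor1_var_len <- NA_integer_

      for (ri in seq_along(g$reads)) {
        segs <- g$reads[[ri]]$segments
        parts <- character(length(segs))
        for (si in seq_along(segs)) {
          s <- segs[[si]]
          if (s$kind == "anchor") {
            parts[[si]] <- s$anchor_seq
            if (ri == 1L && is.na(anchor1_offset)) {
              anchor1_offset <- sum(nchar(parts[seq_len(si - 1L)])) + 1L
              prev <- if (si > 1L) segs[[si - 1L]]
              if (!is.null(prev) && !is.null(prev$length) &&
                  prev$length$variant == "range") {
                anchor1_var_len <- nchar(parts[[si - 1L]])
              }
            }
            next
          }
          follow <- if (si < length(segs) &&
                        segs[[si + 1L]]$kind == "anchor") {
            segs[[si + 1L]]$anchor_seq
          }
          if (s$kind == "barcode") {
            wl <- whitelists[[sprintf("r%d_s%d", g$reads[[ri]]$read_index,
                                      si)]]
            v <- wl[[sample.int(length(wl), 1L)]]
            barcodes <- c(barcodes, v)
            padded_bc <- c(padded_bc,
                           pad_right(v, segment_max_length(s), PAD_BASE))
          } else if (s$kind == "umi") {
            len <- segment_draw_length(s$length)
            repeat {
              v <- rand_bases(len)
              if (anchor_free(v, follow, all_anchors)) break
            }
            umis <- c(umis, v)
            padded_umi <- c(padded_umi,
                            pad_right(v, segment_max_length(s), PAD_BASE))
          } else if (s$kind == "biological") {
            len <- switch(s$length$variant,
              fixed = s$length$n,
              range = segment_draw_length(s$length),
              unbounded = bio_length)
            v <- rand_bases(len)
            bio <- c(bio, v)
          } else {  # discard
            len <- switch(s$length$variant,
              fixed = s$length$n,
              range = segment_draw_length(s$length),
              unbounded = sample(0:8, 1L))
            v <- rand_bases(len)
          }
          parts[[si]] <- v
        }
        seqs[[ri]][[i]] <- paste0(parts, collapse = "")
        quals[[ri]][[i]] <- rand_quals(nchar(seqs[[ri]][[i]]))
      }

      reason <- NA_character_
      if (i %in% corrupt_idx) {
        reason <- corruption$reason
        if (corruption$kind == "anchor_mut") {
          seqs[[1L]][[i]] <- mutate_first_anchor(
            seqs[[1L]][[i]], g$reads[[1L]]$segments, anchor1_offset,
            anchor1_var_len)
        } else {
          seqs[[1L]][[i]] <- substr(seqs[[1L]][[i]], 1L, corruption$keep)
          quals[[1L]][[i]] <- substr(quals[[1L]][[i]], 1L, corruption$keep)
        }
      }

      rows[[i]] <- data.frame(
        record_id = sprintf("read%06d", i),
        barcodes = paste(barcodes, collapse = ";"),
        umis = paste(umis, collapse = ";"),
        bio = paste(bio, collapse = ""),
        expected_tech = if (is.na(reason)) {
          paste0(paste0(padded_bc, collapse = ""),
                 paste0(padded_umi, collapse = ""))
        } else NA_character_,
        reason = reason, stringsAsFactors = FALSE)
    }

    truth <- do.call(rbind, rows)
    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- list()
      for (ri in seq_along(g$reads)) {
        p <- file.path(out_dir,
                       sprintf("reads_R%d.fastq", g$reads[[ri]]$read_index))
        writeLines(as.vector(rbind(paste0("@", truth$record_id),
                                   seqs[[ri]], "+", quals[[ri]])), p)
        files[[sprintf("r%d", g$reads[[ri]]$read_index)]] <- p
      }
      tp <- file.path(out_dir, "truth.tsv")
      utils::write.table(truth, tp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files$truth <- tp
    }
    list(truth = truth, seqs = seqs, quals = quals,
         whitelists = whitelists, files = files)
  })
}

# Independent base-marking oracle for collapsed flanked introns: mark
# every genomic base covered by any flanked per-transcript intron, then
# read off the maximal runs. Used to precompute ToyGenomeTruth intervals.
mark_intron_intervals <- function(models, flank, chrom_len) {
  mask <- logical(chrom_len)
  for (m in models) {
    ex <- m$exons
    if (nrow(ex) < 2L) next
    for (k in seq_len(nrow(ex) - 1L)) {
      is <- ex$end[k] + 1L
      ie <- ex$start[k + 1L] - 1L
      if (is > ie) next
      s <- max(1L, is - as.integer(flank))
      e <- min(chrom_len, ie + as.integer(flank))
      mask[s:e] <- TRUE
    }
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Generate a toy genome with known intron structure
#'
#' Lays out `n_genes` non-overlapping multi-exon genes (mixed strands)
#' along one random chromosome; each gene's first isoform uses every exon
#' slot and further isoforms use random subsets, so alternative intron
#' sets arise. The truth table holds, for every gene and every flank in
#' `flank_grid`, the collapsed flanked-intron intervals computed by an
#' independent base-marking oracle (mark covered bases, read off maximal
#' runs).
#'
#' @param seed RNG seed.
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Isoforms per gene (>= 1; the first always has
#'   all exons).
#' @param flank_grid Flank widths for which truth intervals are computed.
#' @param out_dir If given, `genome.fa` and `annotation.gtf` are written
#'   there.
#' @return List with `genome` (named character vector), `models`
#'   (`transcript_models`), `truth` (list: per gene, per flank, a
#'   data.frame of `start`/`end`), `chrom_len`, and `files` when
#'   `out_dir` is given.
#' @export
gen_toy_genome <- function(seed, n_genes = 5L, isoforms_per_gene = 2L,
                           flank_grid = c(0L, 1L, 2L, 5L), out_dir = NULL) {
  stopifnot(n_genes >= 1L, isoforms_per_gene >= 1L)
  with_seed(seed, {
    models <- list()
    cursor <- sample(10:30, 1L)
    tx_counter <- 0L
    for (gi in seq_len(n_genes)) {
      gene_id <- sprintf("g%d", gi)
      strand <- sample(c("+", "-"), 1L)
      n_slots <- sample(2:4, 1L)
      slot_lens <- sample(5:15, n_slots, replace = TRUE)
      gap_lens <- sample(4:12, n_slots - 1L, replace = TRUE)
      starts <- integer(n_slots)
      ends <- integer(n_slots)
      p <- cursor
      for (k in seq_len(n_slots)) {
        starts[k] <- p
        ends[k] <- p + slot_lens[k] - 1L
        p <- ends[k] + 1L + if (k < n_slots) gap_lens[k] else 0L
      }
      cursor <- p + sample(15:30, 1L)
      for (iso in seq_len(isoforms_per_gene)) {
        tx_counter <- tx_counter + 1L
        slots <- if (iso == 1L) {
          seq_len(n_slots)
        } else {
          sort(sample(n_slots, sample(2:n_slots, 1L)))
        }
        models[[tx_counter]] <- structure(
          list(transcript_id = sprintf("t%d", tx_counter),
               gene_id = gene_id, chrom = "chr1", strand = strand,
               exons = data.frame(start = starts[slots],
                                  end = ends[slots])),
          class = "transcript_model")
      }
    }
    names(models) <- vapply(models, `[[`, character(1), "transcript_id")
    models <- structure(models, class = "transcript_models")
    chrom_len <- cursor + sample(10:20, 1L)
    genome <- c(chr1 = rand_bases(chrom_len))

    by_gene <- group_models_by_gene(models)
    truth <- lapply(by_gene, function(gm) {
      res <- lapply(flank_grid, function(fl) {
        mark_intron_intervals(gm, fl, chrom_len)
      })
      names(res) <- as.character(flank_grid)
      res
    })

    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      fa <- file.path(out_dir, "genome.fa")
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)
      gtf <- file.path(out_dir, "annotation.gtf")
      lines <- unlist(lapply(models, function(m) {
        vapply(seq_len(nrow(m$exons)), function(k) {
          sprintf('chr1\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                  m$exons$start[k], m$exons$end[k], m$strand, m$gene_id,
                  m$transcript_id)
        }, character(1))
      }))
      writeLines(lines, gtf)
      files <- list(genome = fa, gtf = gtf)
    }
    list(genome = genome, models = models, truth = truth,
         chrom_len = chrom_len, files = files)
  })
}
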