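# Matching complex geometries against reads and normalizing them to a
# fixed simple layout.
#
# Matching uses left-to-right cursor semantics:
#   * fixed segment: consume exactly n bases (read_too_short if unavailable)
#   * range segment followed by anchor f[S]: choose the smallest length
#     l in [lo, hi] such that S occurs verbatim right after the l consumed
#     bases; consume l, then |S| (anchor_not_found if no such l)
#   * terminal range segment: consume the remainder
#     (length_out_of_range if the remainder is not within [lo, hi])
#   * unbounded segment: consume the remainder (may be empty except for a
#     biological segment, which must be non-empty)
# Anchor matching is exact (zero mismatches); leftmost placement breaks
# ties, which makes matching deterministic.

PAD_BASE <- "A"
PAD_QUAL <- "I"

#' Match a geometry against the reads of one fragment
#'
#' Applies the cursor semantics described above to each read of the
#' fragment. The outcome is per-record, never an R error: reads that do
#' not fit the geometry yield a failure status (`anchor_not_found`,
#' `read_too_short`, `length_out_of_range`). Only a structural mismatch
#' between the geometry and the supplied sequences (wrong number of reads)
#' is a usage error.
#'
#' @param g A valid `fragment_geometry`.
#' @param seqs Character vector of nucleotide sequences, one per read
#'   descriptor of `g`, in order.
#' @return A `match_result`: list with `status` (one of `ok`,
#'   `anchor_not_found`, `read_too_short`, `length_out_of_range`) and, for
#'   `ok`, `extractions` — a data.frame with one row per barcode, UMI or
#'   biological segment (`read_index`, `segment`, `kind`, `seq`, `start`,
#'   `end`).
#' @examples
#' g <- parse_geometry("1{b[2-3]f[AC]u[2]b[2]}")
#' match_read(g, "GGACTTCA")
#' @export
match_read <- function(g, seqs) {
  validate_geometry(g)
  if (!is.character(seqs) || length(seqs) != length(g$reads)) {
    stop(sprintf(
      "geometry describes %d read(s) but %d sequence(s) were supplied",
      length(g$reads), length(seqs)))
  }

  fail <- function(status) {
    structure(list(status = status, extractions = NULL),
              class = "match_result")
  }
  rows <- list()
  add <- function(read_index, segment, kind, seq, start, end) {
    if (kind == "discard") return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- data.frame(
      read_index = read_index, segment = segment, kind = kind,
      seq = seq, start = start, end = end, stringsAsFactors = FALSE)
  }

  for (ri in seq_along(g$reads)) {
    rd <- g$reads[[ri]]
    s <- seqs[[ri]]
    slen <- nchar(s)
    cursor <- 1L
    segs <- rd$segments
    i <- 1L
    while (i <= length(segs)) {
      seg <- segs[[i]]
      remaining <- slen - cursor + 1L

      if (seg$kind == "anchor") {
        alen <- nchar(seg$anchor_seq)
        if (remaining < alen) return(fail("read_too_short"))
        if (substr(s, cursor, cursor + alen - 1L) != seg$anchor_seq) {
          return(fail("anchor_not_found"))
        }
        cursor <- cursor + alen
        i <- i + 1L
        next
      }

      ls <- seg$length
      if (ls$variant == "fixed") {
        if (remaining < ls$n) return(fail("read_too_short"))
        add(rd$read_index, i, seg$kind,
            substr(s, cursor, cursor + ls$n - 1L), cursor,
            cursor + ls$n - 1L)
        cursor <- cursor + ls$n
      } else if (ls$variant == "unbounded") {
        if (seg$kind == "biological" && remaining < 1L) {
          return(fail("read_too_short"))
        }
        if (remaining > 0L) {
          add(rd$read_index, i, seg$kind, substr(s, cursor, slen), cursor,
              slen)
        } else if (seg$kind != "discard") {
          add(rd$read_index, i, seg$kind, "", cursor, cursor - 1L)
        }
        cursor <- slen + 1L
      } else if (ls$variant == "range") {
        next_is_anchor <- i < length(segs) && segs[[i + 1L]]$kind == "anchor"
        if (next_is_anchor) {
          anchor <- segs[[i + 1L]]$anchor_seq
          alen <- nchar(anchor)
          found <- NA_integer_
          for (l in ls$lo:ls$hi) {
            if (cursor + l + alen - 1L > slen) break
            if (substr(s, cursor + l, cursor + l + alen - 1L) == anchor) {
              found <- l
              break
            }
          }
          if (is.na(found)) return(fail("anchor_not_found"))
          add(rd$read_index, i, seg$kind,
              substr(s, cursor, cursor + found - 1L), cursor,
              cursor + found - 1L)
          cursor <- cursor + found + alen
          i <- i + 2L
          next
        } else {
          # terminal range: consumes everything that is left
          if (remaining < ls$lo || remaining > ls$hi) {
            return(fail("length_out_of_range"))
          }
          add(rd$read_index, i, seg$kind, substr(s, cursor, slen), cursor,
              slen)
          cursor <- slen + 1L
        }
      }
      i <- i + 1L
    }
  }

  extractions <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(read_index = integer(), segment = integer(),
               kind = character(), seq = character(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  }
  structure(list(status = "ok", extractions = extractions),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> status: %s\n", x$status))
  if (x$status == "ok") print(x$extractions)
  invisible(x)
}

pad_right <- function(s, width, pad) {
  deficit <- width - nchar(s)
  ifelse(deficit > 0L,
         paste0(s, strrep(pad, pmax(deficit, 0L))),
         s)
}

#' Normalize one matched fragment to the fixed simple layout
#'
#' Builds the technical read as all barcode extractions in input order,
#' each right-padded to its segment maximum with the pad base `"A"`,
#' followed by all UMI extractions padded likewise; padded quality
#' positions receive the fixed high-quality character `"I"`. The
#' biological read is the concatenation of the biological extractions;
#' anchors and discard segments are dropped. Note that padding can make
#' distinct variable-length barcodes collide (a 9-mer padded with A versus
#' a 10-mer ending in A); downstream permit-list barcode correction is
#' expected to absorb this.
#'
#' @param g The `fragment_geometry` that produced `m`.
#' @param m A `match_result` with status `ok`.
#' @param quals Character vector of quality strings parallel to the
#'   sequences given to [match_read()].
#' @param record_id Record identifier carried through unchanged.
#' @return A `normalized_pair`: list with `record_id`, `tech_seq`,
#'   `tech_qual`, `bio_seq`, `bio_qual`. `nchar(tech_seq)` always equals
#'   the sum of [technical_lengths()].
#' @export
normalize_pair <- function(g, m, quals, record_id = "") {
  if (!inherits(m, "match_result") || m$status != "ok") {
    stop("normalize_pair requires a match_result with status 'ok'")
  }
  if (length(quals) != length(g$reads)) {
    stop("one quality string per read descriptor is required")
  }
  ex <- m$extractions
  read_pos <- match(ex$read_index,
                    vapply(g$reads, `[[`, integer(1), "read_index"))
  ex$qual <- substr(quals[read_pos], ex$start, ex$end)
  ex$max_len <- NA_integer_
  tech <- ex$kind %in% c("barcode", "umi")
  if (any(tech)) {
    ex$max_len[tech] <- mapply(function(rp, si) {
      segment_max_length(g$reads[[rp]]$segments[[si]])
    }, read_pos[tech], ex$segment[tech])
  }

  tech_seq <- ""
  tech_qual <- ""
  for (kind in c("barcode", "umi")) {
    k <- ex[ex$kind == kind, , drop = FALSE]
    if (nrow(k)) {
      tech_seq <- paste0(tech_seq,
                         paste0(pad_right(k$seq, k$max_len, PAD_BASE),
                                collapse = ""))
      tech_qual <- paste0(tech_qual,
                          paste0(pad_right(k$qual, k$max_len, PAD_QUAL),
                                 collapse = ""))
    }
  }
  b <- ex[ex$kind == "biological", , drop = FALSE]
  structure(list(record_id = record_id,
                 tech_seq = tech_seq, tech_qual = tech_qual,
                 bio_seq = paste0(b$seq, collapse = ""),
                 bio_qual = paste0(b$qual, collapse = "")),
            class = "normalized_pair")
}

is_normalized_order <- function(g) {
  # TRUE iff every technical segment sits in read 1 with all barcode
  # segments before all UMI segments (so no reordering would occur).
  seen_umi <- FALSE
  for (r in g$reads) {
    for (s in r$segments) {
      if (s$kind == "umi") seen_umi <- TRUE
      if (s$kind == "barcode" && (seen_umi || r$read_index != 1L)) {
        return(FALSE)
      }
      if (s$kind == "umi" && r$read_index != 1L) return(FALSE)
    }
  }
  TRUE
}

#' The simple geometry a normalized stream conforms to
#'
#' For a complex geometry (or a simple one whose technical segments are
#' not already laid out barcode-block-first in read 1) this is
#' `1{b[B]u[U]}2{r:}` with `(B, U)` given by [technical_lengths()] — the
#' description handed to the mapper in place of the original. A geometry
#' already in normalized simple form is returned unchanged (canonicalized).
#'
#' @param g A valid `fragment_geometry` with bounded barcode/UMI segments.
#' @return A `fragment_geometry`.
#' @export
simplified_geometry <- function(g) {
  tl <- technical_lengths(g)
  if (classify_geometry(g) == "simple" && is_normalized_order(g)) {
    return(parse_geometry(render_geometry(g)))
  }
  parts <- character(0)
  if (tl[["barcode"]] > 0L) parts <- c(parts, sprintf("b[%d]", tl[["barcode"]]))
  if (tl[["umi"]] > 0L) parts <- c(parts, sprintf("u[%d]", tl[["umi"]]))
  if (length(parts) == 0L) stop("geometry has no technical segments")
  parse_geometry(sprintf("1{%s}2{r:}", paste0(parts, collapse = "")))
}

open_fastq <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

strip_record_id <- function(header) {
  id <- sub("^@", "", sub("\\s.*$", "", header))
  sub("/[12]$", "", id)
}

read_fastq_chunk <- function(con, n_records) {
  lines <- readLines(con, n = 4L * n_records)
  if (length(lines) == 0L) return(NULL)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ input: record not a multiple of 4 lines")
  }
  k <- length(lines) / 4L
  list(id = strip_record_id(lines[seq(1L, by = 4L, length.out = k)]),
       seq = lines[seq(2L, by = 4L, length.out = k)],
       qual = lines[seq(4L, by = 4L, length.out = k)],
       n = k)
}

#' Stream a read source through geometry normalization
#'
#' Reads synchronized FASTQ records (one file per read descriptor, gzip
#' accepted, named pipes allowed), matches each fragment against `g`,
#' normalizes passing fragments with [normalize_pair()], and emits the
#' technical reads to `out_tech` and the biological reads to `out_bio` —
#' or hands batches to an in-process `consumer`. Fragments that fail to
#' match are dropped from *both* outputs, so the two output streams carry
#' identical record ids in identical order. Records are processed in
#' bounded chunks, so memory use is independent of the number of records.
#'
#' @param g A valid `fragment_geometry`.
#' @param inputs Character vector of FASTQ paths, one per read descriptor.
#' @param out_tech,out_bio Output FASTQ paths (plain or `.gz`, or named
#'   pipes); omit both to use `consumer` instead.
#' @param consumer Optional function called per chunk with a data.frame
#'   (`record_id`, `tech_seq`, `tech_qual`, `bio_seq`, `bio_qual`).
#' @param chunk_size Records per chunk.
#' @param stats_path Optional path: the returned stats are also written
#'   there as JSON (`{total, passed, failed: {reason: count}}`).
#' @return A `transform_stats`: list with `total`, `passed`, and
#'   `failed_by_reason`; `passed + sum(failed_by_reason) == total` always.
#' @export
transform_stream <- function(g, inputs, out_tech = NULL, out_bio = NULL,
                             consumer = NULL, chunk_size = 5000L,
                             stats_path = NULL) {
  validate_geometry(g)
  if (length(inputs) != length(g$reads)) {
    stop(sprintf("geometry describes %d read(s); %d input file(s) given",
                 length(g$reads), length(inputs)))
  }
  write_files <- !is.null(out_tech)
  if (write_files && is.null(out_bio)) {
    stop("both out_tech and out_bio are required when writing files")
  }
  if (!write_files && is.null(consumer)) {
    consumer <- function(df) invisible(NULL)
  }

  cons <- lapply(inputs, open_fastq, mode = "r")
  on.exit(lapply(cons, close), add = TRUE)
  if (write_files) {
    tech_con <- open_fastq(out_tech, "w")
    bio_con <- open_fastq(out_bio, "w")
    on.exit({ close(tech_con); close(bio_con) }, add = TRUE)
  }

  total <- 0L
  passed <- 0L
  failed <- c(anchor_not_found = 0L, read_too_short = 0L,
              length_out_of_range = 0L)

  repeat {
    chunks <- lapply(cons, read_fastq_chunk, n_records = chunk_size)
    done <- vapply(chunks, is.null, logical(1))
    if (all(done)) break
    if (any(done)) {
      stop(sprintf(
        "desynchronized inputs: file %d exhausted at record %d",
        which(done)[1L], total + 1L))
    }
    ns <- vapply(chunks, `[[`, numeric(1), "n")
    if (length(unique(ns)) != 1L) {
      stop(sprintf(
        "desynchronized inputs: unequal record counts near record %d",
        total + min(ns) + 1L))
    }
    k <- ns[[1L]]
    if (length(chunks) > 1L) {
      for (j in 2:length(chunks)) {
        bad <- which(chunks[[1L]]$id != chunks[[j]]$id)
        if (length(bad)) {
          stop(sprintf(
            "desynchronized inputs: id mismatch at record %d ('%s' vs '%s')",
            total + bad[1L], chunks[[1L]]$id[bad[1L]],
            chunks[[j]]$id[bad[1L]]))
        }
      }
    }

    out_rows <- vector("list", k)
    n_out <- 0L
    for (rec in seq_len(k)) {
      total <- total + 1L
      seqs <- vapply(chunks, function(ch) ch$seq[rec], character(1))
      m <- match_read(g, seqs)
      if (m$status != "ok") {
        failed[[m$status]] <- failed[[m$status]] + 1L
        next
      }
      quals <- vapply(chunks, function(ch) ch$qual[rec], character(1))
      np <- normalize_pair(g, m, quals, record_id = chunks[[1L]]$id[rec])
      passed <- passed + 1L
      n_out <- n_out + 1L
      out_rows[[n_out]] <- np
    }

    if (n_out > 0L) {
      df <- data.frame(
        record_id = vapply(out_rows[1:n_out], `[[`, character(1), "record_id"),
        tech_seq = vapply(out_rows[1:n_out], `[[`, character(1), "tech_seq"),
        tech_qual = vapply(out_rows[1:n_out], `[[`, character(1), "tech_qual"),
        bio_seq = vapply(out_rows[1:n_out], `[[`, character(1), "bio_seq"),
        bio_qual = vapply(out_rows[1:n_out], `[[`, character(1), "bio_qual"),
        stringsAsFactors = FALSE)
      if (write_files) {
        writeLines(as.vector(rbind(paste0("@", df$record_id), df$tech_seq,
                                   "+", df$tech_qual)), tech_con)
        writeLines(as.vector(rbind(paste0("@", df$record_id), df$bio_seq,
                                   "+", df$bio_qual)), bio_con)
      } else {
        consumer(df)
      }
    }
  }

  stats <- structure(
    list(total = total, passed = passed, failed_by_reason = as.list(failed)),
    class = "transform_stats")
  if (!is.null(stats_path)) {
    jsonlite::write_json(
      list(total = total, passed = passed, failed = as.list(failed)),
      stats_path, auto_unbox = TRUE)
  }
  stats
}

#' @export
print.transform_stats <- function(x, ...) {
  cat(sprintf("<transform_stats> total: %d, passed: %d\n", x$total,
              x$passed))
  for (r in names(x$failed_by_reason)) {
    if (x$failed_by_reason[[r]] > 0L) {
      cat(sprintf("  failed (%s): %d\n", r, x$failed_by_reason[[r]]))
    }
  }
  invisible(x)
}
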