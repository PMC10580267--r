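# Brute-force matcher oracle: enumerate every admissible length assignment
# for the range segments of a read, test anchor equality under each
# assignment, and accept the assignment that minimizes the first range
# length, then the second, and so on. Written independently of
# match_read(): no cursor scanning, just full enumeration.

oracle_try_assignment <- function(segs, s, lens) {
  # lens: one assigned length per range segment, in order. Returns a list
  # of extraction rows, or NULL if the assignment is inadmissible.
  slen <- nchar(s)
  cursor <- 1L
  li <- 0L
  rows <- list()
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    last <- i == length(segs)
    if (seg$kind == "anchor") {
      alen <- nchar(seg$anchor_seq)
      if (cursor + alen - 1L > slen) return(NULL)
      if (substr(s, cursor, cursor + alen - 1L) != seg$anchor_seq) {
        return(NULL)
      }
      cursor <- cursor + alen
      next
    }
    ls <- seg$length
    take <- if (ls$variant == "fixed") {
      ls$n
    } else if (ls$variant == "range") {
      li <- li + 1L
      if (last && lens[[li]] != slen - cursor + 1L) return(NULL)
      lens[[li]]
    } else {
      if (!last) return(NULL)
      slen - cursor + 1L
    }
    if (ls$variant == "unbounded" && seg$kind == "biological" && take < 1L) {
      return(NULL)
    }
    if (cursor + take - 1L > slen) return(NULL)
    if (seg$kind != "discard") {
      rows[[length(rows) + 1L]] <- list(
        segment = i, kind = seg$kind,
        seq = substr(s, cursor, cursor + take - 1L))
    }
    cursor <- cursor + take
  }
  rows
}

oracle_fail_reason <- function(segs, s) {
  # Independent re-derivation of the per-read failure reason: recursive
  # formulation over (remaining segments, remaining suffix).
  rec <- function(k, suffix) {
    if (k > length(segs)) return(NULL)
    seg <- segs[[k]]
    last <- k == length(segs)
    if (seg$kind == "anchor") {
      a <- seg$anchor_seq
      if (nchar(suffix) < nchar(a)) return("read_too_short")
      if (substr(suffix, 1L, nchar(a)) != a) return("anchor_not_found")
      return(rec(k + 1L, substr(suffix, nchar(a) + 1L, nchar(suffix))))
    }
    ls <- seg$length
    if (ls$variant == "fixed") {
      if (nchar(suffix) < ls$n) return("read_too_short")
      return(rec(k + 1L, substr(suffix, ls$n + 1L, nchar(suffix))))
    }
    if (ls$variant == "unbounded") {
      if (seg$kind == "biological" && nchar(suffix) < 1L) {
        return("read_too_short")
      }
      return(NULL)
    }
    # range
    if (last) {
      if (nchar(suffix) < ls$lo || nchar(suffix) > ls$hi) {
        return("length_out_of_range")
      }
      return(NULL)
    }
    a <- segs[[k + 1L]]$anchor_seq
    for (l in ls$lo:ls$hi) {
      if (l + nchar(a) > nchar(suffix)) break
      if (substr(suffix, l + 1L, l + nchar(a)) == a) {
        return(rec(k + 2L, substr(suffix, l + nchar(a) + 1L,
                                  nchar(suffix))))
      }
    }
    "anchor_not_found"
  }
  rec(1L, s)
}

oracle_match <- function(g, seqs) {
  all_rows <- list()
  for (ri in seq_along(g$reads)) {
    segs <- g$reads[[ri]]$segments
    s <- seqs[[ri]]
    range_idx <- which(vapply(segs, function(x) {
      !is.null(x$length) && x$length$variant == "range"
    }, logical(1)))
    grids <- lapply(range_idx, function(i) {
      segs[[i]]$length$lo:segs[[i]]$length$hi
    })
    assignments <- if (length(grids)) {
      gr <- as.matrix(expand.grid(grids))
      gr[do.call(order, as.data.frame(gr)), , drop = FALSE]
    } else {
      matrix(integer(0), nrow = 1L, ncol = 0L)
    }
    found <- NULL
    for (row in seq_len(nrow(assignments))) {
      found <- oracle_try_assignment(segs, s, assignments[row, ])
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      reason <- oracle_fail_reason(segs, s)
      if (is.null(reason)) reason <- "anchor_not_found"
      return(list(status = reason, extractions = NULL))
    }
    for (r in found) {
      r$read_index <- g$reads[[ri]]$read_index
      all_rows[[length(all_rows) + 1L]] <- r
    }
  }
  list(status = "ok",
       extractions = data.frame(
         read_index = vapply(all_rows, `[[`, integer(1), "read_index"),
         segment = vapply(all_rows, `[[`, integer(1), "segment"),
         kind = vapply(all_rows, `[[`, character(1), "kind"),
         seq = vapply(all_rows, `[[`, character(1), "seq"),
         stringsAsFactors = FALSE))
}

# Random (geometry, read) instance generator for oracle-equivalence
# fuzzing: half truth-conforming reads, half unstructured random reads.
gen_match_instances <- function(n, seed) {
  set.seed(seed)
  geoms <- gen_geometry(max(25L, ceiling(n / 40L)), seed = seed + 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- parse_geometry(geoms$text[[(i - 1L) %% nrow(geoms) + 1L]])
    seqs <- if (i %% 2L == 0L) {
      rr <- tryCatch(gen_reads(g, n = 1L, seed = seed + i,
                               whitelist_size = 4L),
                     error = function(e) NULL)
      if (is.null(rr)) NULL else vapply(rr$seqs, `[[`, character(1), 1L)
    }
    if (is.null(seqs)) {
      seqs <- vapply(seq_along(g$reads), function(ri) {
        len <- sample(0:60, 1L)
        paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
      }, character(1))
    }
    out[[i]] <- list(g = g, seqs = seqs)
  }
  out
}

# Convenience for tests: the canonical complex sci-RNA-seq3-style layout.
SCI_GEOM <- "1{b[9-10]f[CAGAGC]u[8]b[10]}2{r:}"
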