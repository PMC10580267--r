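# Fragment-geometry description language: parser, validator, renderer,
# classifier, and technical-length accounting.
#
# Grammar (no whitespace anywhere):
#   geometry  := read_desc+
#   read_desc := READNUM '{' segment+ '}'
#   segment   := KIND '[' INT ']'            fixed length
#              | KIND '[' INT '-' INT ']'    length range
#              | KIND ':'                    unbounded
#              | 'f' '[' SEQ ']'             anchor (fixed sequence)
#   KIND      := 'b' | 'u' | 'x' | 'r'      barcode, UMI, discard, biological

.KIND_MAP <- c(b = "barcode", u = "umi", x = "discard", r = "biological")
.KIND_CODE <- c(barcode = "b", umi = "u", discard = "x", biological = "r")

#' Construct a segment descriptor
#'
#' Low-level constructor for one segment of a read descriptor. Most users
#' should build geometries with [parse_geometry()] instead.
#'
#' @param kind One of `"barcode"`, `"umi"`, `"discard"`, `"biological"`,
#'   `"anchor"`.
#' @param length A length specification made with [len_fixed()],
#'   [len_range()] or [len_unbounded()]; must be `NULL` for anchors.
#' @param anchor_seq Uppercase A/C/G/T string; required iff `kind` is
#'   `"anchor"`.
#' @return A list of class `geom_segment`.
#' @export
geom_segment <- function(kind, length = NULL, anchor_seq = NULL) {
  structure(list(kind = kind, length = length, anchor_seq = anchor_seq),
            class = "geom_segment")
}

#' Length specifications for geometry segments
#'
#' @param n,lo,hi Positive integer segment lengths in bases; a range
#'   requires `1 <= lo < hi`.
#' @return A list describing the length variant.
#' @name length_spec
NULL

#' @rdname length_spec
#' @export
len_fixed <- function(n) list(variant = "fixed", n = as.integer(n))

#' @rdname length_spec
#' @export
len_range <- function(lo, hi) {
  list(variant = "range", lo = as.integer(lo), hi = as.integer(hi))
}

#' @rdname length_spec
#' @export
len_unbounded <- function() list(variant = "unbounded")

geom_syntax_error <- function(msg, position) {
  stop(structure(
    class = c("geom_syntax_error", "error", "condition"),
    list(message = sprintf("geometry syntax error at position %d: %s",
                           position, msg),
         call = NULL, position = position)))
}

geom_validation_error <- function(msg) {
  stop(structure(
    class = c("geom_validation_error", "error", "condition"),
    list(message = sprintf("invalid geometry: %s", msg), call = NULL)))
}

#' Parse a fragment-geometry description string
#'
#' Parses the concise description language for single-cell fragment
#' geometry, e.g. `"1{b[16]u[12]x:}2{r:}"` (16 bp barcode, 12 bp UMI,
#' rest of read 1 discarded, all of read 2 biological) or the
#' sci-RNA-seq3-style `"1{b[9-10]f[CAGAGC]u[8]b[10]}2{r:}"` with a
#' variable-length barcode located by a fixed linker (anchor).
#'
#' Syntax errors report the 1-based character offset at which parsing
#' failed; structural violations of the language's rules (e.g. a range with
#' `lo >= hi`, an unbounded segment that is not last) are reported as
#' validation errors, a distinct condition class.
#'
#' @param text A single non-empty geometry string; whitespace is not
#'   permitted anywhere.
#' @return A `fragment_geometry` object: a list of read descriptors, each
#'   holding an ordered list of segments.
#' @seealso [render_geometry()], [classify_geometry()],
#'   [technical_lengths()]
#' @examples
#' g <- parse_geometry("1{b[16]u[12]x:}2{r:}")
#' classify_geometry(g)
#' technical_lengths(g)
#' @export
parse_geometry <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    stop("`text` must be a single non-empty string")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pos <- 1L

  peek <- function() if (pos <= n) chars[[pos]] else NA_character_
  advance <- function() pos <<- pos + 1L
  expect <- function(ch) {
    if (is.na(peek()) || peek() != ch) {
      got <- if (is.na(peek())) "end of input" else sprintf("'%s'", peek())
      geom_syntax_error(sprintf("expected '%s', found %s", ch, got), pos)
    }
    advance()
  }
  parse_int <- function() {
    start <- pos
    while (!is.na(peek()) && grepl("^[0-9]$", peek())) advance()
    if (pos == start) {
      geom_syntax_error("expected an integer", pos)
    }
    as.integer(paste0(chars[start:(pos - 1L)], collapse = ""))
  }

  parse_segment <- function() {
    kind_ch <- peek()
    seg_pos <- pos
    if (is.na(kind_ch)) geom_syntax_error("expected a segment", pos)
    if (kind_ch == "f") {
      advance()
      expect("[")
      start <- pos
      while (!is.na(peek()) && grepl("^[ACGT]$", peek())) advance()
      if (pos == start) {
        geom_syntax_error("anchor sequence must be non-empty A/C/G/T", pos)
      }
      seq <- paste0(chars[start:(pos - 1L)], collapse = "")
      expect("]")
      return(geom_segment("anchor", anchor_seq = seq))
    }
    if (!kind_ch %in% names(.KIND_MAP)) {
      geom_syntax_error(
        sprintf("unknown segment kind '%s' (expected b, u, x, r or f)",
                kind_ch), seg_pos)
    }
    advance()
    nxt <- peek()
    if (identical(nxt, ":")) {
      advance()
      return(geom_segment(.KIND_MAP[[kind_ch]], len_unbounded()))
    }
    expect("[")
    lo <- parse_int()
    if (identical(peek(), "-")) {
      advance()
      hi <- parse_int()
      expect("]")
      return(geom_segment(.KIND_MAP[[kind_ch]], len_range(lo, hi)))
    }
    expect("]")
    geom_segment(.KIND_MAP[[kind_ch]], len_fixed(lo))
  }

  parse_read <- function() {
    ri <- parse_int()
    expect("{")
    segments <- list()
    repeat {
      segments[[length(segments) + 1L]] <- parse_segment()
      if (identical(peek(), "}")) break
      if (is.na(peek())) {
        geom_syntax_error("unterminated read descriptor, expected '}'", pos)
      }
    }
    expect("}")
    list(read_index = ri, segments = segments)
  }

  reads <- list()
  repeat {
    reads[[length(reads) + 1L]] <- parse_read()
    if (is.na(peek())) break
  }

  g <- structure(list(reads = reads), class = "fragment_geometry")
  validate_geometry(g)
  g
}

#' Validate a fragment geometry
#'
#' Checks every structural rule of the language: read indices must be 1
#' and/or 2, unique and ascending; at most one unbounded segment per read
#' and only in last position; every range-length segment must either be
#' immediately followed by an anchor or be the last segment of its read
#' (otherwise its boundary is undecidable); ranges need `1 <= lo < hi`;
#' fixed lengths need `n >= 1`; anchor sequences are non-empty uppercase
#' A/C/G/T and permitted only in read 1.
#'
#' @param g A `fragment_geometry`.
#' @return `g`, invisibly; signals a `geom_validation_error` otherwise.
#' @export
validate_geometry <- function(g) {
  if (!inherits(g, "fragment_geometry")) {
    stop("`g` must be a fragment_geometry")
  }
  idx <- vapply(g$reads, function(r) r$read_index, integer(1))
  if (length(idx) == 0L) geom_validation_error("no read descriptors")
  if (anyDuplicated(idx)) {
    geom_validation_error("duplicate read indices")
  }
  if (is.unsorted(idx, strictly = TRUE)) {
    geom_validation_error("read indices must be ascending")
  }
  if (!all(idx %in% c(1L, 2L))) {
    geom_validation_error(
      sprintf("read indices must be 1 or 2, found %s",
              paste(setdiff(idx, 1:2), collapse = ", ")))
  }
  for (r in g$reads) {
    segs <- r$segments
    if (length(segs) == 0L) {
      geom_validation_error(sprintf("read %d has no segments", r$read_index))
    }
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      last <- i == length(segs)
      if (s$kind == "anchor") {
        if (is.null(s$anchor_seq) || !nzchar(s$anchor_seq) ||
            grepl("[^ACGT]", s$anchor_seq)) {
          geom_validation_error(sprintf(
            "read %d segment %d: anchor sequence must be non-empty uppercase A/C/G/T",
            r$read_index, i))
        }
        if (r$read_index != 1L) {
          geom_validation_error("anchors are permitted only in read 1")
        }
        if (!is.null(s$length)) {
          geom_validation_error("anchor segments carry no length spec")
        }
        next
      }
      if (!is.null(s$anchor_seq)) {
        geom_validation_error("only anchor segments carry a sequence")
      }
      ls <- s$length
      if (is.null(ls)) {
        geom_validation_error(sprintf(
          "read %d segment %d: missing length spec", r$read_index, i))
      }
      if (ls$variant == "fixed" && ls$n < 1L) {
        geom_validation_error(sprintf(
          "read %d segment %d: fixed length must be >= 1", r$read_index, i))
      }
      if (ls$variant == "range") {
        if (ls$lo < 1L || ls$lo >= ls$hi) {
          geom_validation_error(sprintf(
            "read %d segment %d: range requires 1 <= lo < hi (got %d-%d)",
            r$read_index, i, ls$lo, ls$hi))
        }
        followed_by_anchor <- !last && segs[[i + 1L]]$kind == "anchor"
        if (!followed_by_anchor && !last) {
          geom_validation_error(sprintf(
            "read %d segment %d: a range-length segment must be followed by an anchor or be last",
            r$read_index, i))
        }
      }
      if (ls$variant == "unbounded" && !last) {
        geom_validation_error(sprintf(
          "read %d segment %d: an unbounded segment must be last",
          r$read_index, i))
      }
    }
  }
  invisible(g)
}

render_segment <- function(s) {
  if (s$kind == "anchor") return(sprintf("f[%s]", s$anchor_seq))
  code <- .KIND_CODE[[s$kind]]
  ls <- s$length
  switch(ls$variant,
    fixed = sprintf("%s[%d]", code, ls$n),
    range = sprintf("%s[%d-%d]", code, ls$lo, ls$hi),
    unbounded = sprintf("%s:", code))
}

#' Render a fragment geometry to its canonical string
#'
#' The canonical form is the minimal text accepted by [parse_geometry()]:
#' no whitespace, fixed lengths as `k[n]`, ranges as `k[lo-hi]`, unbounded
#' as `k:`, anchors as `f[SEQ]`. `parse_geometry(render_geometry(g))` is
#' structurally identical to `g`.
#'
#' @param g A valid `fragment_geometry`.
#' @return A single geometry string.
#' @export
render_geometry <- function(g) {
  validate_geometry(g)
  paste0(vapply(g$reads, function(r) {
    sprintf("%d{%s}", r$read_index,
            paste0(vapply(r$segments, render_segment, character(1)),
                   collapse = ""))
  }, character(1)), collapse = "")
}

#' Classify a geometry as simple or complex
#'
#' A geometry is *complex* exactly when it contains a range-length segment
#' or an anchor (i.e. variable lengths or floating positions); otherwise it
#' is *simple* — only fixed positions and fixed-length barcodes/UMIs, the
#' class that mappers support natively. Complex geometries must be
#' normalized (see [transform_stream()]) before mapping.
#'
#' @param g A valid `fragment_geometry`.
#' @return `"simple"` or `"complex"`.
#' @export
classify_geometry <- function(g) {
  validate_geometry(g)
  for (r in g$reads) {
    for (s in r$segments) {
      if (s$kind == "anchor") return("complex")
      if (!is.null(s$length) && s$length$variant == "range") {
        return("complex")
      }
    }
  }
  "simple"
}

segment_max_length <- function(s) {
  ls <- s$length
  switch(ls$variant,
    fixed = ls$n,
    range = ls$hi,
    unbounded = stop(sprintf(
      "unbounded %s segment has no finite length", s$kind)))
}

#' Total technical lengths of a geometry
#'
#' Sums, over all barcode segments and over all UMI segments, the maximum
#' length of each (the upper bound for ranges). These totals define the
#' fixed simple layout that normalization pads variable extractions into.
#'
#' @param g A valid `fragment_geometry` whose barcode/UMI segments are all
#'   bounded.
#' @return Named integer vector `c(barcode = B, umi = U)` in bases.
#' @export
technical_lengths <- function(g) {
  validate_geometry(g)
  bc <- 0L
  umi <- 0L
  for (r in g$reads) {
    for (s in r$segments) {
      if (s$kind == "barcode") bc <- bc + segment_max_length(s)
      if (s$kind == "umi") umi <- umi + segment_max_length(s)
    }
  }
  c(barcode = bc, umi = umi)
}

#' @export
print.fragment_geometry <- function(x, ...) {
  tl <- tryCatch(technical_lengths(x), error = function(e) NULL)
  cat(sprintf("<fragment_geometry> %s [%s]\n", render_geometry(x),
              classify_geometry(x)))
  if (!is.null(tl)) {
    cat(sprintf("  barcode: %d bp, UMI: %d bp\n", tl[["barcode"]],
                tl[["umi"]]))
  }
  invisible(x)
}

#' @export
format.fragment_geometry <- function(x, ...) render_geometry(x)
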