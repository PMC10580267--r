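# Augmented transcriptome references (splici / spliceu) and 3-column
# transcript-to-gene maps, built from a genome FASTA and GTF annotation.
#
# All coordinates are 1-based closed intervals (GTF convention): the
# substring [s..e] has length e - s + 1.

#' Load transcript models from a GTF annotation
#'
#' Reads exon features and assembles one transcript model per
#' `transcript_id`: chromosome, strand, gene, and an ascending list of
#' disjoint exon intervals. Attributes in both the GTF dialect
#' (`key "value";`) and the `key=value` dialect are accepted; unknown
#' attributes are ignored. Malformed lines are reported with their line
#' number; a transcript whose exons span two chromosomes or strands is an
#' error, as is an exon without a `gene_id`.
#'
#' @param path Path to a GTF file (plain or gzip).
#' @param strict If `TRUE` (default), overlapping exons within one
#'   transcript are rejected; if `FALSE` they are merged.
#' @return A `transcript_models` object: a named list (by transcript id)
#'   of models, each with `transcript_id`, `gene_id`, `chrom`, `strand`
#'   and an `exons` data.frame (`start`, `end`).
#' @export
load_annotation <- function(path, strict = TRUE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)

  tx_exons <- new.env(parent = emptyenv())
  tx_meta <- new.env(parent = emptyenv())
  tx_order <- character(0)
  missing_gene <- character(0)

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 9L) {
      stop(sprintf("malformed annotation line %d: expected 9 tab-separated fields, found %d",
                   ln, length(fields)))
    }
    if (fields[[3L]] != "exon") next
    start <- suppressWarnings(as.integer(fields[[4L]]))
    end <- suppressWarnings(as.integer(fields[[5L]]))
    if (is.na(start) || is.na(end) || start < 1L || start > end) {
      stop(sprintf("malformed annotation line %d: bad coordinates '%s'-'%s'",
                   ln, fields[[4L]], fields[[5L]]))
    }
    strand <- fields[[7L]]
    if (!strand %in% c("+", "-")) {
      stop(sprintf("malformed annotation line %d: strand must be + or -", ln))
    }
    attrs <- parse_gtf_attributes(fields[[9L]])
    tid <- attrs[["transcript_id"]]
    if (is.null(tid) || !nzchar(tid)) {
      stop(sprintf("annotation line %d: exon lacks a transcript_id", ln))
    }
    gid <- attrs[["gene_id"]]
    if (is.null(gid) || !nzchar(gid)) {
      missing_gene <- union(missing_gene, tid)
      gid <- NA_character_
    }

    if (is.null(tx_meta[[tid]])) {
      tx_meta[[tid]] <- list(gene_id = gid, chrom = fields[[1L]],
                             strand = strand)
      tx_exons[[tid]] <- list()
      tx_order <- c(tx_order, tid)
    } else {
      meta <- tx_meta[[tid]]
      if (meta$chrom != fields[[1L]] || meta$strand != strand) {
        stop(sprintf(
          "annotation line %d: transcript '%s' has exons on more than one chromosome or strand",
          ln, tid))
      }
      if (is.na(meta$gene_id) && !is.na(gid)) tx_meta[[tid]]$gene_id <- gid
    }
    tx_exons[[tid]][[length(tx_exons[[tid]]) + 1L]] <- c(start, end)
  }

  if (length(missing_gene)) {
    still <- missing_gene[vapply(missing_gene, function(t) {
      is.na(tx_meta[[t]]$gene_id)
    }, logical(1))]
    if (length(still)) {
      stop(sprintf("transcripts lacking gene_id: %s",
                   paste(sort(still), collapse = ", ")))
    }
  }
  if (length(tx_order) == 0L) {
    stop("annotation contains no exon features")
  }

  models <- lapply(tx_order, function(tid) {
    meta <- tx_meta[[tid]]
    ex <- do.call(rbind, tx_exons[[tid]])
    ex <- ex[order(ex[, 1L], ex[, 2L]), , drop = FALSE]
    ir <- IRanges::IRanges(start = ex[, 1L], end = ex[, 2L])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    if (length(red) < length(ir)) {
      if (strict) {
        stop(sprintf("transcript '%s' has overlapping exons (set strict = FALSE to merge)",
                     tid))
      }
      ir <- red
    }
    structure(list(transcript_id = tid, gene_id = meta$gene_id,
                   chrom = meta$chrom, strand = meta$strand,
                   exons = data.frame(start = IRanges::start(ir),
                                      end = IRanges::end(ir))),
              class = "transcript_model")
  })
  names(models) <- tx_order
  structure(models, class = "transcript_models")
}

parse_gtf_attributes <- function(text) {
  out <- list()
  for (tok in strsplit(text, ";", fixed = TRUE)[[1L]]) {
    tok <- trimws(tok)
    if (!nzchar(tok)) next
    m <- regmatches(tok, regexec('^([A-Za-z_][A-Za-z0-9_]*)\\s*(?:=|\\s)\\s*"?([^"]*)"?$',
                                 tok))[[1L]]
    if (length(m) == 3L) out[[m[[2L]]]] <- m[[3L]]
  }
  out
}

#' @export
print.transcript_models <- function(x, ...) {
  genes <- unique(vapply(x, `[[`, character(1), "gene_id"))
  cat(sprintf("<transcript_models> %d transcript(s) in %d gene(s)\n",
              length(x), length(genes)))
  invisible(x)
}

genome_as_strings <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    genome
  } else {
    stop("`genome` must be a named character vector or a DNAStringSet")
  }
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract the spliced sequence of one transcript
#'
#' Concatenates the exon substrings in genomic order; for minus-strand
#' transcripts the concatenation is reverse-complemented as a whole.
#'
#' @param model A `transcript_model` (see [load_annotation()]).
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @return The spliced nucleotide sequence as a single string.
#' @export
extract_spliced <- function(model, genome) {
  gs <- genome_as_strings(genome)
  if (!model$chrom %in% names(gs)) {
    stop(sprintf("chromosome '%s' not present in the genome", model$chrom))
  }
  chrom_seq <- gs[[model$chrom]]
  if (any(model$exons$end > nchar(chrom_seq))) {
    stop(sprintf("transcript '%s' extends past the end of chromosome '%s'",
                 model$transcript_id, model$chrom))
  }
  s <- paste0(substring(chrom_seq, model$exons$start, model$exons$end),
              collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

#' Collapsed, flank-extended introns of one gene
#'
#' Per transcript, the introns are the gaps between consecutive exons.
#' Each intron is extended by `flank` bases on both sides, clamped to the
#' chromosome, and the union over all the gene's transcripts is merged —
#' overlapping *and abutting* intervals coalesce, since abutting flanked
#' introns cannot be distinguished by any read. Merged intervals are
#' labeled `<gene>-I`, `<gene>-I1`, `<gene>-I2`, ... in ascending genomic
#' order.
#'
#' @param models List of `transcript_model`s, all of the same gene.
#' @param flank Non-negative flank width in bases.
#' @param chrom_len Chromosome length for clamping.
#' @return A data.frame (`chrom`, `start`, `end`, `strand`, `label`); zero
#'   rows for single-exon genes.
#' @export
gene_introns <- function(models, flank, chrom_len) {
  stopifnot(flank >= 0)
  gene_ids <- unique(vapply(models, `[[`, character(1), "gene_id"))
  chroms <- unique(vapply(models, `[[`, character(1), "chrom"))
  strands <- unique(vapply(models, `[[`, character(1), "strand"))
  if (length(gene_ids) != 1L || length(chroms) != 1L || length(strands) != 1L) {
    stop("all models must belong to one gene on one chromosome and strand")
  }
  starts <- integer(0)
  ends <- integer(0)
  for (m in models) {
    ex <- m$exons
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      is <- ex$end[i] + 1L
      ie <- ex$start[i + 1L] - 1L
      if (is > ie) next  # abutting exons: no intron
      starts <- c(starts, max(1L, is - as.integer(flank)))
      ends <- c(ends, min(as.integer(chrom_len), ie + as.integer(flank)))
    }
  }
  if (length(starts) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  merged <- IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
  labels <- if (length(merged) == 1L) {
    paste0(gene_ids, "-I")
  } else {
    c(paste0(gene_ids, "-I"),
      paste0(gene_ids, "-I", seq_len(length(merged) - 1L)))
  }
  data.frame(chrom = chroms, start = IRanges::start(merged),
             end = IRanges::end(merged), strand = strands, label = labels,
             stringsAsFactors = FALSE)
}

group_models_by_gene <- function(models) {
  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  split(unclass(models), factor(gene_ids, levels = unique(gene_ids)))
}

new_augmented_reference <- function(records, t2g, metadata) {
  if (anyDuplicated(names(records))) {
    stop(sprintf("duplicate reference record names: %s",
                 paste(unique(names(records)[duplicated(names(records))]),
                       collapse = ", ")))
  }
  stopifnot(identical(names(records), t2g$seq_name))
  structure(list(records = Biostrings::DNAStringSet(records), t2g = t2g,
                 metadata = metadata),
            class = "augmented_reference")
}

spliced_block <- function(genome, models) {
  recs <- vapply(models, extract_spliced, character(1), genome = genome)
  names(recs) <- vapply(models, `[[`, character(1), "transcript_id")
  list(records = recs,
       t2g = data.frame(seq_name = names(recs),
                        gene_id = vapply(models, `[[`, character(1),
                                         "gene_id"),
                        status = "S", stringsAsFactors = FALSE))
}

#' Build a splici (spliced + intron) augmented reference
#'
#' The reference contains every spliced transcript (status `S`), followed
#' by, per gene, the collapsed flank-extended intron sequences (status
#' `U`). The flank width is `read_length - flank_trim`; intron sequences
#' of minus-strand genes are reverse-complemented; identical intron
#' sequences within one gene are deduplicated (the first occurrence in
#' genomic order is kept).
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param models A `transcript_models` object or list of models.
#' @param read_length Read length the index is built for, in bases.
#' @param flank_trim Bases trimmed off the read length to obtain the
#'   flank; default 5.
#' @return An `augmented_reference`: `records` (`DNAStringSet`), `t2g`
#'   (data.frame `seq_name`, `gene_id`, `status`), `metadata`.
#' @export
build_splici <- function(genome, models, read_length, flank_trim = 5L) {
  if (flank_trim > read_length) {
    stop("flank_trim must not exceed read_length")
  }
  flank <- as.integer(read_length) - as.integer(flank_trim)
  gs <- genome_as_strings(genome)
  sp <- spliced_block(gs, models)
  recs <- sp$records
  t2g <- sp$t2g

  dedup_dropped <- 0L
  for (gene in group_models_by_gene(models)) {
    chrom <- gene[[1L]]$chrom
    strand <- gene[[1L]]$strand
    introns <- gene_introns(gene, flank, nchar(gs[[chrom]]))
    if (nrow(introns) == 0L) next
    seqs <- substring(gs[[chrom]], introns$start, introns$end)
    if (strand == "-") seqs <- vapply(seqs, revcomp, character(1))
    keep <- !duplicated(seqs)
    dedup_dropped <- dedup_dropped + sum(!keep)
    seqs <- unname(seqs[keep])
    labels <- introns$label[keep]
    recs <- c(recs, stats::setNames(seqs, labels))
    t2g <- rbind(t2g, data.frame(seq_name = labels,
                                 gene_id = gene[[1L]]$gene_id,
                                 status = "U", stringsAsFactors = FALSE))
  }
  new_augmented_reference(
    recs, t2g,
    metadata = list(ref_type = "splici",
                    read_length = as.integer(read_length),
                    flank_trim = as.integer(flank_trim), flank = flank,
                    n_spliced = length(sp$records),
                    n_intron = length(recs) - length(sp$records),
                    n_intron_dedup_dropped = dedup_dropped,
                    provenance = list(builder = "screadkit",
                                      builder_version = as.character(
                                        utils::packageVersion("screadkit")))))
}

#' Build a spliceu (spliced + unspliced gene body) augmented reference
#'
#' The reference contains every spliced transcript (status `S`) plus, per
#' gene, one gene-body sequence spanning `[min exon start, max exon end]`
#' over all the gene's transcripts, named `<gene>-U` (status `U`),
#' reverse-complemented for minus-strand genes.
#'
#' @inheritParams build_splici
#' @return An `augmented_reference`.
#' @export
build_spliceu <- function(genome, models) {
  gs <- genome_as_strings(genome)
  sp <- spliced_block(gs, models)
  recs <- sp$records
  t2g <- sp$t2g
  for (gene in group_models_by_gene(models)) {
    chrom <- gene[[1L]]$chrom
    lo <- min(vapply(gene, function(m) min(m$exons$start), numeric(1)))
    hi <- max(vapply(gene, function(m) max(m$exons$end), numeric(1)))
    if (hi > nchar(gs[[chrom]])) {
      stop(sprintf("gene '%s' extends past the end of chromosome '%s'",
                   gene[[1L]]$gene_id, chrom))
    }
    s <- substring(gs[[chrom]], lo, hi)
    if (gene[[1L]]$strand == "-") s <- revcomp(s)
    nm <- paste0(gene[[1L]]$gene_id, "-U")
    recs <- c(recs, stats::setNames(s, nm))
    t2g <- rbind(t2g, data.frame(seq_name = nm,
                                 gene_id = gene[[1L]]$gene_id,
                                 status = "U", stringsAsFactors = FALSE))
  }
  new_augmented_reference(
    recs, t2g,
    metadata = list(ref_type = "spliceu", n_spliced = length(sp$records),
                    n_gene_body = length(recs) - length(sp$records),
                    provenance = list(builder = "screadkit",
                                      builder_version = as.character(
                                        utils::packageVersion("screadkit")))))
}

#' @export
print.augmented_reference <- function(x, ...) {
  cat(sprintf("<augmented_reference> %s: %d record(s) (%d S, %d U)\n",
              x$metadata$ref_type, nrow(x$t2g), sum(x$t2g$status == "S"),
              sum(x$t2g$status == "U")))
  invisible(x)
}

#' Write an augmented reference to disk
#'
#' Writes `ref.fa` (FASTA of all records), `t2g_3col.tsv` (tab-separated
#' `seq_name`, `gene_id`, `status`), and `ref_metadata.json` into
#' `out_dir`.
#'
#' @param ref An `augmented_reference`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_reference <- function(ref, out_dir) {
  stopifnot(inherits(ref, "augmented_reference"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(out_dir, "ref.fa"),
                t2g = file.path(out_dir, "t2g_3col.tsv"),
                metadata = file.path(out_dir, "ref_metadata.json"))
  Biostrings::writeXStringSet(ref$records, paths$fasta)
  utils::write.table(ref$t2g, paths$t2g, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(ref$metadata, paths$metadata, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Stage a user-provided (direct) reference
#'
#' Copies an existing transcript FASTA and its two-column
#' transcript-to-gene map verbatim into `out_dir` and writes a metadata
#' sidecar with `ref_type = "direct"`.
#'
#' @param fasta,t2g Paths to the user's files.
#' @param out_dir Output directory.
#' @return Invisibly, a named list of the staged paths.
#' @export
write_direct_reference <- function(fasta, t2g, out_dir) {
  if (!file.exists(fasta) || !file.exists(t2g)) {
    stop("direct reference requires existing FASTA and t2g files")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(out_dir, basename(fasta)),
                t2g = file.path(out_dir, basename(t2g)),
                metadata = file.path(out_dir, "ref_metadata.json"))
  file.copy(fasta, paths$fasta, overwrite = TRUE)
  file.copy(t2g, paths$t2g, overwrite = TRUE)
  jsonlite::write_json(list(ref_type = "direct",
                            source_fasta = basename(fasta),
                            source_t2g = basename(t2g)),
                       paths$metadata, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
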