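#' Read a FASTA file
#'
#' Order-preserving reader returning uppercased sequences named by the
#' first whitespace-delimited token of each header; the full header line is
#' kept in the `"descriptions"` attribute.
#'
#' @param path FASTA file (nucleotide or protein).
#' @return named character vector of sequences, with attribute
#'   `descriptions` (named character vector of full headers).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) && !startsWith(trimws(first[nonblank[1]]), ">")) {
    stop("malformed FASTA record at line ", nonblank[1], " of ", path,
         ": expected '>' header")
  }
  set <- Biostrings::readBStringSet(path)
  desc <- names(set)
  ids <- sub("\\s.*$", "", desc)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  names(desc) <- ids
  attr(seqs, "descriptions") <- desc
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector (names become headers; a
#'   `descriptions` attribute, if present, is used instead).
#' @param path output path.
#' @param width line width for wrapping.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  desc <- attr(seqs, "descriptions")
  headers <- if (!is.null(desc)) unname(desc[names(seqs)]) else names(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", headers[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a coding sequence
#'
#' Standard genetic code; a trailing stop codon is dropped. Deviations are
#' flagged rather than fatal: a length not divisible by 3 sets the
#' `partial_codon` attribute (the trailing partial codon is ignored), and
#' any internal stop sets `internal_stop` (stops are kept as `*` in the
#' returned protein).
#'
#' @param cds nucleotide string, length >= 3.
#' @return protein string with logical attributes `partial_codon` and
#'   `internal_stop`.
#' @examples
#' translate_cds("ATGGAA")             # "ME"
#' translate_cds("ATGTAA")             # "M" (trailing stop dropped)
#' attr(translate_cds("ATGTAAGAA"), "internal_stop")
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("coding sequence shorter than one codon")
  partial <- (n %% 3L) != 0L
  nfull <- n - (n %% 3L)
  codons <- substring(cds, seq(1L, nfull, 3L), seq(3L, nfull, 3L))
  res <- unname(Biostrings::GENETIC_CODE[codons])
  res[is.na(res)] <- "X"  # ambiguity letters in the codon
  aa <- paste(res, collapse = "")
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  internal <- grepl("*", aa, fixed = TRUE)
  structure(aa, partial_codon = partial, internal_stop = internal)
}

#' Construct a gene model
#'
#' A gene model is one transcript's CDS geometry plus derived sequences.
#' Coordinates are 0-based half-open internally; [read_gff3()] and
#' [write_gene_models()] convert from/to the 1-based inclusive GFF3
#' convention at the boundary. `intron_records` hold, per coding intron,
#' the number of coding nucleotides preceding it (`cds_offset`) and its
#' genomic span.
#'
#' @param id transcript (mRNA) identifier.
#' @param seqid contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds_segments data.frame with 0-based half-open `start`, `end`
#'   columns, in genomic order.
#' @param genome_seq sequence of the contig (character), used to splice.
#' @param gene_id optional parent gene identifier (defaults to `id`).
#' @param n_utr_introns count of introns lying outside the CDS (recorded,
#'   never coded).
#' @return object of class `"gene_model"`.
#' @export
gene_model <- function(id, seqid, strand, cds_segments, genome_seq,
                       gene_id = id, n_utr_introns = 0L) {
  stopifnot(strand %in% c("+", "-"), nrow(cds_segments) >= 1L,
            all(cds_segments$end > cds_segments$start))
  cds_segments <- cds_segments[order(cds_segments$start), , drop = FALSE]
  pieces <- substring(genome_seq, cds_segments$start + 1L, cds_segments$end)
  if (strand == "-") {
    pieces <- rev(vapply(pieces, revcomp, "", USE.NAMES = FALSE))
  }
  spliced <- paste(pieces, collapse = "")
  lens <- nchar(pieces)  # in transcription order
  n_introns <- nrow(cds_segments) - 1L
  if (n_introns > 0L) {
    cds_offset <- cumsum(lens)[seq_len(n_introns)]
    # genomic gaps between consecutive segments, in transcription order
    gaps <- data.frame(start = cds_segments$end[-nrow(cds_segments)],
                       end = cds_segments$start[-1L])
    if (strand == "-") gaps <- gaps[rev(seq_len(nrow(gaps))), , drop = FALSE]
    intron_records <- data.frame(cds_offset = cds_offset,
                                 genomic_start = gaps$start,
                                 genomic_end = gaps$end)
  } else {
    intron_records <- data.frame(cds_offset = integer(0),
                                 genomic_start = integer(0),
                                 genomic_end = integer(0))
  }
  prot <- translate_cds(spliced)
  structure(
    list(id = id, gene_id = gene_id, seqid = seqid, strand = strand,
         cds_segments = cds_segments, spliced_cds = spliced,
         protein = as.character(prot),
         partial = isTRUE(attr(prot, "partial_codon")),
         internal_stop = isTRUE(attr(prot, "internal_stop")),
         intron_records = intron_records,
         n_utr_introns = as.integer(n_utr_introns)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene model %s (%s, strand %s): %d CDS segment(s), %d coding intron(s), %d aa%s\n",
              x$id, x$seqid, x$strand, nrow(x$cds_segments),
              nrow(x$intron_records), nchar(x$protein),
              if (x$partial) " [partial]" else ""))
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read gene models from GFF3 + genome
#'
#' Builds one [gene_model()] per mRNA/transcript feature from its CDS
#' children. Minus-strand models are reverse-complemented and ordered
#' 5'-to-3'; coding introns are derived from the gaps between consecutive
#' CDS segments, and exon-exon gaps without coding sequence on both sides
#' are tallied as UTR introns.
#'
#' @param path GFF3 file with gene/mRNA/CDS (and optionally exon) rows.
#' @param genome named character vector of contig sequences (see
#'   [read_fasta()]).
#' @return named list of `gene_model` objects (mRNAs without CDS are
#'   skipped with a warning).
#' @export
read_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ %in% c("mRNA", "transcript")]
  if (length(mrna) == 0L) stop("no mRNA/transcript features in ", path)
  parent_of <- function(g) {
    p <- gr$Parent[match(g$ID, gr$ID)]
    vapply(p, function(v) if (length(v)) v[[1]] else NA_character_, "")
  }
  out <- list()
  for (i in seq_along(mrna)) {
    mid <- mrna$ID[i]
    kids <- gr[typ == "CDS" &
                 vapply(gr$Parent, function(p) mid %in% p, TRUE)]
    if (length(kids) == 0L) {
      warning("mRNA ", mid, " has no CDS features; skipped")
      next
    }
    seqid <- as.character(GenomicRanges::seqnames(kids))[1]
    if (!seqid %in% names(genome)) {
      stop("CDS of ", mid, " references contig '", seqid,
           "' absent from the genome")
    }
    segs <- data.frame(
      start = GenomicRanges::start(kids) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(kids)
    )
    strand <- as.character(GenomicRanges::strand(kids))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    exons <- gr[typ == "exon" &
                  vapply(gr$Parent, function(p) mid %in% p, TRUE)]
    n_utr <- 0L
    if (length(exons) >= 2L) {
      n_exon_gaps <- length(exons) - 1L
      n_utr <- n_exon_gaps - (length(kids) - 1L)
      if (n_utr < 0L) n_utr <- 0L
    }
    gid <- parent_of(mrna[i])
    out[[mid]] <- gene_model(
      id = mid, seqid = seqid, strand = strand, cds_segments = segs,
      genome_seq = genome[[seqid]],
      gene_id = if (is.na(gid)) mid else gid,
      n_utr_introns = n_utr
    )
  }
  out
}

# GFF3 phase of the CDS segment following `offset` coding nucleotides
phase_after_offset <- function(offset) (3L - (offset %% 3L)) %% 3L

#' Write gene models back to GFF3 (+ FASTA)
#'
#' Emits gene/mRNA/exon/CDS rows (1-based inclusive coordinates,
#' `##gff-version 3` header) with CDS phases computed from each segment's
#' preceding coding length. Round-trips with [read_gff3()].
#'
#' @param models list of [gene_model()] objects.
#' @param gff_path output GFF3 path.
#' @param genome optional named character vector; when given, contigs
#'   referenced by the models are written to `fasta_path`.
#' @param fasta_path output FASTA path (required when `genome` is given).
#' @return invisibly, `gff_path`.
#' @export
write_gene_models <- function(models, gff_path, genome = NULL,
                              fasta_path = NULL) {
  rows <- list()
  for (m in models) {
    segs <- m$cds_segments  # genomic order
    n <- nrow(segs)
    ord <- if (m$strand == "-") rev(seq_len(n)) else seq_len(n)
    lens <- (segs$end - segs$start)[ord]
    before <- c(0L, cumsum(lens))[seq_len(n)]
    phase <- phase_after_offset(before)[order(ord)]  # back to genomic order
    span <- c(min(segs$start) + 1L, max(segs$end))
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = m$seqid, source = "serpintron",
      type = c("gene", "mRNA", rep("exon", n), rep("CDS", n)),
      start = c(span[1], span[1], segs$start + 1L, segs$start + 1L),
      end = c(span[2], span[2], segs$end, segs$end),
      score = ".", strand = m$strand,
      phase = c(".", ".", rep(".", n), as.character(phase)),
      attributes = c(
        paste0("ID=", m$gene_id),
        paste0("ID=", m$id, ";Parent=", m$gene_id),
        paste0("ID=", m$id, ".exon", seq_len(n), ";Parent=", m$id),
        paste0("ID=", m$id, ".cds", seq_len(n), ";Parent=", m$id)
      ),
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  con <- file(gff_path, "w")
  writeLines("##gff-version 3", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  if (!is.null(genome)) {
    stopifnot(!is.null(fasta_path))
    used <- unique(vapply(models, `[[`, "", "seqid"))
    write_fasta(genome[used], fasta_path)
  }
  invisible(gff_path)
}
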