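# codon table for back-translation: sense codons per amino acid
.CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- .CODONS_BY_AA[[a]]
    if (is.null(a) || is.null(opts)) stop("cannot back-translate residue ", a)
    opts[sample.int(length(opts), 1L)]
  }, "", USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

mutate_protein <- function(protein, rate) {
  stopifnot(rate >= 0, rate <= 0.3)
  if (rate == 0) return(protein)
  aa20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  res <- strsplit(protein, "")[[1]]
  hit <- which(stats::runif(length(res)) < rate)
  for (i in hit) res[i] <- sample(setdiff(aa20, res[i]), 1L)
  paste(res, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic serpin gene with prescribed intron codes
#'
#' Inverts the coding scheme for validation: the scaffold protein (the
#' reference frame itself, optionally with seeded point mutations) is
#' back-translated with seeded synonymous codons, and an intron with fixed
#' `GT...AG` termini and random interior is inserted at the coding offset
#' `3*(codon-1) + {a:1, b:2, c:3}[letter]` of each target code. On the
#' unmutated scaffold the protein aligns to the reference as the identity,
#' so coding the resulting gene model provably recovers the target codes.
#' Output is deterministic per seed, byte-identical across runs.
#'
#' @param target_codes character vector of intron codes (e.g.
#'   `c("192a","282b","331c")`); may be empty for a single-exon gene.
#' @param seed integer seed driving codon choice, intron sequences,
#'   flanks, and scaffold mutations.
#' @param mutation_rate per-residue substitution rate on the scaffold,
#'   in [0, 0.3]; 0 keeps the reference scaffold.
#' @param intron_length_range integer length-2; intron lengths are drawn
#'   uniformly from this range (default 120-300 nt).
#' @param flank length of random sequence added on each side of the gene.
#' @param id gene identifier (also used for the contig name).
#' @param strand `"+"` or `"-"`: the minus-strand gene is the
#'   reverse-complement layout of the same transcript.
#' @param registry a [load_registry()] bundle (used for the expected
#'   classification).
#' @return object of class `"synthetic_gene"`: list with `id`,
#'   `target_codes` (sorted), `model` (a [gene_model()]), `genome` (named
#'   contig sequence), `protein`, and `expected_call` (the [classify()]
#'   result for the target codes).
#' @examples
#' g <- generate_gene(c("192a", "282b", "331c"), seed = 1)
#' g$model$intron_records$cds_offset  # 574 845 993
#' @export
generate_gene <- function(target_codes = character(0), seed = 1L,
                          mutation_rate = 0,
                          intron_length_range = c(120L, 300L),
                          flank = 60L, id = "syn1", strand = "+",
                          registry = load_registry()) {
  stopifnot(strand %in% c("+", "-"),
            length(intron_length_range) == 2L,
            intron_length_range[1] >= 10L,
            intron_length_range[1] <= intron_length_range[2])
  target_codes <- as.character(target_codes)
  if (length(target_codes)) {
    p <- parse_intron_code(target_codes)
    if (any(p$approximate)) stop("target codes cannot be approximate")
    ord <- order(p$codon, p$letter)
    target_codes <- target_codes[ord]
    p <- p[ord, ]
    if (anyDuplicated(paste0(p$codon, p$letter))) {
      stop("duplicate target codes")
    }
  }
  with_local_seed(seed, {
    scaffold <- reference_frame()$sequence
    if (mutation_rate > 0) scaffold <- mutate_protein(scaffold, mutation_rate)
    if (length(target_codes) &&
        max(parse_intron_code(target_codes)$codon) > nchar(scaffold)) {
      stop("target code beyond scaffold length (", nchar(scaffold), " aa)")
    }
    cds <- paste0(back_translate(scaffold), "TAA")
    offs <- if (length(target_codes)) {
      pp <- parse_intron_code(target_codes)
      local_code_to_offset(pp$codon, pp$letter)
    } else integer(0)
    stopifnot(all(offs >= 1L), all(offs <= nchar(cds) - 1L))
    # CDS pieces between consecutive intron insertion points
    bounds <- c(0L, offs, nchar(cds))
    pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
    introns <- vapply(seq_along(offs), function(i) {
      len <- sample(seq(intron_length_range[1], intron_length_range[2]), 1L)
      paste0("GT", random_dna(len - 4L), "AG")
    }, "")
    gene_seq <- paste0(pieces[1],
                       paste0(introns, pieces[-1], collapse = ""))
    contig <- paste0(random_dna(flank), gene_seq, random_dna(flank))
    # CDS segment coordinates on the plus-strand layout (0-based half-open)
    piece_len <- nchar(pieces)
    intr_len <- nchar(introns)
    starts <- flank + c(0L, cumsum(piece_len[-length(piece_len)] +
                                     intr_len))
    segs <- data.frame(start = starts, end = starts + piece_len)
    if (strand == "-") {
      n <- nchar(contig)
      contig <- revcomp(contig)
      segs <- data.frame(start = n - segs$end, end = n - segs$start)
    }
    genome <- stats::setNames(contig, paste0(id, "_contig"))
    model <- gene_model(id = paste0(id, ".m1"), seqid = names(genome),
                        strand = strand, cds_segments = segs,
                        genome_seq = genome[[1]], gene_id = id)
    structure(
      list(id = id, target_codes = target_codes, model = model,
           genome = genome, protein = model$protein,
           expected_call = classify(target_codes, registry)),
      class = "synthetic_gene"
    )
  })
}

#' @export
print.synthetic_gene <- function(x, ...) {
  cat(sprintf("synthetic gene %s: codes {%s}, expected %s\n", x$id,
              paste(x$target_codes, collapse = ", "),
              x$expected_call$group))
  invisible(x)
}

#' Write a synthetic gene (or several) to FASTA + GFF3
#'
#' @param genes a `synthetic_gene` or list of them.
#' @param fasta_path,gff_path output paths.
#' @param labels_path optional TSV of expected labels (id, codes, group,
#'   subgroup).
#' @return invisibly, a data.frame of the labels.
#' @export
write_synthetic <- function(genes, fasta_path, gff_path,
                            labels_path = NULL) {
  if (inherits(genes, "synthetic_gene")) genes <- list(genes)
  genome <- unlist(unname(lapply(genes, `[[`, "genome")))
  labels <- do.call(rbind, lapply(genes, function(g) {
    data.frame(id = g$id, codes = paste(g$target_codes, collapse = ","),
               group = g$expected_call$group,
               subgroup = g$expected_call$subgroup,
               stringsAsFactors = FALSE)
  }))
  attr(genome, "descriptions") <- stats::setNames(
    sprintf("%s expected_group=%s expected_subgroup=%s codes=%s",
            names(genome), labels$group, labels$subgroup, labels$codes),
    names(genome))
  write_fasta(genome, fasta_path)
  write_gene_models(lapply(genes, `[[`, "model"), gff_path)
  if (!is.null(labels_path)) {
    utils::write.table(labels, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(labels)
}

#' Generate a labeled validation panel covering every signature
#'
#' Builds one synthetic gene per positional signature variant — V1a, V1b,
#' V2, each V3 first-intron alternative (86a/88a/90a), V4, V6 — plus V2
#' carrying each registered fish-specific gain (241c; 94a; 215c; 77c with
#' 233c). Strands alternate so both orientations are exercised.
#'
#' @param registry a [load_registry()] bundle.
#' @param seed base seed; gene `i` uses `seed * 1000 + i`.
#' @param mutation_rate scaffold substitution rate applied to every panel
#'   member.
#' @return named list of `synthetic_gene` objects; names are the panel
#'   labels (`"V1a"`, `"V3_88a"`, `"V2_241c"`, ...).
#' @export
generate_panel <- function(registry = load_registry(), seed = 1L,
                           mutation_rate = 0) {
  v1 <- unlist(registry$signatures$V1$required)
  v2 <- unlist(registry$signatures$V2$required)
  v3_rest <- vapply(
    Filter(function(x) length(x) == 1L, registry$signatures$V3$required),
    `[[`, "", 1L)
  panel <- list(
    V1a = c("85c", v1),
    V1b = v1,
    V2 = v2,
    V3_86a = c("86a", v3_rest),
    V3_88a = c("88a", v3_rest),
    V3_90a = c("90a", v3_rest),
    V4 = unlist(registry$signatures$V4$required),
    V6 = unlist(registry$signatures$V6$required),
    V2_241c = c(v2, "241c"),
    V2_94a = c(v2, "94a"),
    V2_215c = c(v2, "215c"),
    V2_77c_233c = c(v2, "77c", "233c")
  )
  out <- vector("list", length(panel))
  names(out) <- names(panel)
  for (i in seq_along(panel)) {
    out[[i]] <- generate_gene(
      panel[[i]], seed = seed * 1000L + i,
      mutation_rate = mutation_rate,
      id = names(panel)[i],
      strand = if (i %% 2L == 0L) "-" else "+",
      registry = registry
    )
  }
  out
}
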