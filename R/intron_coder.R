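#' Convert a CDS offset to a local intron code
#'
#' An intron after `cds_offset` coding nucleotides interrupts codon
#' `N = ceiling(cds_offset / 3)` after its `r = cds_offset - 3(N-1)`-th
#' base; `r` of 1/2/3 maps to letter a/b/c. This is the query-local code,
#' before projection onto the reference frame. Note the complementary GFF3
#' phase of the following segment is `(3 - cds_offset mod 3) mod 3`, i.e.
#' a/b/c correspond to phases 2/1/0.
#'
#' @param cds_offset integer vector of coding-nucleotide counts preceding
#'   each intron (>= 1).
#' @return data.frame with columns `cds_offset`, `codon`, `letter`.
#' @examples
#' offset_to_local_code(c(499, 845, 3))  # 167a, 282b, 1c
#' @export
offset_to_local_code <- function(cds_offset) {
  if (any(cds_offset < 1L)) stop("cds_offset must be >= 1")
  n <- ceiling(cds_offset / 3)
  r <- cds_offset - 3 * (n - 1)
  data.frame(cds_offset = as.integer(cds_offset), codon = as.integer(n),
             letter = c("a", "b", "c")[r])
}

# inverse: coding nucleotides preceding an intron with code (codon, letter)
local_code_to_offset <- function(codon, letter) {
  3L * (as.integer(codon) - 1L) + match(letter, c("a", "b", "c"))
}

#' Code a gene model's introns in the reference frame
#'
#' Each coding intron's offset is converted to its local (codon, letter)
#' code, and the codon is projected through the query-to-reference
#' alignment ([project_residue()]). Codes whose codon projects across a
#' reference gap are flagged approximate and rendered with a `~` suffix
#' ("174a~"); the phase letter is never altered by projection.
#'
#' @param model a [gene_model()].
#' @param alignment a [global_align()] of the model's protein against the
#'   reference frame; its query must equal the model's protein.
#' @return data.frame with columns `cds_offset`, `local_code`,
#'   `projected_code`, `approximate`; one row per coding intron, in gene
#'   order. The `projected_code` column carries the `~` rendering.
#' @examples
#' # a single-exon model yields a zero-row table
#' @export
code_introns <- function(model, alignment) {
  stopifnot(inherits(model, "gene_model"),
            inherits(alignment, "residue_alignment"))
  if (!identical(alignment$query, model$protein)) {
    stop("alignment query does not match the gene model's protein (",
         model$id, ")")
  }
  offs <- model$intron_records$cds_offset
  if (length(offs) == 0L) {
    return(data.frame(cds_offset = integer(0), local_code = character(0),
                      projected_code = character(0),
                      approximate = logical(0)))
  }
  loc <- offset_to_local_code(offs)
  # an intron may sit just past the last complete codon of a partial CDS;
  # clamp to the aligned protein length
  codon <- pmin(loc$codon, nchar(model$protein))
  proj <- project_residue(alignment, codon)
  data.frame(
    cds_offset = loc$cds_offset,
    local_code = format_intron_code(loc$codon, loc$letter),
    projected_code = format_intron_code(proj$ref, loc$letter, !proj$exact),
    approximate = !proj$exact
  )
}

#' Code every model in a collection and tabulate
#'
#' Convenience wrapper: aligns each model's protein to the reference frame
#' and codes its introns, returning one long table suitable for TSV
#' export.
#'
#' @param models list of [gene_model()] objects.
#' @param scoring an [align_scoring()] configuration.
#' @return data.frame with columns `gene_id`, `mrna_id`, `cds_offset`,
#'   `local_code`, `projected_code`, `approximate`.
#' @export
code_models <- function(models, scoring = align_scoring()) {
  rows <- lapply(models, function(m) {
    aln <- global_align(m$protein, scoring = scoring, query_id = m$id)
    tab <- code_introns(m, aln)
    if (nrow(tab) == 0L) return(NULL)
    cbind(gene_id = m$gene_id, mrna_id = m$id, tab,
          stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), mrna_id = character(0),
                      cds_offset = integer(0), local_code = character(0),
                      projected_code = character(0),
                      approximate = logical(0)))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
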