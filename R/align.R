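#' Alignment scoring configuration
#'
#' Defaults follow common practice for within-family protein comparison:
#' BLOSUM62 with affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`). The ambiguity letter `X` is scored 0
#' against everything.
#'
#' @param matrix_name name of a substitution matrix shipped with
#'   Biostrings (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @param gap_open gap opening penalty (positive number).
#' @param gap_extend per-residue gap extension penalty (positive number).
#' @return list with the resolved `matrix` plus the three parameters.
#' @export
align_scoring <- function(matrix_name = "BLOSUM62", gap_open = 10,
                          gap_extend = 1) {
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  mat <- get(matrix_name, envir = e)
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  list(matrix = mat, matrix_name = matrix_name,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Global protein alignment against the reference frame
#'
#' Optimal Needleman-Wunsch global alignment with affine gap penalties,
#' wrapped into a column-wise residue pairing that supports coordinate
#' projection ([project_residue()]) and the indel/RCL diagnostics.
#' Deterministic: equal-scoring paths are resolved by the aligner's fixed
#' internal tie-break.
#'
#' @param query query protein (character string).
#' @param reference reference protein; defaults to the mature human
#'   alpha-1-antitrypsin frame.
#' @param scoring an [align_scoring()] configuration.
#' @param query_id identifier carried into reports.
#' @return object of class `"residue_alignment"`: list with `query_id`,
#'   `columns` (data.frame `q`, `r`; `NA` marks a gap, no column is
#'   gap/gap), `score`, `matrix_name`, `gap_open`, `gap_extend`, and the
#'   two input sequences.
#' @examples
#' aln <- global_align("ACD", "AD")
#' aln$columns
#' @export
global_align <- function(query, reference = reference_frame()$sequence,
                         scoring = align_scoring(), query_id = "query") {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(reference), length(reference) == 1L)
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    stop("cannot align an empty sequence")
  }
  ok <- rownames(scoring$matrix)
  qres <- strsplit(query, "")[[1]]
  rres <- strsplit(reference, "")[[1]]
  if (!all(qres %in% ok) || !all(rres %in% ok)) {
    bad <- setdiff(unique(c(qres, rres)), ok)
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global"
  )
  qg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  rg <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  stopifnot(length(qg) == length(rg))
  q_idx <- ifelse(qg == "-", NA_integer_, cumsum(qg != "-"))
  r_idx <- ifelse(rg == "-", NA_integer_, cumsum(rg != "-"))
  structure(
    list(query_id = query_id,
         columns = data.frame(q = q_idx, r = r_idx),
         score = Biostrings::score(pa),
         matrix_name = scoring$matrix_name,
         matrix = scoring$matrix,
         gap_open = scoring$gap_open, gap_extend = scoring$gap_extend,
         query = query, reference = reference),
    class = "residue_alignment"
  )
}

#' @export
print.residue_alignment <- function(x, ...) {
  cat(sprintf(
    "global alignment %s vs reference: %d columns, score %.1f (%s, gap %g/%g)\n",
    x$query_id, nrow(x$columns), x$score, x$matrix_name,
    x$gap_open, x$gap_extend))
  invisible(x)
}

#' Project a query residue onto the reference frame
#'
#' A query residue paired with a reference residue projects exactly to
#' that residue number. A query residue sitting in a reference gap
#' (an insertion relative to the frame) projects approximately to the
#' nearest preceding reference residue, or 0 if the insertion precedes the
#' whole frame.
#'
#' @param alignment a [global_align()] result.
#' @param query_residue_index integer vector of 1-based query positions.
#' @return data.frame with columns `query`, `ref` and `exact` (logical;
#'   `FALSE` means the projection is approximate).
#' @export
project_residue <- function(alignment, query_residue_index) {
  stopifnot(inherits(alignment, "residue_alignment"))
  cols <- alignment$columns
  nq <- nchar(alignment$query)
  if (any(query_residue_index < 1L | query_residue_index > nq)) {
    stop("query residue index out of range 1..", nq)
  }
  # last reference residue seen at or before each column
  last_ref <- cummax(ifelse(is.na(cols$r), 0L, cols$r))
  col_of_q <- match(query_residue_index, cols$q)
  ref_here <- cols$r[col_of_q]
  exact <- !is.na(ref_here)
  data.frame(
    query = query_residue_index,
    ref = ifelse(exact, ref_here, last_ref[col_of_q]),
    exact = exact
  )
}

#' Percent identity and similarity of an alignment
#'
#' Identity counts identical residue pairs; similarity counts pairs with a
#' strictly positive substitution score. By default the denominator is the
#' full number of alignment columns, gap columns included; set
#' `denominator = "gapfree"` to divide by residue-residue columns only.
#' Both values are rounded to whole percent.
#'
#' @param alignment a [global_align()] result.
#' @param denominator `"all"` (default) or `"gapfree"`.
#' @return named numeric vector `c(identity =, similarity =)`.
#' @export
identity_similarity <- function(alignment,
                                denominator = c("all", "gapfree")) {
  stopifnot(inherits(alignment, "residue_alignment"))
  denominator <- match.arg(denominator)
  cols <- alignment$columns
  qres <- strsplit(alignment$query, "")[[1]]
  rres <- strsplit(alignment$reference, "")[[1]]
  both <- !is.na(cols$q) & !is.na(cols$r)
  qa <- qres[cols$q[both]]
  ra <- rres[cols$r[both]]
  ident <- sum(qa == ra)
  simil <- sum(alignment$matrix[cbind(qa, ra)] > 0)
  den <- if (denominator == "all") nrow(cols) else sum(both)
  c(identity = round(100 * ident / den),
    similarity = round(100 * simil / den))
}

#' Write a pairwise alignment as aligned FASTA
#'
#' @param alignment a [global_align()] result.
#' @param path output path.
#' @param reference_id header for the reference row.
#' @return invisibly, `path`.
#' @export
write_alignment_fasta <- function(alignment, path,
                                  reference_id = "reference") {
  cols <- alignment$columns
  qres <- strsplit(alignment$query, "")[[1]]
  rres <- strsplit(alignment$reference, "")[[1]]
  qrow <- ifelse(is.na(cols$q), "-", qres[cols$q])
  rrow <- ifelse(is.na(cols$r), "-", rres[cols$r])
  seqs <- c(paste(qrow, collapse = ""), paste(rrow, collapse = ""))
  names(seqs) <- c(alignment$query_id, reference_id)
  write_fasta(seqs, path)
}
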