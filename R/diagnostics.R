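#' Detect the diagnostic 173-174 indel
#'
#' Reports the number of query residues inserted strictly between
#' reference residues 173 and 174 of the alpha-1-antitrypsin frame — the
#' two-residue insertion at this site is one of the rare indels that
#' separate the serpin groups. The measurement is projection-based, so it
#' is unaffected by unrelated N-terminal extensions. When either flanking
#' reference residue is deleted in the query, the length is undefined
#' (`NA`) and the indel is reported absent.
#'
#' @param alignment a [global_align()] result against the reference frame.
#' @param diagnostic_length insertion length that counts as the diagnostic
#'   indel (default 2).
#' @return object of class `"indel_report"`: list with `present`,
#'   `length`, `flanks_aligned`.
#' @export
detect_indel_173_174 <- function(alignment, diagnostic_length = 2L) {
  stopifnot(inherits(alignment, "residue_alignment"))
  cols <- alignment$columns
  c173 <- which(!is.na(cols$r) & cols$r == 173L)
  c174 <- which(!is.na(cols$r) & cols$r == 174L)
  if (length(c173) != 1L || length(c174) != 1L) {
    stop("alignment does not cover reference residues 173-174")
  }
  flanks <- !is.na(cols$q[c173]) && !is.na(cols$q[c174])
  if (!flanks) {
    out <- list(present = FALSE, length = NA_integer_,
                flanks_aligned = FALSE)
  } else {
    between <- cols[seq_len(nrow(cols)) > c173 &
                      seq_len(nrow(cols)) < c174, , drop = FALSE]
    len <- sum(is.na(between$r) & !is.na(between$q))
    out <- list(present = len == diagnostic_length,
                length = as.integer(len), flanks_aligned = TRUE)
  }
  structure(out, class = "indel_report")
}

#' @export
print.indel_report <- function(x, ...) {
  cat(sprintf("173-174 indel: %s (length %s, flanks %saligned)\n",
              if (x$present) "present" else "absent",
              format(x$length), if (x$flanks_aligned) "" else "not "))
  invisible(x)
}

#' Annotate the reactive center loop (RCL)
#'
#' Extracts the query residues projected into the RCL window of the
#' reference frame and reads off the P1 and P1' residues of the scissile
#' bond. Defaults use the canonical alpha-1-antitrypsin coordinates:
#' window 342-361 (20 residues, within the 17-20 typical of serpin RCLs)
#' and P1/P1' at reference 358/359 (M358-S359 in the frame itself).
#'
#' @param alignment a [global_align()] result against the reference frame.
#' @param window integer length-2 reference interval (inclusive).
#' @param p1_site reference residue number of P1 (P1' is `p1_site + 1`).
#' @return object of class `"rcl_annotation"`: list with `window`,
#'   `sequence` (query residues across the window, insertions included),
#'   `p1`, `p1_prime` (`NA` if the site is deleted in the query).
#' @export
annotate_rcl <- function(alignment, window = c(342L, 361L),
                         p1_site = 358L) {
  stopifnot(inherits(alignment, "residue_alignment"),
            length(window) == 2L, window[1] < window[2])
  cols <- alignment$columns
  qres <- strsplit(alignment$query, "")[[1]]
  in_win <- which(!is.na(cols$r) & cols$r >= window[1] & cols$r <= window[2])
  if (length(in_win) == 0L) stop("RCL absent")
  span <- seq(min(in_win), max(in_win))
  q_in <- cols$q[span]
  if (all(is.na(q_in))) stop("RCL absent")
  seq_txt <- paste(qres[q_in[!is.na(q_in)]], collapse = "")
  site_q <- function(refpos) {
    i <- which(!is.na(cols$r) & cols$r == refpos)
    if (length(i) != 1L || is.na(cols$q[i])) NA_character_
    else qres[cols$q[i]]
  }
  structure(
    list(window = as.integer(window), sequence = seq_txt,
         p1 = site_q(p1_site), p1_prime = site_q(p1_site + 1L)),
    class = "rcl_annotation"
  )
}

#' @export
print.rcl_annotation <- function(x, ...) {
  cat(sprintf("RCL %d-%d: %s  (P1-P1' = %s-%s)\n", x$window[1],
              x$window[2], x$sequence, x$p1, x$p1_prime))
  invisible(x)
}

#' Parse an RCL string carrying the P1-P1' dash
#'
#' The packaged lamprey table prints each RCL with a dash marking the
#' scissile bond ("GTEAAAATAAIVMMR–CARMG"): P1 is the residue immediately
#' before the dash and P1' the one after. Both the printed en-dash and the
#' ASCII hyphen-minus are accepted; exactly one must be present.
#'
#' @param text_with_dash RCL string with one dash separator.
#' @return list with `p1`, `p1_prime`, `n_before`, `n_after`.
#' @examples
#' parse_rcl_string("GTEAAAATAAIVMMR-CARMG")
#' @export
parse_rcl_string <- function(text_with_dash) {
  stopifnot(is.character(text_with_dash), length(text_with_dash) == 1L)
  norm <- gsub("–", "-", text_with_dash)
  n_dash <- nchar(norm) - nchar(gsub("-", "", norm, fixed = TRUE))
  if (n_dash != 1L) {
    stop("RCL string must contain exactly one dash, found ", n_dash,
         ": ", text_with_dash)
  }
  parts <- strsplit(norm, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
    stop("RCL string must have residues on both sides of the dash: ",
         text_with_dash)
  }
  list(
    p1 = substr(parts[1], nchar(parts[1]), nchar(parts[1])),
    p1_prime = substr(parts[2], 1L, 1L),
    n_before = nchar(parts[1]),
    n_after = nchar(parts[2])
  )
}

#' Scan a protein C-terminus for an ER-retention signal
#'
#' The canonical endoplasmic-reticulum retention/retrieval signal is the
#' C-terminal tetrapeptide class `[KRHQSA]-[DENQ]-E-L` (PROSITE), covering
#' KDEL, HEEL, SDEL and 21 other variants. Tails ending in `EEL` whose
#' fourth-from-last residue falls outside the class — such as the HDFEEL
#' end of tetrapod neuroserpin — are reported as `"eel_variant"`.
#'
#' @param protein protein sequence, length >= 4.
#' @return object of class `"er_motif_report"`: list with `status`
#'   (`"canonical"`, `"eel_variant"` or `"none"`) and `matched_tail`
#'   (last four residues).
#' @examples
#' scan_er_retention("MASSSHEEL")$status   # canonical
#' scan_er_retention("MAHDFEEL")$status    # eel_variant
#' @export
scan_er_retention <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L,
            nchar(protein) >= 4L)
  tail4 <- substr(protein, nchar(protein) - 3L, nchar(protein))
  status <- if (grepl("^[KRHQSA][DENQ]EL$", tail4)) {
    "canonical"
  } else if (endsWith(protein, "EEL")) {
    "eel_variant"
  } else {
    "none"
  }
  structure(list(status = status, matched_tail = tail4),
            class = "er_motif_report")
}

#' @export
print.er_motif_report <- function(x, ...) {
  cat(sprintf("ER-retention signal: %s (tail %s)\n", x$status,
              x$matched_tail))
  invisible(x)
}

#' Run all protein diagnostics over a collection
#'
#' Aligns each protein to the reference frame and reports the 173-174
#' indel, the P1/P1' residues, and the ER-retention status in one table.
#'
#' @param proteins named character vector of protein sequences.
#' @param scoring an [align_scoring()] configuration.
#' @param diagnostic_length passed to [detect_indel_173_174()].
#' @return data.frame with columns `protein_id`, `indel_length`,
#'   `indel_present`, `p1`, `p1_prime`, `er_status`.
#' @export
diagnose_proteins <- function(proteins, scoring = align_scoring(),
                              diagnostic_length = 2L) {
  stopifnot(!is.null(names(proteins)))
  rows <- lapply(names(proteins), function(id) {
    aln <- global_align(proteins[[id]], scoring = scoring, query_id = id)
    ind <- detect_indel_173_174(aln, diagnostic_length)
    rcl <- tryCatch(annotate_rcl(aln), error = function(e) NULL)
    data.frame(
      protein_id = id,
      indel_length = ind$length,
      indel_present = ind$present,
      p1 = if (is.null(rcl)) NA_character_ else rcl$p1,
      p1_prime = if (is.null(rcl)) NA_character_ else rcl$p1_prime,
      er_status = scan_er_retention(proteins[[id]])$status,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
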