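#' Parse intron codes
#'
#' An intron code names an intron position on the mature human
#' alpha-1-antitrypsin reference frame: the 1-based codon (residue) number
#' followed by a phase letter, where `a`, `b`, `c` place the intron after the
#' 1st, 2nd or 3rd base of that codon. A trailing `~` marks an approximate
#' code, i.e. one whose projection onto the reference crossed an alignment
#' gap ("174a~").
#'
#' @param codes character vector of codes such as `"167a"` or `"174a~"`.
#' @return A data.frame with columns `codon` (integer), `letter`
#'   (one of `"a"`, `"b"`, `"c"`) and `approximate` (logical), one row per
#'   input code.
#' @examples
#' parse_intron_code(c("167a", "282b", "174a~"))
#' @export
parse_intron_code <- function(codes) {
  stopifnot(is.character(codes))
  m <- regmatches(codes, regexec("^([0-9]+)([abc])(~?)$", codes))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) {
    stop("malformed intron code(s): ", paste(codes[bad], collapse = ", "))
  }
  codon <- as.integer(vapply(m, `[[`, "", 2L))
  if (any(codon < 1L)) stop("intron code codon must be >= 1")
  data.frame(
    codon = codon,
    letter = vapply(m, `[[`, "", 3L),
    approximate = vapply(m, `[[`, "", 4L) == "~",
    stringsAsFactors = FALSE
  )
}

#' Format intron codes
#'
#' Inverse of [parse_intron_code()]: builds the textual form
#' `<codon><letter>` with a `~` suffix for approximate codes.
#'
#' @param codon integer vector of reference codon numbers (>= 1).
#' @param letter character vector in `c("a","b","c")`.
#' @param approximate logical vector; `TRUE` appends `~`.
#' @return character vector of codes.
#' @examples
#' format_intron_code(c(167L, 174L), c("a", "a"), c(FALSE, TRUE))
#' @export
format_intron_code <- function(codon, letter, approximate = FALSE) {
  stopifnot(all(codon >= 1L), all(letter %in% c("a", "b", "c")))
  n <- max(length(codon), length(letter), length(approximate))
  approximate <- rep_len(approximate, n)
  paste0(codon, letter, ifelse(approximate, "~", ""))
}

# strip the approximate marker, keeping (codon, letter) identity
strip_approx <- function(codes) sub("~$", "", codes)

# validation-free parser for hot paths; returns plain vectors
parse_codes_fast <- function(codes) {
  approx <- endsWith(codes, "~")
  core <- ifelse(approx, substr(codes, 1L, nchar(codes) - 1L), codes)
  n <- nchar(core)
  list(codon = as.integer(substr(core, 1L, n - 1L)),
       letter = substr(core, n, n),
       approximate = approx)
}

# order codes by (codon, letter); used for canonical display
order_codes <- function(codes) {
  p <- parse_intron_code(codes)
  codes[order(p$codon, p$letter)]
}
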