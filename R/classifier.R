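#' Match one observed intron code against a target
#'
#' Letters (phases) must agree exactly; codon numbers may differ by up to
#' `tolerance` residues, widened by 2 when the observed code is
#' approximate (its projection crossed a reference gap). A target given as
#' a vector is an alternative-set and matches if any member matches —
#' used for the group V3 first intron, whose exact site is uncertain
#' between 86a/88a/90a.
#'
#' @param observed single observed code (may carry the `~` suffix).
#' @param target single code or character vector (alternative-set).
#' @param tolerance non-negative integer, in codon units.
#' @return logical scalar.
#' @examples
#' match_code("88a", c("86a", "88a", "90a"), 0)  # TRUE
#' match_code("167c", "167a", 2)                 # FALSE: phase differs
#' @export
match_code <- function(observed, target, tolerance = 0L) {
  stopifnot(length(observed) == 1L, tolerance >= 0)
  o <- parse_intron_code(observed)
  t <- parse_intron_code(target)
  tol <- tolerance + if (o$approximate) 2L else 0L
  any(t$letter == o$letter & abs(t$codon - o$codon) <= tol)
}

# required-element label: "86a|88a|90a" for alternative-sets
req_label <- function(required) {
  vapply(required, paste, "", collapse = "|")
}

score_against_signature <- function(codes, sig, fish_codes, tolerance,
                                    weights) {
  req <- sig$required
  po <- parse_codes_fast(codes)
  tol <- tolerance + 2L * po$approximate
  # per-code hit against one target element (possibly an alternative-set)
  hits_elem <- function(targets) {
    pt <- parse_codes_fast(targets)
    vapply(seq_along(codes), function(i) {
      any(pt$letter == po$letter[i] & abs(pt$codon - po$codon[i]) <= tol[i])
    }, TRUE)
  }
  req_hits <- if (length(req)) {
    vapply(req, hits_elem, logical(length(codes)))
  } else {
    matrix(FALSE, length(codes), 0L)
  }
  if (is.null(dim(req_hits))) req_hits <- matrix(req_hits, nrow = length(codes))
  matched_elem <- colSums(req_hits) > 0L
  hits_req <- rowSums(req_hits) > 0L
  hits_opt <- if (length(sig$optional)) hits_elem(sig$optional)
    else rep(FALSE, length(codes))
  hits_fish <- if (length(fish_codes)) hits_elem(fish_codes)
    else rep(FALSE, length(codes))
  extra <- codes[!(hits_req | hits_opt | hits_fish)]
  n_matched <- sum(matched_elem)
  n_missing <- sum(!matched_elem)
  # a gained intron is reported as fish-specific only when the signature
  # itself does not already account for it (262c is V1-required but an
  # ATIII gain elsewhere)
  unexplained <- (!(hits_req | hits_opt))
  pu <- list(codon = po$codon[unexplained], letter = po$letter[unexplained],
             tol = tol[unexplained])
  pf <- parse_codes_fast(fish_codes)
  fish_hit <- vapply(seq_along(fish_codes), function(j) {
    any(pu$letter == pf$letter[j] & abs(pu$codon - pf$codon[j]) <= pu$tol)
  }, TRUE)
  opt_hit <- if (length(sig$optional)) {
    pq <- parse_codes_fast(sig$optional)
    vapply(seq_along(sig$optional), function(j) {
      any(po$letter == pq$letter[j] & abs(po$codon - pq$codon[j]) <= tol)
    }, TRUE)
  } else logical(0)
  list(
    matched = req_label(req)[matched_elem],
    missing = req_label(req)[!matched_elem],
    extra = extra,
    optional_matched = sig$optional[opt_hit],
    fish_hits = fish_codes[fish_hit],
    n_matched = n_matched,
    score = weights[["matched"]] * n_matched -
      weights[["missing"]] * n_missing -
      weights[["extra"]] * length(extra)
  )
}

#' Classify an intron-code set into groups V1-V6
#'
#' Scores the observed codes against every group signature:
#' `score = matched - 0.5 * missing - 0.25 * extra`, where `matched` and
#' `missing` count required signature positions (an alternative-set counts
#' once), and codes explained by a group's optional positions or by the
#' registered fish-specific gains are neither matched nor extra. The
#' winner is the top-scoring group with at least 2 required positions
#' matched; a tie at the top yields `"ambiguous"` with ranked candidates.
#' When no group reaches the 2-match floor, a set of exactly 6 codes falls
#' through to the count-only V5 (antithrombin III) signature; otherwise
#' the call is `"ambiguous"` if two or more groups tie at the top with at
#' least one match each, and `"unclassified"` if not. A V1 winner is
#' sub-grouped V1a when the optional 85c intron is present, V1b when
#' absent.
#'
#' @param codes character vector of projected intron codes (possibly with
#'   `~` markers); typically `code_introns()$projected_code`.
#' @param registry a [load_registry()] bundle.
#' @param tolerance codon tolerance passed to [match_code()] (default 2).
#' @param weights named numeric vector with elements `matched`, `missing`,
#'   `extra` (positive magnitudes; defaults 1, 0.5, 0.25).
#' @return object of class `"group_call"`: list with `group`, `subgroup`,
#'   `matched`, `missing`, `extra`, `optional_matched`,
#'   `fish_specific_hits` (named by host gene), `score`, `candidates`
#'   (data.frame of all groups with >= 1 match, ranked), `n_codes`, and
#'   `v5_by_count` (logical).
#' @examples
#' reg <- load_registry()
#' classify(c("78c", "128c", "167a", "212c", "262c"), reg)$group  # "V1"
#' @export
classify <- function(codes, registry = load_registry(), tolerance = 2L,
                     weights = c(matched = 1, missing = 0.5, extra = 0.25)) {
  stopifnot(inherits(registry, "serpin_registry"),
            all(c("matched", "missing", "extra") %in% names(weights)))
  codes <- as.character(codes)
  if (length(codes)) parse_intron_code(codes)
  sigs <- registry$signatures
  fish_codes <- registry$fish_specific$code
  res <- lapply(sigs, function(sig) {
    if (length(sig$required) == 0L) return(NULL)  # count-only V5
    score_against_signature(codes, sig, fish_codes, tolerance, weights)
  })
  pos_groups <- names(res)[!vapply(res, is.null, TRUE)]
  scores <- vapply(pos_groups, function(g) res[[g]]$score, 0)
  matched_n <- vapply(pos_groups, function(g) res[[g]]$n_matched, 0)
  cand_groups <- pos_groups[matched_n >= 1L]
  candidates <- data.frame(
    group = cand_groups,
    score = scores[cand_groups],
    n_matched = matched_n[cand_groups],
    row.names = NULL
  )
  candidates <- candidates[order(-candidates$score,
                                 -candidates$n_matched), , drop = FALSE]
  qualified <- pos_groups[matched_n >= 2L]
  call_for <- function(g, group_label = g, v5_by_count = FALSE) {
    r <- res[[g]]
    fish_hits <- r$fish_hits
    names(fish_hits) <- registry$fish_specific$host[
      match(fish_hits, registry$fish_specific$code)]
    sub <- NA_character_
    if (group_label == "V1") {
      sub <- if ("85c" %in% r$optional_matched) "V1a" else "V1b"
    }
    structure(
      list(group = group_label, subgroup = sub, matched = r$matched,
           missing = r$missing, extra = r$extra,
           optional_matched = r$optional_matched,
           fish_specific_hits = fish_hits, score = r$score,
           candidates = candidates, n_codes = length(codes),
           v5_by_count = v5_by_count),
      class = "group_call"
    )
  }
  empty_call <- function(label, v5_by_count = FALSE, score = NA_real_) {
    fish <- registry$fish_specific
    hits <- fish$code[vapply(fish$code, function(t) {
      any(vapply(codes, match_code, TRUE, target = t,
                 tolerance = tolerance))
    }, TRUE)]
    names(hits) <- fish$host[match(hits, fish$code)]
    structure(
      list(group = label, subgroup = NA_character_, matched = character(0),
           missing = character(0), extra = codes,
           optional_matched = character(0), fish_specific_hits = hits,
           score = score, candidates = candidates, n_codes = length(codes),
           v5_by_count = v5_by_count),
      class = "group_call"
    )
  }
  if (length(qualified)) {
    top <- max(scores[qualified])
    winners <- qualified[scores[qualified] == top]
    if (length(winners) > 1L) {
      out <- empty_call("ambiguous", score = top)
      return(out)
    }
    return(call_for(winners))
  }
  # no positional group reaches the floor
  if (is.na(sigs$V5$count) == FALSE && length(sigs$V5$required) == 0L &&
      length(codes) == sigs$V5$count) {
    return(empty_call("V5", v5_by_count = TRUE, score = 0.5))
  }
  if (nrow(candidates) >= 2L &&
      sum(candidates$score == max(candidates$score)) >= 2L) {
    return(empty_call("ambiguous", score = max(candidates$score)))
  }
  empty_call("unclassified")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.group_call <- function(x, ...) {
  cat(sprintf("group call: %s%s (score %s, %d codes)\n", x$group,
              if (!is.na(x$subgroup)) paste0("/", x$subgroup) else "",
              format(x$score), x$n_codes))
  if (length(x$matched)) {
    cat("  matched:", paste(x$matched, collapse = ", "), "\n")
  }
  if (length(x$missing)) {
    cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  }
  if (length(x$extra)) {
    cat("  extra:  ", paste(x$extra, collapse = ", "), "\n")
  }
  if (length(x$fish_specific_hits)) {
    cat("  fish-specific:",
        paste(sprintf("%s (%s)", x$fish_specific_hits,
                      names(x$fish_specific_hits)), collapse = ", "), "\n")
  }
  if (isTRUE(x$v5_by_count)) {
    cat("  NOTE: V5 assigned by intron count alone (no printed positions);\n",
        "  supply v5_positions in load_registry() for a positional call\n")
  }
  invisible(x)
}

#' Classify a collection of gene models
#'
#' Full pipeline per mRNA: align the protein to the reference frame, code
#' the introns, deduplicate repeated codes (recording how many were
#' dropped), classify, and tabulate.
#'
#' @param models list of [gene_model()] objects.
#' @param registry a [load_registry()] bundle.
#' @param scoring an [align_scoring()] configuration.
#' @param tolerance,weights passed to [classify()].
#' @return data.frame with one row per mRNA: `gene_id`, `mrna_id`,
#'   `group`, `subgroup`, `score`, `n_introns`, `n_duplicate_codes`,
#'   comma-joined `codes`, `matched`, `missing`, `extra`,
#'   `fish_specific_hits`, and `v5_by_count`.
#' @export
classify_models <- function(models, registry = load_registry(),
                            scoring = align_scoring(), tolerance = 2L,
                            weights = c(matched = 1, missing = 0.5,
                                        extra = 0.25)) {
  rows <- lapply(models, function(m) {
    aln <- global_align(m$protein, registry$reference$sequence,
                        scoring = scoring, query_id = m$id)
    tab <- code_introns(m, aln)
    codes <- tab$projected_code
    dedup <- unique(strip_approx(codes))
    keep <- codes[match(dedup, strip_approx(codes))]
    call <- classify(keep, registry, tolerance, weights)
    data.frame(
      gene_id = m$gene_id, mrna_id = m$id, group = call$group,
      subgroup = call$subgroup, score = call$score,
      n_introns = length(codes),
      n_duplicate_codes = length(codes) - length(keep),
      codes = paste(keep, collapse = ","),
      matched = paste(call$matched, collapse = ","),
      missing = paste(call$missing, collapse = ","),
      extra = paste(call$extra, collapse = ","),
      fish_specific_hits = paste(call$fish_specific_hits, collapse = ","),
      v5_by_count = call$v5_by_count,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
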