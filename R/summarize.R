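#' Summarize a cohort of group calls
#'
#' @param groups group labels: a character vector, a list of
#'   [classify()] results, or a [classify_models()] report (its `group`
#'   column is used).
#' @return object of class `"cohort_summary"`: list with
#'   `per_group_counts` (named, every observed label), `n_genes`,
#'   `n_groups_present` (labels among V1..V6 with a count >= 1) and
#'   `unclassified`.
#' @examples
#' summarize_calls(lamprey_fixture()$group)
#' @export
summarize_calls <- function(groups) {
  if (is.data.frame(groups)) groups <- groups$group
  if (is.list(groups)) groups <- vapply(groups, `[[`, "", "group")
  groups <- as.character(groups)
  counts <- table(groups)
  per_group <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(
      per_group_counts = per_group,
      n_genes = length(groups),
      n_groups_present = sum(names(per_group) %in%
                               paste0("V", 1:6) & per_group >= 1L),
      unclassified = sum(groups == "unclassified")
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort: %d genes in %d group(s)", x$n_genes,
              x$n_groups_present))
  if (x$unclassified) cat(sprintf(", %d unclassified", x$unclassified))
  cat("\n")
  if (length(x$per_group_counts)) {
    cat(" ", paste(sprintf("%s:%d", names(x$per_group_counts),
                           x$per_group_counts), collapse = "  "), "\n")
  }
  invisible(x)
}

read_newick <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  stopifnot(is.character(tree), length(tree) == 1L)
  if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
}

#' Check group monophyly on a supplied tree
#'
#' Validates the classification against an externally inferred phylogeny:
#' after rooting on the designated outgroup tip, a group is monophyletic
#' iff the smallest clade containing all its tips contains no tips of any
#' other group. Groups with fewer than two tips are vacuously
#' monophyletic and flagged as such. Topology only — support values in
#' the newick are tolerated and ignored.
#'
#' @param tree an `ape` phylo object, a newick string, or a path to a
#'   newick file.
#' @param tip_to_group named character vector mapping tip labels to group
#'   labels; every tip except the outgroup must be mapped.
#' @param outgroup_tip tip label used to root the tree.
#' @return object of class `"concordance_report"`: list with
#'   `per_group_monophyly` (named logical), `vacuous` (named logical),
#'   `n_monophyletic`, `outgroup_tip`.
#' @examples
#' tree_concordance("((a1,a2),(b1,b2),o);",
#'                  c(a1 = "V1", a2 = "V1", b1 = "V2", b2 = "V2"), "o")
#' @export
tree_concordance <- function(tree, tip_to_group, outgroup_tip) {
  phy <- read_newick(tree)
  if (!outgroup_tip %in% phy$tip.label) {
    stop("outgroup tip '", outgroup_tip, "' absent from the tree")
  }
  others <- setdiff(phy$tip.label, outgroup_tip)
  unmapped <- setdiff(others, names(tip_to_group))
  if (length(unmapped)) {
    stop("unmapped tip(s): ", paste(unmapped, collapse = ", "))
  }
  rooted <- ape::root(phy, outgroup = outgroup_tip, resolve.root = TRUE)
  groups <- unique(unname(tip_to_group[others]))
  mono <- vacuous <- stats::setNames(logical(length(groups)), groups)
  for (g in groups) {
    tips <- intersect(others, names(tip_to_group)[tip_to_group == g])
    if (length(tips) < 2L) {
      mono[g] <- TRUE
      vacuous[g] <- TRUE
      next
    }
    mrca <- ape::getMRCA(rooted, tips)
    clade_tips <- ape::extract.clade(rooted, mrca)$tip.label
    foreign <- names(tip_to_group)[tip_to_group != g]
    mono[g] <- !any(clade_tips %in% foreign)
  }
  structure(
    list(per_group_monophyly = mono, vacuous = vacuous,
         n_monophyletic = sum(mono), outgroup_tip = outgroup_tip),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("tree concordance (outgroup %s): %d/%d groups monophyletic\n",
              x$outgroup_tip, x$n_monophyletic,
              length(x$per_group_monophyly)))
  for (g in names(x$per_group_monophyly)) {
    cat(sprintf("  %s: %s%s\n", g,
                if (x$per_group_monophyly[g]) "monophyletic" else "NOT monophyletic",
                if (x$vacuous[g]) " (single tip; vacuous)" else ""))
  }
  invisible(x)
}

#' Write a cohort summary or concordance report as TSV
#'
#' @param x a `cohort_summary` or `concordance_report`.
#' @param path output path.
#' @return invisibly, the data.frame written.
#' @export
write_summary_tsv <- function(x, path) {
  df <- if (inherits(x, "cohort_summary")) {
    data.frame(group = names(x$per_group_counts),
               count = unname(x$per_group_counts),
               stringsAsFactors = FALSE)
  } else if (inherits(x, "concordance_report")) {
    data.frame(group = names(x$per_group_monophyly),
               monophyletic = unname(x$per_group_monophyly),
               vacuous = unname(x$vacuous), stringsAsFactors = FALSE)
  } else {
    stop("unsupported object")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
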