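# Independent oracles and small generators used across the suite.

# Brute-force affine-gap global alignment score, written as a memoized
# three-state recursion independent of the package's aligner. Cost model:
# a gap of length L costs open + L * ext; terminal gaps are penalized.
bf_align_score <- function(q, r, mat, open = 10, ext = 1) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  n <- length(qs); m <- length(rs)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, mat[qs[i], rs[j]] + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= n) {  # q residue against a gap in the reference row
      cost <- if (prev == "rg") ext else open + ext
      best <- max(best, -cost + rec(i + 1L, j, "rg"))
    }
    if (j <= m) {  # r residue against a gap in the query row
      cost <- if (prev == "qg") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1L, "qg"))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "m")
}

# All-clades monophyly oracle: enumerate every clade's tip set by a
# manual postorder over the rooted tree's edge matrix, find the smallest
# clade containing all of a group's tips, and check it for foreign tips.
bf_monophyletic <- function(rooted, tips, foreign) {
  ntip <- length(rooted$tip.label)
  nodes <- ntip + seq_len(rooted$Nnode)
  kids <- split(rooted$edge[, 2], rooted$edge[, 1])
  tipset <- function(node) {
    if (node <= ntip) return(rooted$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tipset))
  }
  clades <- lapply(nodes, tipset)
  containing <- Filter(function(cl) all(tips %in% cl), clades)
  sizes <- vapply(containing, length, 0L)
  smallest <- containing[[which.min(sizes)]]
  !any(smallest %in% foreign)
}

aa_letters <- function() setdiff(unique(Biostrings::GENETIC_CODE), "*")

random_protein <- function(n) {
  paste(sample(aa_letters(), n, replace = TRUE), collapse = "")
}

# a random strictly increasing, realizable intron-code set
random_code_set <- function(n_codes = NULL, max_codon = 394L) {
  if (is.null(n_codes)) n_codes <- sample(1:8, 1)
  codons <- sort(sample(2:(max_codon - 1L), n_codes))
  letters_ <- sample(c("a", "b", "c"), n_codes, replace = TRUE)
  format_intron_code(codons, letters_)
}

# expected P1/P1' pairs for the packaged lamprey RCL strings
lamprey_p1_pairs <- function() {
  data.frame(
    p1 = c("R", "R", "M", "I", "L", "M", "T", "M"),
    p1_prime = c("C", "C", "C", "S", "T", "S", "N", "R"),
    stringsAsFactors = FALSE
  )
}
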