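# Mature human alpha-1-antitrypsin (UniProt P01009, residues 25-418; 394 aa).
# 1-based mature numbering defines every intron code and all diagnostic
# coordinates (P1/P1' = M358/S359).
A1AT_MATURE <- paste0(
  "EDPQGDAAQKTDTSHHDQDHPTFNKITPNLAEFAFSLYRQLAHQSNSTNI",
  "FFSPVSIATAFAMLSLGTKADTHDEILEGLNFNLTEIPEAQIHEGFQELL",
  "RTLNQPDSQLQLTTGNGLFLSEGLKLVDKFLEDVKKLYHSEAFTVNFGDT",
  "EEAKKQINDYVEKGTQGKIVDLVKELDRDTVFALVNYIFFKGKWERPFEV",
  "KDTEEEDFHVDQVTTVKVPMMKRLGMFNIQHCKKLSSWVLLMKYLGNATA",
  "IFFLPDEGKLQHLENELTHDIITKFLENEDRRSASLHLPKLSITGTYDLK",
  "SVLGQLGITKVFSNGADLSGVTEEAPLKLSKAVHKAVLTIDEKGTEAAGA",
  "MFLEAIPMSIPPEVKFNKPFVFLMIEQNTKSPLFMGKVVNPTQK"
)

#' The reference frame for intron-position mapping
#'
#' Returns the mature human alpha-1-antitrypsin protein sequence together
#' with its name. All intron codes ("167a", "282b", ...) and diagnostic
#' coordinates (the 173-174 indel, the RCL window, P1/P1') are expressed in
#' this sequence's 1-based residue numbering.
#'
#' @return list with elements `name` and `sequence` (single string, 394
#'   residues).
#' @examples
#' rf <- reference_frame()
#' nchar(rf$sequence)  # 394
#' substr(rf$sequence, 358, 359)  # "MS": the P1-P1' scissile bond
#' @export
reference_frame <- function() {
  list(name = "A1AT_HSA_mature", sequence = A1AT_MATURE)
}

# Group signatures. `required` is a list whose elements are character
# vectors; a length > 1 element is an alternative-set (any member matching
# counts as that one required position matched). V5 has no printed
# positions: only an intron count, overridable via load_registry().
.SIGNATURES <- list(
  V1 = list(
    group = "V1",
    required = list("78c", "128c", "167a", "212c", "262c"),
    optional = c("85c"),
    count = NA_integer_,
    indel_173_174 = NA,
    notes = paste(
      "ov-serpins (clade B), mostly intracellular; optional 85c defines",
      "sub-group V1a (present) vs V1b (absent); human clusters at 6p25",
      "and 18q21"
    )
  ),
  V2 = list(
    group = "V2",
    required = list("192a", "282b", "331c"),
    optional = character(0),
    count = NA_integer_,
    indel_173_174 = NA,
    notes = paste(
      "alpha-1-antitrypsin-like serpins, angiotensinogen (clade A),",
      "heparin cofactor II (clade D); most members also carry a UTR",
      "intron (not coded); fish-specific gains 241c (HCII), 77c+233c",
      "(AGT), and the fish-only genes Spn_94a / Spn_215c"
    )
  ),
  V3 = list(
    group = "V3",
    required = list(c("86a", "88a", "90a"),
                    "167a", "230a", "290b", "323a", "352a", "380a"),
    optional = character(0),
    count = NA_integer_,
    indel_173_174 = NA,
    notes = paste(
      "clades E and I (PAI1, GDN, SERPINE3, neuroserpin, pancpin); the",
      "exact site of the first intron is uncertain between 86a/88a/90a",
      "owing to alignment ambiguity; neuroserpin-like members carry",
      "C-terminal ER-retention signals (HEEL/KDEL/SDEL; tetrapod",
      "neuroserpin ends HDFEEL)"
    )
  ),
  V4 = list(
    group = "V4",
    required = list("67a", "123a", "192a", "238c", "307a"),
    optional = character(0),
    count = NA_integer_,
    indel_173_174 = NA,
    notes = paste(
      "PEDF, alpha-2-antiplasmin (clade F) and C1 inhibitor (clade G);",
      "fish C1IN carries two N-terminal Ig-like domains with a",
      "fish-specific intron in the Ig region (domain-level note, never",
      "projected onto the serpin frame)"
    )
  ),
  V5 = list(
    group = "V5",
    required = list(),
    optional = character(0),
    count = 6L,
    indel_173_174 = NA,
    notes = paste(
      "antithrombin III (ATIII/SERPINC1) only; seven exons / six",
      "introns; positions unspecified-in-text (shown only graphically),",
      "so the signature is count-only unless positions are supplied;",
      "262c lost in tetrapods/coelacanth and regained in ray-finned",
      "fishes"
    )
  ),
  V6 = list(
    group = "V6",
    required = list("192a", "225a", "300c"),
    optional = character(0),
    count = NA_integer_,
    indel_173_174 = NA,
    notes = "HSP47/SERPINH1 (clade H); fishes carry 1-3 paralogs"
  )
)

.FISH_SPECIFIC <- data.frame(
  code = c("94a", "215c", "241c", "77c", "233c", "262c"),
  host = c("Spn_94a (ZPI/SERPINA10 paralog)", "Spn_215c",
           "HCII/SERPIND1", "AGT/SERPINA8", "AGT/SERPINA8",
           "ATIII/SERPINC1"),
  group = c("V2", "V2", "V2", "V2", "V2", "V5"),
  stringsAsFactors = FALSE
)

.LOCUS_NOTES <- list(
  list(locus = "6p25", members = c("SERPINB1", "SERPINB6", "SERPINB9"),
       remark = "first human group V1 cluster (as-printed)"),
  list(locus = "18q21",
       members = c("SERPINB2", "SERPINB3", "SERPINB4", "SERPINB5",
                   "SERPINB7", "SERPINB8", "SERPINB10", "SERPINB11",
                   "SERPINB12", "SERPINB13"),
       remark = "second human group V1 cluster (as-printed)"),
  list(locus = "1q23-q25", members = "SERPINC1",
       remark = "antithrombin III locus (as-printed)"),
  list(locus = "22q11 (PIK4CA intron)", members = "SERPIND1",
       remark = paste("HCII nested within the largest PIK4CA intron for",
                      "~500 MY; the lamprey A2APL1 group V4 gene shares",
                      "this nest")),
  list(locus = "chromosome 3", members = "SERPINE1",
       remark = "PAI1 (as-printed)"),
  list(locus = "chromosome 2", members = "SERPINE2",
       remark = "GDN (as-printed)"),
  list(locus = "chromosome 13", members = "SERPINE3",
       remark = "as-printed")
)

#' Load the serpin classification registry
#'
#' Bundles everything the classifier and diagnostics need: the reference
#' frame, the six group signatures (required / optional intron codes,
#' alternative-sets, the count-only V5 entry), the six fish-specific
#' intron gains with their host genes, human locus notes, and the packaged
#' lamprey serpin table.
#'
#' @param v5_positions optional character vector of intron codes to use as
#'   the V5 required signature (the printed text gives only a count of 6;
#'   supplying positions turns V5 into a positional signature like the
#'   others).
#' @param indel_173_174 optional named logical vector (names in V1..V6)
#'   recording which groups carry the two-residue 173-174 indel; default
#'   `NA` for every group (the published status is graphical only).
#' @return list of class `"serpin_registry"` with elements `reference`,
#'   `signatures` (named list V1..V6), `fish_specific` (data.frame
#'   code/host/group), `locus_notes`, and `lamprey` (the fixture of
#'   [lamprey_fixture()]).
#' @examples
#' reg <- load_registry()
#' reg$signatures$V4$required
#' @export
load_registry <- function(v5_positions = NULL, indel_173_174 = NULL) {
  sigs <- .SIGNATURES
  if (!is.null(v5_positions)) {
    parse_intron_code(v5_positions)  # validate
    sigs$V5$required <- as.list(v5_positions)
    sigs$V5$count <- length(v5_positions)
  }
  if (!is.null(indel_173_174)) {
    stopifnot(is.logical(indel_173_174), !is.null(names(indel_173_174)),
              all(names(indel_173_174) %in% names(sigs)))
    for (g in names(indel_173_174)) {
      sigs[[g]]$indel_173_174 <- indel_173_174[[g]]
    }
  }
  for (g in names(sigs)) {
    req <- unlist(sigs[[g]]$required)
    if (length(req)) parse_intron_code(req)
    if (length(intersect(req, sigs[[g]]$optional))) {
      stop("registry corrupt: code in both required and optional of ", g)
    }
  }
  need <- c("V1", "V2", "V3", "V4", "V6")
  if (!all(vapply(sigs[need], function(s) length(s$required) > 0, TRUE))) {
    stop("registry corrupt: empty required set in a positional group")
  }
  structure(
    list(
      reference = reference_frame(),
      signatures = sigs,
      fish_specific = .FISH_SPECIFIC,
      locus_notes = .LOCUS_NOTES,
      lamprey = lamprey_fixture()
    ),
    class = "serpin_registry"
  )
}

#' @export
print.serpin_registry <- function(x, ...) {
  cat("serpin classification registry\n")
  cat("  reference:", x$reference$name,
      sprintf("(%d aa)\n", nchar(x$reference$sequence)))
  for (s in x$signatures) {
    req <- vapply(s$required, paste, "", collapse = "|")
    cat(sprintf("  %s: required {%s}%s%s\n", s$group,
                paste(req, collapse = ", "),
                if (length(s$optional))
                  paste0(" optional {", paste(s$optional, collapse = ", "), "}")
                else "",
                if (!is.na(s$count)) paste0(" [count ", s$count, "]") else ""))
  }
  cat("  fish-specific gains:", paste(x$fish_specific$code, collapse = ", "),
      "\n")
  invisible(x)
}

#' Lamprey serpin fixture
#'
#' The eight sea-lamprey (*Petromyzon marinus*) serpins with their
#' accessions, group and clade assignments, RCL strings carrying the
#' P1-P1' dash, and river-lamprey ortholog ids, as packaged reference
#' data. The RCL strings use the en-dash separator as printed;
#' [parse_rcl_string()] accepts both en-dash and hyphen-minus.
#'
#' @return data.frame with columns `given_name`, `accession`,
#'   `serpin_name`, `group`, `clade`, `rcl_with_dash`, `ortholog_ids`
#'   (8 rows).
#' @examples
#' lam <- lamprey_fixture()
#' table(lam$group)
#' @export
lamprey_fixture <- function() {
  data.frame(
    given_name = c(
      "Pma-Spn-1", "MNE1L_PMA/Pma-Spn-2", "SPB6_PMA (Pma-Spn-3)",
      "A1ATL_PMA (Pma-Spn-4)", "A1ATL_PMA (Pma-Spn-5)",
      "A2APL1_PMA (Pma-Spn-6)", "A2APL2_PMA (Pma-Spn-7)",
      "HSP47_PMA (Pma-Spn-8)"
    ),
    accession = c(
      "ENSPMAG00000001963", "ENSPMAG00000009027", "ENSPMAG00000009040",
      "ENSPMAG00000006108", "ENSPMAG00000008131", "ENSPMAG00000008124",
      "ENSPMAG00000002992", "ENSPMAG00000007485"
    ),
    serpin_name = c(
      "SERPINB1-like", "MNEI1-like/SERPINB1-like", "SPB6/SERPINB6-like",
      "A1AT-like, angiotensinogen, SERPINA8",
      "Heparin cofactor II/SERPIND1", "Alpha-2-antiplasmin-like 1",
      "Alpha-2-antiplasmin-like 2, A2APL2_PMA", "HSP47/SERPINH1"
    ),
    group = c("V1", "V1", "V1", "V2", "V2", "V4", "V4", "V6"),
    clade = c("B", "B", "B", "A", "D", "F", "F", "H"),
    rcl_with_dash = c(
      "GTEAAAATAAIVMMR–CARMG", "GTEAAAATAVTMKLR–CAMPT",
      "GTEAAAATAISVMLM–CAMPT", "GTEAKAETVVGIMPI–SMPPT",
      "GSEAAAVTTVGFTPL–TSHNR", "GVKATAATGIMISLM–SVQHS",
      "GAEAAAVTGVFLSRT–NPIYP", "GEEYDMSVHGHPDM–RNPHL"
    ),
    ortholog_ids = c(
      "", "", "", "CAV16871.1/CAV29466.1", "CAX18777.1/AIA57696.1",
      "CAX18777.1/CAX18778.1", "AIE16052.1/AIE16053.1", ""
    ),
    stringsAsFactors = FALSE
  )
}

#' Look up a lamprey record by (partial) name
#'
#' Matches `name` as a fixed substring of `given_name`, so the short form
#' "Pma-Spn-4" retrieves "A1ATL_PMA (Pma-Spn-4)".
#'
#' @param name substring of the printed given name.
#' @return one-row data.frame (errors if the match is not unique).
#' @export
lamprey_record <- function(name) {
  lam <- lamprey_fixture()
  hit <- grepl(name, lam$given_name, fixed = TRUE)
  if (sum(hit) != 1L) {
    stop("name '", name, "' matches ", sum(hit), " lamprey records")
  }
  lam[hit, , drop = FALSE]
}

#' Export the registry as TSV
#'
#' Writes one row per group with the required codes (alternative-sets
#' joined by `|`), optional codes and the fish-specific codes attributed
#' to that group, all comma-joined; and, separately, the lamprey table
#' with its seven printed columns.
#'
#' @param registry a [load_registry()] bundle.
#' @param groups_path path for the per-group TSV.
#' @param lamprey_path optional path for the lamprey fixture TSV.
#' @return invisibly, the per-group data.frame.
#' @export
export_registry_tsv <- function(registry, groups_path, lamprey_path = NULL) {
  stopifnot(inherits(registry, "serpin_registry"))
  rows <- lapply(registry$signatures, function(s) {
    fish <- registry$fish_specific$code[registry$fish_specific$group == s$group]
    data.frame(
      group = s$group,
      required = paste(vapply(s$required, paste, "", collapse = "|"),
                       collapse = ","),
      optional = paste(s$optional, collapse = ","),
      fish_specific = paste(fish, collapse = ","),
      intron_count = if (is.na(s$count)) length(s$required) else s$count,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(lamprey_path)) {
    utils::write.table(registry$lamprey, lamprey_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
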