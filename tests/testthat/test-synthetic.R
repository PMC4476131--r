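test_that("generation is deterministic per seed, byte-identical on disk", {
  g1 <- generate_gene(c("192a", "282b", "331c"), seed = 101)
  g2 <- generate_gene(c("192a", "282b", "331c"), seed = 101)
  expect_identical(g1$genome, g2$genome)
  f1 <- tempfile(); f2 <- tempfile(); gf1 <- tempfile(); gf2 <- tempfile()
  write_synthetic(g1, f1, gf1)
  write_synthetic(g2, f2, gf2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(gf1), readLines(gf2))
  g3 <- generate_gene(c("192a", "282b", "331c"), seed = 102)
  expect_false(identical(g1$genome, g3$genome))
})

test_that("generator inverts the coding scheme at hand-checked offsets", {
  g <- generate_gene(c("192a", "282b", "331c"), seed = 103)
  expect_identical(g$model$intron_records$cds_offset, c(574L, 845L, 993L))
  tab <- code_introns(g$model, global_align(g$model$protein))
  expect_identical(tab$projected_code, c("192a", "282b", "331c"))
})

test_that("an empty code set yields a single-exon gene", {
  g <- generate_gene(character(0), seed = 104)
  expect_identical(nrow(g$model$cds_segments), 1L)
  expect_identical(nrow(g$model$intron_records), 0L)
})

test_that("unrealizable or malformed code requests error", {
  expect_error(generate_gene("395a", seed = 1), "beyond scaffold")
  expect_error(generate_gene(c("10a", "10a"), seed = 1), "duplicate")
  expect_error(generate_gene("174a~", seed = 1), "approximate")
})

test_that("synthetic introns carry GT/AG termini and consistent phases", {
  set.seed(105)
  for (i in 1:5) {
    codes <- random_code_set()
    g <- generate_gene(codes, seed = 200 + i,
                       strand = if (i %% 2) "+" else "-")
    m <- g$model
    contig <- g$genome[[1]]
    for (j in seq_len(nrow(m$intron_records))) {
      s <- m$intron_records$genomic_start[j]
      e <- m$intron_records$genomic_end[j]
      intron <- substr(contig, s + 1L, e)
      if (m$strand == "-") {
        intron <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(intron)))
      }
      expect_identical(substr(intron, 1, 2), "GT")
      expect_identical(substr(intron, nchar(intron) - 1, nchar(intron)),
                       "AG")
      expect_gte(nchar(intron), 120L)
      expect_lte(nchar(intron), 300L)
    }
  }
})

test_that("zero-mutation round trip recovers every code exactly", {
  reg <- load_registry()
  set.seed(106)
  for (i in 1:10) {
    codes <- random_code_set()
    g <- generate_gene(codes, seed = 300 + i)
    fa <- tempfile(fileext = ".fa")
    gff <- tempfile(fileext = ".gff3")
    write_synthetic(g, fa, gff)
    m <- read_gff3(gff, read_fasta(fa))[[1]]
    tab <- code_introns(m, global_align(m$protein))
    expect_identical(tab$projected_code, g$target_codes)
    expect_false(any(tab$approximate))
  }
})

test_that("the labeled panel covers all signatures and classifies 100%", {
  reg <- load_registry()
  panel <- generate_panel(reg, seed = 107)
  expect_setequal(
    names(panel),
    c("V1a", "V1b", "V2", "V3_86a", "V3_88a", "V3_90a", "V4", "V6",
      "V2_241c", "V2_94a", "V2_215c", "V2_77c_233c"))
  rep <- classify_models(lapply(panel, `[[`, "model"), reg)
  expected_group <- vapply(panel, function(g) g$expected_call$group, "")
  expect_identical(rep$group, unname(expected_group))
  expect_identical(rep$subgroup[rep$gene_id == "V1a"], "V1a")
  expect_identical(rep$subgroup[rep$gene_id == "V1b"], "V1b")
  expect_identical(rep$group[startsWith(rep$gene_id, "V3_")],
                   rep("V3", 3L))
  expect_identical(rep$fish_specific_hits[rep$gene_id == "V2_241c"],
                   "241c")
  expect_identical(rep$fish_specific_hits[rep$gene_id == "V2_77c_233c"],
                   "77c,233c")
})

test_that("labels are embedded in panel FASTA headers", {
  panel <- generate_panel(seed = 108)
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  labels_tsv <- tempfile(fileext = ".tsv")
  labels <- write_synthetic(panel, fa, gff, labels_tsv)
  heads <- grep("^>", readLines(fa), value = TRUE)
  expect_length(heads, 12L)
  expect_true(all(grepl("expected_group=", heads)))
  back <- read.delim(labels_tsv)
  expect_identical(nrow(back), 12L)
  # the written pair re-reads as a coherent panel: contig names in the
  # GFF3 resolve against the FASTA and classification matches the labels
  models <- read_gff3(gff, read_fasta(fa))
  expect_length(models, 12L)
  rep <- classify_models(models)
  expect_setequal(rep$gene_id, back$id)
  expect_identical(rep$group[match(back$id, rep$gene_id)], back$group)
})

test_that("a mutated scaffold still classifies correctly at tolerance 2", {
  reg <- load_registry()
  v1 <- unlist(reg$signatures$V1$required)
  v2 <- unlist(reg$signatures$V2$required)
  v3_rest <- vapply(Filter(function(x) length(x) == 1L,
                           reg$signatures$V3$required), `[[`, "", 1L)
  variants <- list(
    V1a = c("85c", v1), V1b = v1, V2 = v2,
    V3_86a = c("86a", v3_rest), V3_88a = c("88a", v3_rest),
    V3_90a = c("90a", v3_rest),
    V4 = unlist(reg$signatures$V4$required),
    V6 = unlist(reg$signatures$V6$required),
    V2_241c = c(v2, "241c"), V2_94a = c(v2, "94a"),
    V2_215c = c(v2, "215c"), V2_77c_233c = c(v2, "77c", "233c"))
  # one rotating signature variant per seed covers every variant
  # several times across the 50 seeds
  for (seed in 1:50) {
    pick <- (seed - 1L) %% length(variants) + 1L
    g <- generate_gene(variants[[pick]], seed = 400L + seed,
                       mutation_rate = 0.1,
                       id = names(variants)[pick],
                       strand = if (seed %% 2L) "+" else "-",
                       registry = reg)
    rep <- classify_models(list(g$model), reg, tolerance = 2L)
    expect_identical(rep$group, g$expected_call$group,
                     info = paste("seed", seed, g$id))
  }
})
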