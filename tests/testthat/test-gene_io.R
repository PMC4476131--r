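make_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

test_that("read_fasta preserves order, uppercases, and keeps descriptions", {
  f <- make_fasta(c(">s2 second record", "acGTacgt", ">s1 first", "TTTT"))
  seqs <- read_fasta(f)
  expect_identical(names(seqs), c("s2", "s1"))
  expect_identical(unname(seqs[["s2"]]), "ACGTACGT")
  expect_identical(unname(attr(seqs, "descriptions")[["s2"]]),
                   "s2 second record")
  empty <- make_fasta(character(0))
  expect_length(read_fasta(empty), 0L)
  bad <- make_fasta(c("ACGT", ">s1", "ACGT"))
  expect_error(read_fasta(bad), "line 1")
})

test_that("translate_cds follows the standard code and flags deviations", {
  expect_identical(as.character(translate_cds("ATGGAA")), "ME")
  expect_identical(as.character(translate_cds("atggaa")), "ME")
  p <- translate_cds("ATGTAA")
  expect_identical(as.character(p), "M")
  expect_false(attr(p, "internal_stop"))
  p2 <- translate_cds("ATGTAAGAA")
  expect_true(attr(p2, "internal_stop"))
  p3 <- translate_cds("ATGGAAG")
  expect_true(attr(p3, "partial_codon"))
  expect_identical(as.character(p3), "ME")
  expect_error(translate_cds("AT"), "shorter")
})

two_exon_gene <- function(strand) {
  # 300 nt CDS segment, 200 nt intron, 300 nt CDS segment inside 1 kb
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  contig <- paste(sample(bases, 1000, TRUE), collapse = "")
  segs <- data.frame(start = c(100L, 600L), end = c(400L, 900L))
  if (strand == "-") {
    contig_rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(contig)))
    segs <- data.frame(start = 1000L - rev(segs$end),
                       end = 1000L - rev(segs$start))
    contig <- contig_rc
  }
  gff <- tempfile(fileext = ".gff3")
  lines <- c(
    "##gff-version 3",
    sprintf("chr1\tt\tgene\t%d\t%d\t.\t%s\t.\tID=g1", segs$start[1] + 1,
            segs$end[2], strand),
    sprintf("chr1\tt\tmRNA\t%d\t%d\t.\t%s\t.\tID=m1;Parent=g1",
            segs$start[1] + 1, segs$end[2], strand),
    sprintf("chr1\tt\tCDS\t%d\t%d\t.\t%s\t0\tID=c1;Parent=m1",
            segs$start[1] + 1, segs$end[1], strand),
    sprintf("chr1\tt\tCDS\t%d\t%d\t.\t%s\t0\tID=c2;Parent=m1",
            segs$start[2] + 1, segs$end[2], strand)
  )
  writeLines(lines, gff)
  list(gff = gff, genome = c(chr1 = contig))
}

test_that("read_gff3 derives intron offsets on both strands identically", {
  plus <- two_exon_gene("+")
  mp <- read_gff3(plus$gff, plus$genome)[["m1"]]
  expect_identical(mp$intron_records$cds_offset, 300L)
  expect_identical(nchar(mp$spliced_cds), 600L)
  minus <- two_exon_gene("-")
  mm <- read_gff3(minus$gff, minus$genome)[["m1"]]
  expect_identical(mm$intron_records$cds_offset, 300L)
  # the mirrored construction carries the same transcript
  expect_identical(mm$spliced_cds, mp$spliced_cds)
})

test_that("read_gff3 error/warning paths behave", {
  plus <- two_exon_gene("+")
  expect_error(read_gff3(plus$gff, c(other = "ACGT")), "absent")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t10\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t1\t10\t.\t+\t.\tID=m1;Parent=g1"), gff)
  expect_warning(models <- read_gff3(gff, c(chr1 = "ACGTACGTAC")),
                 "no CDS")
  expect_length(models, 0L)
})

test_that("single-exon models have no intron records", {
  g <- generate_gene(character(0), seed = 5)
  expect_identical(nrow(g$model$intron_records), 0L)
  expect_identical(nrow(g$model$cds_segments), 1L)
})

test_that("GFF3 round trip reproduces cds offsets exactly", {
  for (seed in 1:5) {
    codes <- with(list(), {
      set.seed(seed + 100)
      random_code_set()
    })
    g <- generate_gene(codes, seed = seed,
                       strand = if (seed %% 2) "+" else "-")
    fa <- tempfile(fileext = ".fa")
    gff <- tempfile(fileext = ".gff3")
    write_synthetic(g, fa, gff)
    back <- read_gff3(gff, read_fasta(fa))[[g$model$id]]
    expect_identical(back$intron_records$cds_offset,
                     g$model$intron_records$cds_offset)
    expect_identical(back$protein, g$protein)
    expect_identical(back$strand, g$model$strand)
  }
})

test_that("strand mirror of the same transcript yields identical intron records", {
  codes <- c("78c", "128c", "167a", "212c", "262c")
  gp <- generate_gene(codes, seed = 7, strand = "+")
  gm <- generate_gene(codes, seed = 7, strand = "-")
  expect_identical(gp$model$intron_records$cds_offset,
                   gm$model$intron_records$cds_offset)
  expect_identical(gp$model$spliced_cds, gm$model$spliced_cds)
})

test_that("UTR-only introns are counted, never coded", {
  gff <- tempfile(fileext = ".gff3")
  # exon1 is pure 5' UTR; CDS spans exons 2-3
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t520\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t520\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tt\texon\t1\t50\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\tt\texon\t101\t250\t.\t+\t.\tID=e2;Parent=m1",
    "chr1\tt\texon\t301\t520\t.\t+\t.\tID=e3;Parent=m1",
    "chr1\tt\tCDS\t101\t250\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\tt\tCDS\t301\t451\t.\t+\t0\tID=c2;Parent=m1"
  ), gff)
  set.seed(9)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 520, TRUE),
                           collapse = ""))
  m <- read_gff3(gff, genome)[["m1"]]
  expect_identical(nrow(m$intron_records), 1L)
  expect_identical(m$n_utr_introns, 1L)
})
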