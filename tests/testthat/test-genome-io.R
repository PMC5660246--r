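# GenBank parsing, coordinate conventions, extraction, round trips.

test_that("GenBank coordinates convert as a bijection", {
  for (s1 in c(1L, 7L, 15300L)) for (e1 in c(s1, s1 + 52L)) {
    iv <- mitocomp:::gb_to_internal(s1, e1)
    back <- mitocomp:::internal_to_gb(iv)
    expect_identical(unname(back[1, 1]), s1)
    expect_identical(unname(back[1, 2]), e1)
    expect_equal(unname(iv[1, 2] - iv[1, 1]), e1 - s1 + 1L)
  }
})

test_that("location strings parse including complement and origin-wrapping join", {
  p <- mitocomp:::parse_location("join(15300..15352,1..50)")
  expect_identical(p$strand, "J")
  expect_equal(nrow(p$intervals), 2L)
  expect_equal(sum(p$intervals[, 2] - p$intervals[, 1]), 103)
  p2 <- mitocomp:::parse_location("complement(42..108)")
  expect_identical(p2$strand, "N")
  expect_equal(unname(p2$intervals[1, ]), c(41L, 108L))
})

test_that("a hand-written record parses with canonical names and wrap feature", {
  gb <- c(
    "LOCUS       TEST01 120 bp    DNA     circular INV 01-JAN-2000",
    "DEFINITION  Toyus exampleus mitochondrion.",
    "ACCESSION   TEST01",
    "SOURCE      Toyus exampleus",
    "  ORGANISM  Toyus exampleus",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             complement(10..45)",
    "                     /gene=\"ND1\"",
    "     tRNA            46..80",
    "                     /product=\"tRNA-Trp\"",
    "     rRNA            join(100..120,1..9)",
    "                     /product=\"16S ribosomal RNA\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//")
  f <- tempfile(fileext = ".gb")
  writeLines(gb, f)
  g <- read_genbank(f)
  expect_identical(g$accession, "TEST01")
  expect_identical(g$taxon, "Toyus exampleus")
  expect_true(g$is_circular)
  expect_equal(nchar(g$sequence), 120)
  tab <- feature_table(g)
  expect_setequal(tab$gene, c("nad1", "trnW", "rrnL"))
  expect_identical(tab$strand[tab$gene == "nad1"], "N")
  rr <- mitocomp:::get_feature(g, "rrnL")
  expect_equal(nrow(rr$intervals), 2L)
  expect_equal(rr$length, 30L)
  expect_equal(nchar(extract_region(g, rr)), 30L)
})

test_that("synonym canonicalization covers common spellings and anticodons", {
  expect_identical(canonical_gene_name("COI"), "cox1")
  expect_identical(canonical_gene_name("ND4L"), "nad4l")
  expect_identical(canonical_gene_name("16S ribosomal RNA"), "rrnL")
  expect_identical(canonical_gene_name("tRNA-Leu (UUR)"), "trnL2")
  expect_identical(canonical_gene_name("tRNA-Leu", anticodon = "tag"), "trnL1")
  expect_identical(canonical_gene_name("tRNA-Ser", anticodon = "tga"), "trnS2")
  expect_true(is.na(canonical_gene_name("mystery ORF")))
})

test_that("write then re-read is the identity on all model fields", {
  g <- generate_genome(genome_spec(seed = 21))$genome
  f <- tempfile(fileext = ".gb")
  write_genbank(g, f)
  g2 <- read_genbank(f)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$accession, g$accession)
  expect_identical(g2$taxon, g$taxon)
  expect_identical(g2$is_circular, g$is_circular)
  t1 <- feature_table(g); t2 <- feature_table(g2)
  cols <- c("gene", "class", "strand", "start", "end", "length", "wraps")
  expect_identical(t2[, cols], t1[, cols])
})

test_that("duplicate canonical genes and empty sequences are hard errors", {
  f1 <- gene_feature("cox1", "J", cbind(0L, 30L))
  f2 <- gene_feature("cox1", "J", cbind(40L, 70L))
  expect_error(mito_genome(strrep("ACGT", 30), list(f1, f2)), "cox1")
  expect_error(mito_genome("", list()), "empty")
})

test_that("extract_region honours strand and wrap order, length always matches", {
  g <- mito_genome("ACGTT", list(gene_feature("trnA", "J", cbind(0L, 4L))))
  expect_identical(extract_region(g, "trnA"), "ACGT")
  gn <- mito_genome("ACGTT", list(gene_feature("trnA", "N", cbind(0L, 4L))))
  expect_identical(extract_region(gn, "trnA"), "ACGT")   # palindrome
  syn <- generate_genome(genome_spec(seed = 22))$genome
  for (f in syn$features)
    expect_equal(nchar(extract_region(syn, f)), f$length)
})

test_that("alignment reader accepts FASTA and relaxed PHYLIP, rejects ragged input", {
  aln <- random_pcg_alignment(5, 40, gene_name = "cox1", seed = 3)
  fa <- tempfile(fileext = ".fasta"); ph <- tempfile(fileext = ".phy")
  write_alignment(aln, fa, "fasta")
  write_alignment(aln, ph, "phylip")
  a1 <- read_alignment(fa, "cox1", "PCG")
  a2 <- read_alignment(ph, "cox1", "PCG")
  expect_identical(a1$seqs, aln$seqs)
  expect_identical(a2$seqs, aln$seqs)
  expect_equal(a1$column_count, 120)
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTACG"), bad)
  expect_error(read_alignment(bad, "x", "rRNA"), "ragged")
  expect_error(mito_alignment(c(a = strrep("A", 10), b = strrep("A", 10)),
                              "x", "PCG"), "divisible")
})
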