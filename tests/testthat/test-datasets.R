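# Supermatrix construction, codon subsetting, translation, partition export.

test_that("concatenation records charsets and slicing inverts it", {
  a <- random_pcg_alignment(4, 100, gene_name = "cox1", seed = 71)
  b <- random_pcg_alignment(4, 200, gene_name = "nad2", seed = 72)
  sm <- concatenate_alignments(list(a, b))
  expect_equal(sm$column_count, 900)
  expect_equal(sm$charsets$start, c(1, 301))
  expect_equal(sm$charsets$end, c(300, 900))
  expect_identical(slice_charset(sm, "cox1")$seqs, a$seqs)
  expect_identical(slice_charset(sm, "nad2")$seqs, b$seqs)
  # missing taxa are gap-filled with a warning
  b2 <- b; b2$seqs <- b2$seqs[-1]; b2$taxa <- b2$taxa[-1]
  expect_warning(sm2 <- concatenate_alignments(list(a, b2)), "gaps")
  expect_equal(substr(sm2$seqs[["t1"]], 301, 900), strrep("-", 600))
})

test_that("codon subsetting keeps gene-local positions", {
  # toy gene: rows of codons ATG AAA TTT; position 3 gives G A T
  aln <- mito_alignment(c(t1 = "ATGAAATTT", t2 = "ATGAAATTT"), "toy", "PCG")
  sm <- concatenate_alignments(list(aln))
  p3 <- codon_subset(sm, 3)
  expect_identical(unname(p3$seqs[["t1"]]), "GAT")
  expect_identical(codon_subset(sm, c(1, 2, 3))$seqs, sm$seqs)
  rr <- random_rrna_alignment(2, 30, seed = 73)
  smr <- concatenate_alignments(list(rr))
  expect_error(codon_subset(smr, 1:2), "PCG")
})

test_that("translation follows the invertebrate mitochondrial code", {
  aln <- mito_alignment(c(t1 = "ATGAGAAGG", t2 = "---AGANNN"), "toy", "PCG")
  aa <- translate_matrix(concatenate_alignments(list(aln)))
  expect_identical(unname(aa$seqs[["t1"]]), "MSS")  # AGA/AGG are Ser, not Arg
  expect_identical(unname(aa$seqs[["t2"]]), "-SX")
  bad <- mito_alignment(c(t1 = "ATGTAAAAA"), "toy", "PCG")
  expect_error(translate_matrix(concatenate_alignments(list(bad))),
               "stop codon at codon 2")
})

test_that("the five datasets satisfy the column bookkeeping identities", {
  set.seed(74)
  lens <- c(170, 220, 300, 145, 90, 260, 65, 330, 410, 75, 120, 280, 236)
  pcgs <- lapply(seq_along(lens), function(i)
    random_pcg_alignment(6, lens[i], gene_name = paste0("g", i), seed = 740 + i))
  rrnas <- list(random_rrna_alignment(6, 1100, "rrnL", seed = 75),
                random_rrna_alignment(6, 700, "rrnS", seed = 76))
  ds <- build_five_datasets(pcgs, rrnas)
  n123 <- ds$P123$column_count
  expect_equal(n123, 3 * sum(lens))
  expect_equal(ds$P12$column_count, (2 / 3) * n123)
  expect_equal(ds$AA$column_count, n123 / 3)
  expect_equal(ds$P123R$column_count - n123,
               ds$P12R$column_count - ds$P12$column_count)
  expect_identical(ds$AA$alphabet, "amino-acid")
  # empty rRNA input: P123R equals P123
  ds0 <- build_five_datasets(pcgs)
  expect_identical(ds0$P123R$seqs, ds0$P123$seqs)
})

test_that("supermatrix writers round-trip and emit partition schemes", {
  pcgs <- lapply(1:2, function(i)
    random_pcg_alignment(4, 50, gene_name = paste0("g", i), seed = 770 + i))
  sm <- concatenate_alignments(pcgs)
  fa <- tempfile(fileext = ".fasta")
  write_supermatrix(sm, fa, "fasta", partitions = "gene_codon")
  back <- read_alignment(fa, "all", "PCG")
  expect_identical(back$seqs, sm$seqs)
  parts <- readLines(paste0(fa, ".partitions"))
  expect_length(parts, 6)                       # 2 genes x 3 positions
  expect_true(any(grepl("g1_pos1 = 1-150\\\\3", parts)))
  nx <- tempfile(fileext = ".nex")
  write_supermatrix(sm, nx, "nexus", partitions = "gene")
  txt <- readLines(nx)
  expect_true(any(grepl("^#NEXUS", txt)))
  expect_true(any(grepl("CHARSET g2 = 151-300;", txt)))
  expect_true(any(grepl("CHARPARTITION", txt)))
})

test_that("gap/stop column stripping removes exactly the flagged codons", {
  aln <- mito_alignment(c(t1 = "ATGTAAAAA---", t2 = "ATGCCCAAA---"), "g", "PCG")
  clean <- strip_gap_stop_columns(aln)
  expect_equal(clean$column_count, 6)           # stop codon + all-gap codon dropped
  expect_identical(unname(clean$seqs[["t1"]]), "ATGAAA")
})
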