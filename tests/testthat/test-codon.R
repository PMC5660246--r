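# Codon extraction, usage, RSCU and start/stop classification under the
# invertebrate mitochondrial code.

test_that("the genetic code is transl_table 5", {
  code <- inv_mito_code()
  expect_identical(unname(code[c("ATA", "AGA", "AGG", "TGA")]),
                   c("M", "S", "S", "W"))
  expect_identical(sort(names(code)[code == "*"]), c("TAA", "TAG"))
  expect_equal(sum(code != "*"), 62)
})

test_that("codon extraction counts in frame, stops and tails handled", {
  g <- mito_genome(
    paste0("ATGAAATAA", strrep("C", 6)),
    list(gene_feature("nad3", "J", cbind(0L, 9L))))
  cu <- codon_usage(g)
  expect_equal(unname(cu$counts[c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(cu$total_codons, 2)
  expect_equal(unname(cu$stop_counts[["TAA"]]), 1L)
  # length-10 CDS ending in T: trailing base is an incomplete stop, not a codon
  g2 <- mito_genome(
    paste0("ATGAAACCCT", strrep("G", 5)),
    list(gene_feature("nad3", "J", cbind(0L, 10L))))
  cu2 <- codon_usage(g2)
  expect_equal(cu2$total_codons, 3)
  expect_equal(sum(cu2$stop_counts), 0L)
  # drop_first_codon removes each gene's start triplet
  expect_equal(codon_usage(g2, drop_first_codon = TRUE)$total_codons, 2)
})

test_that("codon totals are invariant to strand and feature order", {
  spec <- genome_spec(seed = 41)
  g <- generate_genome(spec)$genome
  cu <- codon_usage(g)
  # same genome re-read from disk (feature list rebuilt in sorted order)
  f <- tempfile(fileext = ".gb"); write_genbank(g, f)
  cu2 <- codon_usage(read_genbank(f))
  expect_identical(cu$counts, cu2$counts)
  expect_identical(unname(cu$counts[c("TAA", "TAG")]), c(0L, 0L))  # stops excluded
})

test_that("RSCU matches per-family hand arithmetic", {
  base <- generate_genome(genome_spec(seed = 42))$genome
  usage <- codon_usage(base)
  # overwrite with a hand-built table: 4-fold family (4,0,0,0); 2-fold (3,1)
  usage$counts[] <- 0L
  usage$counts[c("GGA", "GGC", "GGG", "GGT")] <- c(4L, 0L, 0L, 0L)  # Gly
  usage$counts[c("TGC", "TGT")] <- c(3L, 1L)                        # Cys
  usage$total_codons <- 8L
  r <- rscu(usage)
  expect_equal(unname(r$values[c("GGA", "GGC", "GGG", "GGT")]), c(4, 0, 0, 0))
  expect_equal(unname(r$values[c("TGC", "TGT")]), c(1.5, 0.5))
  # equal counts give RSCU 1 everywhere in the family
  usage$counts[c("GGA", "GGC", "GGG", "GGT")] <- 5L
  expect_equal(unname(rscu(usage)$values[c("GGA", "GGC", "GGG", "GGT")]),
               rep(1, 4))
})

test_that("RSCU family sums equal family sizes on random usage tables", {
  set.seed(17)
  base <- generate_genome(genome_spec(seed = 43))$genome
  usage <- codon_usage(base)
  for (rep_ in 1:20) {
    usage$counts[] <- stats::rpois(64, lambda = sample(c(0.5, 3, 20), 1))
    code <- inv_mito_code()
    usage$counts[code[names(usage$counts)] == "*"] <- 0L
    usage$total_codons <- sum(usage$counts)
    if (usage$total_codons == 0) next
    r <- rscu(usage)
    sums <- tapply(r$values, r$amino_acid[names(r$values)], sum)
    sizes <- r$family_sizes[names(sums)]
    nonzero <- !(names(sums) %in% r$zero_families)
    expect_equal(as.numeric(sums[nonzero]), as.numeric(sizes[nonzero]),
                 tolerance = 1e-12)
    expect_true(all(sums[!nonzero] == 0))
    expect_true(all(r$values[r$counts == 0] == 0))
  }
})

test_that("start/stop report classifies planted codons including incomplete stops", {
  g <- generate_genome(genome_spec(seed = 44))$genome
  ssr <- start_stop_report(g)
  expect_identical(ssr$start_codon[ssr$gene == "nad5"], "TTG")
  expect_identical(ssr$stop_codon[ssr$gene == "nad5"], "TAG")
  expect_identical(ssr$stop_class[ssr$gene == "cox2"], "incomplete")
  expect_identical(ssr$stop_codon[ssr$gene == "cox2"], "T")
  expect_identical(ssr$stop_class[ssr$gene == "nad1"], "incomplete")
  others <- !(ssr$gene %in% c("nad5", "cox2", "nad1"))
  expect_true(all(ssr$start_class[others] == "ATN"))
  expect_true(all(ssr$stop_codon[others] == "TAA"))
  s <- attr(ssr, "summary")
  expect_equal(unname(s["incomplete"]), 2L)
  # incomplete iff CDS length mod 3 in {1,2}
  ft <- feature_table(g)
  for (i in seq_len(nrow(ssr))) {
    len <- ft$length[ft$gene == ssr$gene[i]]
    expect_identical(ssr$stop_class[i] == "incomplete", len %% 3L != 0L)
  }
})
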