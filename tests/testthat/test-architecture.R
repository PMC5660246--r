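# Gene order, breakpoints, junctions, control region, tandem repeats.

wcy_permuted_order <- function() {
  ord <- ancestral_gene_order()$entries
  i <- match(c("trnW", "trnC", "trnY"), ord$gene)
  ord[i, ] <- ord[match(c("trnY", "trnW", "trnC"), ord$gene), ]
  ord
}

test_that("gene order extraction anchors, rotates and preserves strands", {
  g <- generate_genome(genome_spec(seed = 51))$genome
  go <- gene_order(g)
  ref <- ancestral_gene_order()
  expect_identical(go$entries, ref$entries)
  # re-anchoring is a rotation; anchoring twice returns the original
  go2 <- gene_order(gene_order(go, anchor = "cox1"), anchor = "trnI")
  expect_identical(go2$entries, go$entries)
  expect_error(gene_order(g, anchor = "nope"), "available genes")
})

test_that("identical orders give zero breakpoints; W/C/Y shuffle gives three", {
  ref <- ancestral_gene_order()
  expect_equal(compare_orders(ref, ref)$breakpoint_count, 0)
  g <- generate_genome(genome_spec(gene_order = wcy_permuted_order(),
                                   seed = 52))$genome
  rr <- compare_orders(gene_order(g), ref)
  expect_equal(rr$breakpoint_count, 3)
  expect_equal(length(rr$differing_blocks), 1L)
  expect_true(all(c("trnY", "trnW", "trnC") %in% rr$differing_blocks[[1]]$observed))
  # the only surviving cluster adjacency is trnW-trnC
  sh <- rr$shared_adjacencies
  expect_true(any(sh$gene_a == "trnW" & sh$gene_b == "trnC"))
  expect_false(any(sh$gene_a == "nad2" & sh$gene_b == "trnY"))
  # symmetry
  expect_equal(compare_orders(ref, gene_order(g))$breakpoint_count, 3)
})

test_that("breakpoint counts equal the brute-force adjacency oracle", {
  set.seed(23)
  genes <- canonical_genes()
  for (i in 1:40) {
    n <- sample(6:37, 1)
    gs <- sample(genes, n)
    st1 <- sample(c("J", "N"), n, replace = TRUE)
    perm <- sample(n)
    o1 <- mitocomp:::new_gene_order(gs, st1, anchor = gs[1])
    o2 <- mitocomp:::new_gene_order(gs[perm], st1[perm], anchor = gs[perm][1])
    got <- compare_orders(o1, o2)$breakpoint_count
    want <- oracle_breakpoints(o1$entries$gene, o1$entries$strand,
                               o2$entries$gene, o2$entries$strand)
    expect_equal(got, want)
    expect_lte(got, n)
    # invariant under rotation of either order
    o2r <- gene_order(o2, anchor = o2$entries$gene[3])
    expect_equal(compare_orders(o1, o2r)$breakpoint_count, got)
  }
})

test_that("junction walk classifies overlaps and spacers with exact lengths", {
  feats <- list(gene_feature("trnA", "J", cbind(0L, 10L)),
                gene_feature("trnR", "J", cbind(7L, 20L)),
                gene_feature("trnN", "J", cbind(25L, 35L)))
  g <- mito_genome(strrep("ACGT", 10), feats)
  jr <- junctions(g)
  expect_equal(jr$overlaps$length, 3)            # (0,10) vs (7,20)
  expect_identical(jr$overlaps$gene_a, "trnA")
  expect_equal(sort(jr$spacers$length), c(5, 5)) # 20..25 and wrap 35..40
  g2 <- generate_genome(genome_spec(seed = 53))$genome
  jr2 <- junctions(g2)
  ov <- jr2$overlaps
  expect_equal(ov$length[ov$gene_a == "atp8" & ov$gene_b == "atp6"], 7)
  expect_equal(ov$length[ov$gene_a == "nad4" & ov$gene_b == "nad4l"], 7)
  expect_equal(ov$length[ov$gene_a == "trnW" & ov$gene_b == "trnC"], 8)
  expect_equal(unname(jr2$totals["overlap_bp"]), 22)
  expect_equal(jr2$cr$length, 908)
})

test_that("architecture bookkeeping conserves genome length on synthetic genomes", {
  for (seed in c(54, 55)) {
    g <- generate_genome(genome_spec(seed = seed))$genome
    jr <- junctions(g)
    ft <- feature_table(g)
    gene_bp <- sum(ft$length[ft$class != "CR"])
    total <- gene_bp - unname(jr$totals["overlap_bp"]) +
      unname(jr$totals["spacer_bp"]) + jr$cr$length
    expect_equal(total, nchar(g$sequence))
  }
})

test_that("control region located between rrnS and trnI, annotation preferred", {
  g <- generate_genome(genome_spec(seed = 56))$genome
  cr_ann <- locate_control_region(g)            # annotated CR present
  expect_identical(cr_ann$flags, "")
  expect_equal(cr_ann$length, 908L)
  # strip the annotation: inference must find the same span
  g2 <- g
  g2$features <- Filter(function(f) f$class != "CR", g2$features)
  cr_inf <- locate_control_region(g2)
  expect_identical(cr_inf$flags, "inferred")
  expect_equal(cr_inf$length, 908L)
  expect_equal(cr_inf$intervals, cr_ann$intervals, ignore_attr = TRUE)
  # a 500 bp planted CR is recovered at 500
  g3 <- generate_genome(genome_spec(
    cr_spec = list(length = 500L, period = 100L, copies = 2.5, noise = 0),
    seed = 57))$genome
  g3$features <- Filter(function(f) f$class != "CR", g3$features)
  expect_equal(locate_control_region(g3)$length, 500L)
  # missing anchors are an error
  g4 <- g2
  g4$features <- Filter(function(f) f$gene != "rrnS", g4$features)
  expect_error(locate_control_region(g4), "rrnS")
})

test_that("pure tandem repeats are found with exact period and copies", {
  tr <- find_tandem_repeats("ACGTACGTACGT", min_period = 4)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$period, 4)
  expect_equal(tr$copies, 3.0)
  expect_equal(tr$identity, 1.0)
  expect_equal(tr$start, 0)
  # too short a region: empty
  expect_equal(nrow(find_tandem_repeats("ACGTACG", min_period = 10)), 0L)
})

test_that("a planted 239 bp repeat with a partial copy is recovered from the CR", {
  g <- generate_genome(genome_spec(seed = 58))$genome
  cr <- extract_region(g, locate_control_region(g))
  tr <- find_tandem_repeats(cr)
  expect_true(239 %in% tr$period)
  hit <- tr[tr$period == 239, ][1, ]
  expect_equal(hit$copies, 657 / 239, tolerance = 0.05)
  expect_gt(hit$identity, 0.95)
})

test_that("random sequence yields no repeats in at least 95% of seeded trials", {
  hits <- 0L
  for (s in 1:60) {
    set.seed(1000 + s)
    r <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    if (nrow(find_tandem_repeats(r)) > 0) hits <- hits + 1L
  }
  expect_lte(hits, 3L)
})
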