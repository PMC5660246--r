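# p-distance, GTR distance, saturation regression, NG86 Ka.

test_that("p-distance uses pairwise deletion", {
  expect_equal(as.numeric(p_distance("ACGT", "ACGT")), 0)
  expect_equal(as.numeric(p_distance("ACGT", "ACGA")), 0.25)
  d <- p_distance("AC-T", "ACGT")
  expect_equal(as.numeric(d), 0)
  expect_equal(attr(d, "n_sites"), 3)
  expect_true(is.na(p_distance("----", "ACGT")))
  expect_error(p_distance("ACG", "ACGT"), "lengths")
})

test_that("GTR distance is zero for identical sequences and NA at saturation", {
  s <- strrep("ACGT", 100)
  expect_equal(as.numeric(gtr_distance(s, s)), 0, tolerance = 1e-12)
  # p = 3/4 with uniform composition: the JC saturation limit, undefined
  a <- strrep("ACGT", 25)
  b <- strrep("CGTA", 25)   # every site differs, uniform
  expect_true(is.na(gtr_distance(a, b)))
})

test_that("GTR equals the JC closed form on an exactly JC-symmetric pair", {
  # 25 of each match pair, 4 of each ordered mismatch pair: uniform marginals
  bases <- c("A", "C", "G", "T")
  a <- c(rep(bases, each = 25),
         rep(bases, each = 12))
  b <- c(rep(bases, each = 25),
         as.vector(vapply(bases, function(x) rep(setdiff(bases, x), 4), character(12))))
  p <- as.numeric(p_distance(a, b))
  expect_equal(as.numeric(gtr_distance(a, b)),
               -0.75 * log(1 - 4 * p / 3), tolerance = 1e-6)
})

test_that("simulated JC pairs recover the true branch length", {
  m <- gtr_model(t = 0.3, seed = 61)
  pr <- evolve_pair(10000, m)
  p_exp <- 0.75 * (1 - exp(-4 * 0.3 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(as.numeric(p_distance(pr$ancestor, pr$descendant)) - p_exp), 3 * se)
  g <- as.numeric(gtr_distance(pr$ancestor, pr$descendant))
  # delta-method SE of the JC estimate at p_exp
  se_d <- se / (1 - 4 * p_exp / 3)
  expect_lt(abs(g - 0.3), 3 * se_d)
})

test_that("the correction inequality gtr >= p holds on simulated pairs", {
  set.seed(62)
  for (i in 1:60) {
    m <- gtr_model(exp(runif(6, -1, 1)), {x <- rgamma(4, 5); x / sum(x)},
                   t = runif(1, 0.02, 0.6), seed = 6000 + i)
    pr <- evolve_pair(400, m, seed = 6000 + i)
    g <- as.numeric(gtr_distance(pr$ancestor, pr$descendant))
    if (is.na(g)) next
    expect_gte(g, as.numeric(p_distance(pr$ancestor, pr$descendant)) - 1e-12)
  }
})

test_that("saturation regression finds slope 1 at small distances and ranks pos3 lowest", {
  m_small <- gtr_model(t = 0.02, seed = 63)
  aln <- evolve_star(8, 3000, m_small)
  sat <- saturation_analysis(list(aln))
  expect_true(all(sat$slope > 0.9 & sat$slope < 1.1))
  m_fast3 <- gtr_model(t = 0.15, site_rate_classes = c(1, 1, 5), seed = 64)
  aln3 <- evolve_star(8, 3000, m_fast3)
  sat3 <- saturation_analysis(list(aln3))
  s <- stats::setNames(sat3$slope, sat3$position_class)
  expect_lt(s[["pos3"]], s[["pos1"]])
  expect_lt(s[["pos3"]], s[["pos2"]])
  # rRNA pooling adds a class; excluded saturated pairs are counted
  rr <- evolve_star(8, 900, gtr_model(t = 0.05, seed = 65),
                    feature_class = "rRNA")
  sat4 <- saturation_analysis(list(aln3), list(rr))
  expect_setequal(sat4$position_class, c("pos1", "pos2", "pos3", "rRNA"))
  expect_true(all(sat4$n_pairs_used + sat4$n_pairs_excluded == choose(8, 2)))
})

test_that("NG86 sites and pathway counts match the exhaustive oracle", {
  code <- inv_mito_code()
  sense <- names(code)[code != "*"]
  # all sense codons: site fractions
  for (cd in sense) {
    expect_equal(mitocomp:::ng86_sites(cd, code), oracle_ng86_sites(cd),
                 tolerance = 1e-12)
  }
  # all codon pairs with <= 2 differences: pathway-averaged counts
  set.seed(66)
  diffs <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  pairs <- expand.grid(a = sense, b = sense, stringsAsFactors = FALSE)
  pairs <- pairs[mapply(diffs, pairs$a, pairs$b) <= 2 & pairs$a != pairs$b, ]
  for (i in seq_len(nrow(pairs))) {
    got <- mitocomp:::ng86_diffs(pairs$a[i], pairs$b[i], code)
    want <- oracle_ng86_diffs(pairs$a[i], pairs$b[i])
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("Ka is zero for identical or synonymous-only pairs and symmetric", {
  expect_equal(ka_ng86("ATGAAATTT", "ATGAAATTT")$ka, 0)
  # one synonymous third-position change only: Nd = 0, ka = 0
  r <- ka_ng86("ATGAAATTT", "ATGAAATTC")   # TTT->TTC both Phe
  expect_equal(r$nd, 0)
  expect_equal(r$ka, 0)
  expect_gt(r$sd, 0)
  # toy two-step codon difference equals the hand-enumerated pathway average
  o <- oracle_ng86_diffs("TTA", "CTC")
  r2 <- ka_ng86("ATGTTA", "ATGCTC")
  expect_equal(r2$nd, unname(o["nd"]), tolerance = 1e-12)
  expect_equal(r2$sd, unname(o["sd"]), tolerance = 1e-12)
  # symmetry on simulated coding pairs
  cp <- evolve_pair(300, gtr_model(t = 0.25, seed = 67), mode = "codon")
  k1 <- ka_ng86(cp$ancestor, cp$descendant)
  k2 <- ka_ng86(cp$descendant, cp$ancestor)
  expect_equal(k1$ka, k2$ka, tolerance = 1e-12)
  expect_equal(k1$sites_n + k1$sites_s, 3 * k1$codons_compared)
  expect_gte(k1$ka, k1$pn)   # JC correction only inflates
})

test_that("whole-genome Ka helper pairs genes by name and needs equal lengths", {
  a <- generate_genome(genome_spec(seed = 68))$genome
  b <- generate_genome(genome_spec(seed = 69))$genome
  pc <- pair_pcg_concat(a, b)
  expect_equal(length(pc$genes), 13)
  expect_equal(nchar(pc$focal), nchar(pc$reference))
  k <- ka_ng86(pc$focal, pc$reference, a$accession, b$accession)
  expect_true(is.finite(k$ka) && k$ka > 0)
  # unequal gene lengths demand pre-aligned input
  gl <- mitocomp:::default_gene_lengths(); gl["cox1"] <- gl["cox1"] + 9
  c_ <- generate_genome(genome_spec(gene_lengths = gl, seed = 70))$genome
  expect_error(pair_pcg_concat(a, c_), "codon-aligned")
})
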