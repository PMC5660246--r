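# Independent oracles used to cross-check the package's implementations.
# These deliberately share no code with the package internals.

ORACLE_CODE <- Biostrings::getGeneticCode("5")

# NG86 site counts by direct enumeration (stop-target mutations excluded from
# the per-position denominator)
oracle_ng86_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  ch <- unlist(strsplit(codon, ""))
  aa0 <- ORACLE_CODE[[codon]]
  syn <- 0
  for (pos in 1:3) {
    nsyn <- 0; nvalid <- 0
    for (b in bases[bases != ch[pos]]) {
      mut <- ch; mut[pos] <- b
      aa <- ORACLE_CODE[[paste(mut, collapse = "")]]
      if (aa == "*") next
      nvalid <- nvalid + 1
      if (aa == aa0) nsyn <- nsyn + 1
    }
    if (nvalid > 0) syn <- syn + nsyn / nvalid
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# NG86 pathway differences by exhaustive enumeration of step orderings
oracle_ng86_diffs <- function(c1, c2) {
  ch1 <- unlist(strsplit(c1, "")); ch2 <- unlist(strsplit(c2, ""))
  pos <- which(ch1 != ch2)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  orderings <- if (length(pos) == 1) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
      out
    }
    perms(pos)
  }
  walk <- function(ordering, allow_stop) {
    cur <- ch1; sd <- 0; nd <- 0
    for (p in ordering) {
      from <- ORACLE_CODE[[paste(cur, collapse = "")]]
      cur[p] <- ch2[p]
      to <- ORACLE_CODE[[paste(cur, collapse = "")]]
      if (to == "*" && !allow_stop) return(NULL)
      if (from == to) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  counted <- Filter(Negate(is.null), lapply(orderings, walk, allow_stop = FALSE))
  if (!length(counted)) counted <- lapply(orderings, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, counted))
}

# brute-force signed circular breakpoint count: adjacencies of `obs` absent
# from `ref`; each adjacency is stored in both reading directions
oracle_breakpoints <- function(obs_genes, obs_strands, ref_genes, ref_strands) {
  adj_set <- function(genes, strands) {
    n <- length(genes)
    sg <- paste0(ifelse(strands == "J", "+", "-"), genes)
    flip <- function(x) ifelse(startsWith(x, "+"), sub("^\\+", "-", x),
                               sub("^-", "+", x))
    keys <- character(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      keys <- c(keys, paste(sg[i], sg[j]), paste(flip(sg[j]), flip(sg[i])))
    }
    unique(keys)
  }
  oa <- adj_set(obs_genes, obs_strands)
  ra <- adj_set(ref_genes, ref_strands)
  # each adjacency contributes two keys; count adjacencies, not keys
  sum(!(oa %in% ra)) / 2
}

# random alignment of stop-free codons (for dataset/translation tests)
random_pcg_alignment <- function(n_taxa, n_codons, gene_name = "g",
                                 seed = 1) {
  set.seed(seed)
  sense <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  seqs <- vapply(seq_len(n_taxa), function(i)
    paste(sample(sense, n_codons, replace = TRUE), collapse = ""), "")
  mito_alignment(stats::setNames(seqs, paste0("t", seq_len(n_taxa))),
                 gene_name = gene_name, feature_class = "PCG")
}

random_rrna_alignment <- function(n_taxa, n_cols, gene_name = "r", seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_taxa), function(i)
    paste(sample(c("A", "C", "G", "T"), n_cols, replace = TRUE), collapse = ""), "")
  mito_alignment(stats::setNames(seqs, paste0("t", seq_len(n_taxa))),
                 gene_name = gene_name, feature_class = "rRNA")
}
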