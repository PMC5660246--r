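# Pairwise distances, substitution-saturation regression, and Nei-Gojobori
# nonsynonymous divergence.

# comparable positions: both sequences have an unambiguous base
.comparable <- function(a, b) a %in% .BASES & b %in% .BASES

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among pairwise-complete sites (columns with
#' a gap or N in either sequence are excluded).
#'
#' @param a,b equal-length gapped sequences (character scalars or vectors of
#'   single characters).
#' @return numeric; `NA` (flagged undefined) when no sites are comparable.
#'   Attribute `n_sites` carries the number of compared sites.
#' @export
p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- s2c(toupper(a))
  if (is.character(b) && length(b) == 1L) b <- s2c(toupper(b))
  if (length(a) != length(b)) stop("sequences have different lengths")
  ok <- .comparable(a, b)
  n <- sum(ok)
  out <- if (n == 0L) NA_real_ else sum(a[ok] != b[ok]) / n
  attr(out, "n_sites") <- n
  out
}

#' Closed-form GTR distance between two aligned sequences
#'
#' The general time-reversible distance from the divergence matrix: with F the
#' symmetrized 4x4 matrix of site-pattern proportions over comparable columns
#' and Pi the diagonal of its marginal base frequencies, the distance is
#' `-tr(Pi log(Pi^-1 F))`. The matrix logarithm is taken by eigendecomposition
#' of the symmetric form `Pi^-1/2 F Pi^-1/2`; any eigenvalue at or below the
#' positivity tolerance marks a saturated pair and the distance is undefined
#' (`NA`, never an exception). Reduces to the Jukes-Cantor closed form
#' `-(3/4) log(1 - (4/3) p)` when F is exactly JC-symmetric with uniform
#' frequencies.
#'
#' @param a,b equal-length gapped sequences.
#' @param tol eigenvalue positivity tolerance.
#' @return substitutions/site (numeric), or `NA` when undefined; attribute
#'   `n_sites` as in [p_distance()].
#' @export
gtr_distance <- function(a, b, tol = 1e-12) {
  if (is.character(a) && length(a) == 1L) a <- s2c(toupper(a))
  if (is.character(b) && length(b) == 1L) b <- s2c(toupper(b))
  if (length(a) != length(b)) stop("sequences have different lengths")
  ok <- .comparable(a, b)
  n <- sum(ok)
  out <- NA_real_
  if (n >= 4L) {
    FF <- table(factor(a[ok], .BASES), factor(b[ok], .BASES)) / n
    FF <- (FF + t(FF)) / 2
    pi_ <- rowSums(FF)
    if (all(pi_ > 0)) {
      d_half <- 1 / sqrt(pi_)
      S <- diag(d_half) %*% FF %*% diag(d_half)
      S <- (S + t(S)) / 2
      eg <- eigen(S, symmetric = TRUE)
      if (all(eg$values > tol)) {
        logS <- eg$vectors %*% (log(eg$values) * t(eg$vectors))
        out <- -sum(pi_ * diag(logS))
        if (!is.finite(out) || out < 0) out <- NA_real_
      }
    }
  }
  attr(out, "n_sites") <- n
  out
}

#' Pairwise distance matrix for an alignment
#'
#' @param aln a [mito_alignment] or supermatrix.
#' @param method `"p"` or `"gtr"`.
#' @return list of class `distance_matrix`: `taxa`, `values` (symmetric
#'   matrix, zero diagonal), `defined` (logical mask; a GTR distance may be
#'   undefined at saturation).
#' @export
pairwise_distances <- function(aln, method = c("p", "gtr")) {
  method <- match.arg(method)
  fn <- if (method == "p") p_distance else gtr_distance
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  taxa <- aln$taxa %||% names(aln$seqs)
  k <- nrow(m)
  v <- matrix(0, k, k, dimnames = list(taxa, taxa))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- fn(m[i, ], m[j, ])
    v[i, j] <- v[j, i] <- as.numeric(d)
  }
  structure(list(taxa = taxa, values = v, defined = !is.na(v)),
            class = "distance_matrix")
}

# ---- saturation analysis ----

# pooled per-class alignments from per-gene matrices
pool_position_classes <- function(pcg_alignments, rrna_alignments = NULL) {
  taxa <- Reduce(union, lapply(c(pcg_alignments, rrna_alignments), `[[`, "taxa"))
  pool <- function(alns, pos = NULL) {
    seqs <- stats::setNames(rep("", length(taxa)), taxa)
    for (aln in alns) {
      m <- matrix("-", length(taxa), aln$column_count,
                  dimnames = list(taxa, NULL))
      m[aln$taxa, ] <- aln_matrix(aln)
      if (!is.null(pos)) m <- m[, rep(1:3, length.out = ncol(m)) %in% pos, drop = FALSE]
      seqs <- paste0(seqs, apply(m, 1, paste, collapse = ""))
    }
    stats::setNames(seqs, taxa)
  }
  out <- list(pos1 = pool(pcg_alignments, 1L), pos2 = pool(pcg_alignments, 2L),
              pos3 = pool(pcg_alignments, 3L))
  if (length(rrna_alignments)) out$rRNA <- pool(rrna_alignments)
  out
}

#' Substitution-saturation analysis
#'
#' For each position class (codon positions pooled across all PCGs; rRNA
#' pooled) the uncorrected p-distance of every taxon pair is regressed on its
#' GTR distance (ordinary least squares, free intercept by default). A shallow
#' slope means observed differences plateau as true divergence grows: the
#' lower the slope, the greater the saturation. Pairs whose GTR distance is
#' undefined (saturated beyond the estimator) are excluded and counted.
#'
#' @param pcg_alignments list of PCG [mito_alignment]s (columns divisible
#'   by 3).
#' @param rrna_alignments optional list of rRNA alignments, pooled into an
#'   `rRNA` class.
#' @param through_origin force a zero intercept.
#' @return data.frame of class `saturation_result`, one row per class:
#'   `position_class`, `slope`, `intercept`, `pearson_r`, `mean_gtr`,
#'   `n_pairs_used`, `n_pairs_excluded`.
#' @export
saturation_analysis <- function(pcg_alignments, rrna_alignments = NULL,
                                through_origin = FALSE) {
  classes <- pool_position_classes(pcg_alignments, rrna_alignments)
  if (length(names(classes[[1]])) < 3L) stop("need at least 3 taxa")
  rows <- lapply(names(classes), function(cl) {
    seqs <- classes[[cl]]
    fake <- list(taxa = names(seqs), seqs = seqs)
    p <- pairwise_distances(fake, "p")$values
    g <- pairwise_distances(fake, "gtr")$values
    ut <- upper.tri(p)
    x <- g[ut]; y <- p[ut]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) stop("fewer than 3 defined pairs for class ", cl)
    fit <- if (through_origin) stats::lm(y[ok] ~ 0 + x[ok]) else stats::lm(y[ok] ~ x[ok])
    cf <- stats::coef(fit)
    data.frame(position_class = cl,
               slope = unname(cf[length(cf)]),
               intercept = if (through_origin) 0 else unname(cf[1]),
               pearson_r = if (stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
                 stats::cor(x[ok], y[ok]) else NA_real_,
               mean_gtr = mean(x[ok]),
               n_pairs_used = sum(ok),
               n_pairs_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("saturation_result", "data.frame")
  out
}

#' @export
print.saturation_result <- function(x, digits = 4, ...) {
  cat("Substitution-saturation regression (p-distance on GTR distance):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.saturation_result <- function(x, ...) {
  graphics::barplot(x$slope, names.arg = x$position_class,
                    ylab = "slope (p vs GTR)", ylim = c(0, 1), ...)
  invisible(x)
}

# ---- Nei-Gojobori (1986) nonsynonymous divergence ----

# per-codon synonymous site count; mutations creating stops are excluded from
# the per-position denominator
ng86_sites <- function(codon, code = inv_mito_code()) {
  if (code[[codon]] == "*") return(c(syn = NA_real_, nonsyn = NA_real_))
  ch <- s2c(codon)
  syn <- 0
  for (pos in 1:3) {
    alts <- setdiff(.BASES, ch[pos])
    s <- 0L; valid <- 0L
    for (nt in alts) {
      mut <- ch; mut[pos] <- nt
      aa <- code[[c2s(mut)]]
      if (aa == "*") next
      valid <- valid + 1L
      if (aa == code[[codon]]) s <- s + 1L
    }
    if (valid > 0L) syn <- syn + s / valid
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# synonymous/nonsynonymous differences between two codons: average over all
# orderings of single-nucleotide steps, pathways through stops excluded
# (all pathways used if every one passes through a stop)
ng86_diffs <- function(c1, c2, code = inv_mito_code()) {
  pos <- which(s2c(c1) != s2c(c2))
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    pp <- list()
    for (ord in asplit(permutations_of(k), 1)) pp[[length(pp) + 1]] <- pos[ord]
    pp
  }
  path_counts <- function(order_, allow_stop) {
    cur <- s2c(c1); tgt <- s2c(c2)
    sd <- 0; nd <- 0
    for (p in order_) {
      aa_from <- code[[c2s(cur)]]
      cur[p] <- tgt[p]
      aa_to <- code[[c2s(cur)]]
      if (aa_to == "*" && !allow_stop) return(NULL)
      if (aa_from == aa_to) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, path_counts, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, path_counts, allow_stop = TRUE)
  cnt <- do.call(rbind, res)
  c(sd = mean(cnt[, "sd"]), nd = mean(cnt[, "nd"]))
}

# all permutations of 1..k as a matrix (k <= 3 here)
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations_of(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Nei-Gojobori nonsynonymous divergence (Ka)
#'
#' NG86 counting under the invertebrate mitochondrial code on a codon-aligned
#' coding sequence pair: per-codon synonymous/nonsynonymous site fractions
#' averaged over the two sequences; differences at multi-hit codons averaged
#' over all orderings of single steps with pathways through stop codons
#' excluded; proportion pn = Nd/N Jukes-Cantor corrected to
#' `ka = -(3/4) log(1 - (4/3) pn)`. Symmetric in its arguments. Codons
#' containing a gap or N, or a stop, are skipped.
#'
#' @param focal,reference equal-length coding sequences (character scalars),
#'   codon-aligned, lengths divisible by 3.
#' @param focal_taxon,reference_taxon labels carried into the result.
#' @return object of class `ka_result`: `ka`, `ks`, `pn`, `ps`, `sites_n`
#'   (nonsynonymous sites, fractional), `sites_s`, `nd`, `sd`,
#'   `codons_compared`; `ka` is `NA` (flagged) when pn >= 3/4.
#' @export
ka_ng86 <- function(focal, reference, focal_taxon = "focal",
                    reference_taxon = "reference") {
  code <- inv_mito_code()
  stopifnot(nchar(focal) == nchar(reference))
  if (nchar(focal) %% 3L != 0L) stop("sequence length not divisible by 3")
  ca <- split_codons(toupper(focal))$codons
  cb <- split_codons(toupper(reference))$codons
  N <- 0; S <- 0; Nd <- 0; Sd <- 0; used <- 0L
  for (i in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    if (code[[ca[i]]] == "*" || code[[cb[i]]] == "*") next
    sa <- ng86_sites(ca[i], code); sb <- ng86_sites(cb[i], code)
    S <- S + (sa[["syn"]] + sb[["syn"]]) / 2
    N <- N + (sa[["nonsyn"]] + sb[["nonsyn"]]) / 2
    d <- ng86_diffs(ca[i], cb[i], code)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
    used <- used + 1L
  }
  if (used == 0L) stop("no comparable codons")
  pn <- Nd / N; ps <- if (S > 0) Sd / S else NA_real_
  jc <- function(p) if (!is.na(p) && p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  structure(list(focal_taxon = focal_taxon, reference_taxon = reference_taxon,
                 ka = jc(pn), ks = jc(ps), pn = pn, ps = ps,
                 sites_n = N, sites_s = S, nd = Nd, sd = Sd,
                 codons_compared = used),
            class = "ka_result")
}

#' @export
print.ka_result <- function(x, ...) {
  cat(sprintf("Ka (NG86, %s vs %s): %s  (pn = %.4f over %.1f nonsynonymous sites, %d codons)\n",
              x$focal_taxon, x$reference_taxon,
              if (is.na(x$ka)) "undefined (pn >= 3/4)" else sprintf("%.4f", x$ka),
              x$pn, x$sites_n, x$codons_compared))
  invisible(x)
}

#' Pair the PCGs of two genomes into one concatenated coding alignment
#'
#' Helper for whole-mitogenome Ka: pairs genes by canonical name and
#' concatenates their coding-sense sequences, dropping each gene's terminal
#' (complete or incomplete) stop codon and truncating to complete codons.
#' Requires the paired gene sequences to have equal codon counts (i.e.
#' pre-aligned or alignment-free identical-length data); otherwise it stops
#' and asks for externally aligned input.
#'
#' @param focal,reference [mito_genome] objects.
#' @return list with `focal`, `reference` (concatenated coding strings) and
#'   `genes` used.
#' @export
pair_pcg_concat <- function(focal, reference) {
  code <- inv_mito_code()
  stops <- names(code)[code == "*"]
  strip <- function(genome, gene) {
    cds <- extract_region(genome, gene)
    cds <- substr(cds, 1, 3L * (nchar(cds) %/% 3L))
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (last %in% stops) cds <- substr(cds, 1, nchar(cds) - 3L)
    cds
  }
  fg <- vapply(Filter(function(f) f$class == "PCG", focal$features),
               function(f) f$gene, "")
  rg <- vapply(Filter(function(f) f$class == "PCG", reference$features),
               function(f) f$gene, "")
  genes <- sort(intersect(fg, rg))
  if (!length(genes)) stop("no shared PCGs")
  a <- b <- ""
  for (g in genes) {
    ga <- strip(focal, g); gb <- strip(reference, g)
    if (nchar(ga) != nchar(gb))
      stop(sprintf("gene %s differs in length (%d vs %d nt): supply a codon-aligned pair",
                   g, nchar(ga), nchar(gb)))
    a <- paste0(a, ga); b <- paste0(b, gb)
  }
  list(focal = a, reference = b, genes = genes)
}
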