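# Genome architecture: gene order and rearrangement comparison, gene
# overlap / intergenic spacer accounting, control-region localization and
# tandem-repeat detection.

# ---- gene order ----

new_gene_order <- function(genes, strands, anchor = genes[1]) {
  stopifnot(length(genes) == length(strands), !anyDuplicated(genes),
            all(strands %in% c("J", "N")))
  i <- match(anchor, genes)
  if (is.na(i)) stop("anchor ", anchor, " not in gene set")
  rot <- c(i:length(genes), seq_len(i - 1L))
  structure(list(anchor = anchor,
                 entries = data.frame(gene = genes[rot], strand = strands[rot],
                                      stringsAsFactors = FALSE)),
            class = "gene_order")
}

#' Extract the gene order of a genome
#'
#' Walks the annotated genes (the control region and unmappable features are
#' excluded) 5' to 3' along the J strand and rotates the circular order so
#' the anchor comes first. Re-anchoring is a rotation, never a reordering.
#'
#' @param genome a [mito_genome] or an existing `gene_order` to re-anchor.
#' @param anchor canonical gene used as linearization start (default `trnI`,
#'   the conventional anchor next to the control region).
#' @return object of class `gene_order`: `anchor` and `entries`
#'   (data.frame of gene, strand).
#' @export
gene_order <- function(genome, anchor = "trnI") {
  if (inherits(genome, "gene_order"))
    return(new_gene_order(genome$entries$gene, genome$entries$strand, anchor))
  fs <- Filter(function(f) f$class %in% c("PCG", "tRNA", "rRNA") &&
                 !grepl("unmappable", f$flags), genome$features)
  genes <- vapply(fs, function(f) f$gene, "")
  strands <- vapply(fs, function(f) f$strand, "")
  if (!(anchor %in% genes))
    stop("anchor ", anchor, " absent; available genes: ",
         paste(genes, collapse = ", "))
  new_gene_order(genes, strands, anchor)
}

#' @export
print.gene_order <- function(x, ...) {
  lab <- ifelse(x$entries$strand == "N", paste0("-", x$entries$gene),
                x$entries$gene)
  cat(sprintf("gene_order (%d genes, anchored at %s):\n  %s\n",
              nrow(x$entries), x$anchor, paste(lab, collapse = " ")))
  invisible(x)
}

# signed circular adjacency keys: adjacency (a,sa)->(b,sb) is the same
# adjacency read on the other strand as (b,-sb)->(a,-sa)
adjacency_keys <- function(entries) {
  n <- nrow(entries)
  g <- entries$gene
  s <- ifelse(entries$strand == "J", "+", "-")
  flip <- c("+" = "-", "-" = "+")
  nxt <- c(2:n, 1L)
  fwd <- paste0(s, g, ">", s[nxt], g[nxt])
  rev_ <- paste0(flip[s[nxt]], g[nxt], ">", flip[s], g)
  key <- pmin(fwd, rev_)
  data.frame(gene_a = g, gene_b = g[nxt], key = key, stringsAsFactors = FALSE)
}

#' Compare two gene orders by signed breakpoint analysis
#'
#' Counts the strand-signed circular gene adjacencies of `observed` that are
#' absent from `reference`. Zero breakpoints means the orders are identical
#' up to rotation; the count is symmetric in the two arguments. Genes missing
#' from either order are dropped from both with a warning. Maximal runs of
#' non-shared adjacencies are reported as differing blocks together with the
#' corresponding reference segment.
#'
#' @param observed,reference `gene_order` objects (or [mito_genome]s, which
#'   are converted).
#' @return object of class `rearrangement_report`: `breakpoint_count`,
#'   `shared_adjacencies` (data.frame), `differing_blocks` (list of
#'   `list(ancestral=, observed=)` character vectors), `n_genes`.
#' @export
compare_orders <- function(observed, reference = ancestral_gene_order()) {
  if (inherits(observed, "mito_genome")) observed <- gene_order(observed)
  if (inherits(reference, "mito_genome")) reference <- gene_order(reference)
  common <- intersect(observed$entries$gene, reference$entries$gene)
  if (!length(common)) stop("gene sets are disjoint")
  dropped <- union(setdiff(observed$entries$gene, common),
                   setdiff(reference$entries$gene, common))
  if (length(dropped))
    warning("genes dropped from comparison: ", paste(dropped, collapse = ", "))
  oe <- observed$entries[observed$entries$gene %in% common, , drop = FALSE]
  re <- reference$entries[reference$entries$gene %in% common, , drop = FALSE]
  if (nrow(oe) < 2L) stop("fewer than two shared genes")
  oadj <- adjacency_keys(oe)
  radj <- adjacency_keys(re)
  shared <- oadj$key %in% radj$key
  blocks <- list()
  if (!all(shared)) {
    n <- nrow(oe)
    # a gene is disturbed if either of its adjacencies is non-shared; blocks
    # are maximal circular runs of disturbed genes (rearranged cluster plus
    # its flanking genes)
    prev_adj <- c(n, seq_len(n - 1L))        # adjacency entering gene i
    disturbed <- !shared[prev_adj] | !shared
    if (all(disturbed)) {
      blocks <- list(list(ancestral = re$gene, observed = oe$gene))
    } else {
      off <- which(!disturbed)[1]
      idx <- c(off:n, seq_len(off - 1L))
      r <- rle(disturbed[idx])
      pos <- cumsum(c(1L, r$lengths))
      for (b in which(r$values)) {
        gi <- idx[pos[b]:(pos[b] + r$lengths[b] - 1L)]
        obs_seg <- oe$gene[gi]
        blocks[[length(blocks) + 1]] <-
          list(ancestral = reference_segment(re$gene, obs_seg[1],
                                             obs_seg[length(obs_seg)]),
               observed = obs_seg)
      }
    }
  }
  structure(list(breakpoint_count = sum(!shared),
                 shared_adjacencies = oadj[shared, c("gene_a", "gene_b")],
                 differing_blocks = blocks,
                 n_genes = nrow(oe)),
            class = "rearrangement_report")
}

# genes from `from` to `to` walking forward in reference circular order
reference_segment <- function(ref_genes, from, to) {
  n <- length(ref_genes)
  i <- match(from, ref_genes); j <- match(to, ref_genes)
  if (is.na(i) || is.na(j)) return(character())
  if (j >= i) ref_genes[i:j] else c(ref_genes[i:n], ref_genes[1:j])
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf("rearrangement_report: %d breakpoint(s) over %d genes\n",
              x$breakpoint_count, x$n_genes))
  for (b in x$differing_blocks)
    cat(sprintf("  reference %s -> observed %s\n",
                paste(b$ancestral, collapse = "-"),
                paste(b$observed, collapse = "-")))
  invisible(x)
}

# ---- junctions: overlaps and intergenic spacers ----

# circular end position of a feature (end of its last interval)
.feat_end <- function(f) f$intervals[nrow(f$intervals), 2]
.feat_wraps <- function(f) nrow(f$intervals) > 1L

#' Gene overlaps and intergenic spacers
#'
#' Walks consecutive annotated features around the circle (ordered by start)
#' and classifies each junction as an overlap (shared bases), an intergenic
#' spacer (gap), or abutting. Junctions involving the control region are
#' excluded from the spacer/overlap statistics and reported separately, since
#' the control region is tallied on its own.
#'
#' @param genome a [mito_genome] with at least 2 features.
#' @return object of class `junction_report`: data.frames `overlaps` and
#'   `spacers` (gene_a, gene_b, length), `totals` (overlap_bp,
#'   overlap_junctions, spacer_bp, spacer_count), and `cr` (flanks and length
#'   of the control region if annotated).
#' @export
junctions <- function(genome) {
  fs <- genome$features
  if (length(fs) < 2L) stop("need at least two features")
  n <- nchar(genome$sequence)
  k <- length(fs)
  rows <- lapply(seq_len(k), function(i) {
    a <- fs[[i]]; b <- fs[[if (i == k) 1L else i + 1L]]
    ea <- .feat_end(a); sb <- b$intervals[1, 1]
    gap <- if (i == k && !.feat_wraps(a)) (n - ea) + sb else sb - ea
    data.frame(gene_a = a$gene, gene_b = b$gene, gap = gap,
               has_cr = a$class == "CR" || b$class == "CR",
               stringsAsFactors = FALSE)
  })
  j <- do.call(rbind, rows)
  if (!genome$is_circular) j <- j[-nrow(j), , drop = FALSE]
  core <- j[!j$has_cr, , drop = FALSE]
  overlaps <- core[core$gap < 0, c("gene_a", "gene_b", "gap")]
  overlaps$length <- -overlaps$gap; overlaps$gap <- NULL
  spacers <- core[core$gap > 0, c("gene_a", "gene_b", "gap")]
  names(spacers)[3] <- "length"
  cr_f <- Filter(function(f) f$class == "CR", fs)
  cr <- NULL
  if (length(cr_f)) {
    crj <- j[j$has_cr, , drop = FALSE]
    cr <- list(gene = cr_f[[1]]$gene, length = cr_f[[1]]$length,
               upstream = crj$gene_a[crj$gene_b == "CR"][1],
               downstream = crj$gene_b[crj$gene_a == "CR"][1])
  }
  structure(list(overlaps = overlaps, spacers = spacers,
                 totals = c(overlap_bp = sum(overlaps$length),
                            overlap_junctions = nrow(overlaps),
                            spacer_bp = sum(spacers$length),
                            spacer_count = nrow(spacers)),
                 cr = cr),
            class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat(sprintf("junction_report: %d bp in overlaps at %d junctions; %d spacers totaling %d bp\n",
              x$totals[["overlap_bp"]], x$totals[["overlap_junctions"]],
              x$totals[["spacer_count"]], x$totals[["spacer_bp"]]))
  if (!is.null(x$cr))
    cat(sprintf("  control region: %d bp between %s and %s\n",
                x$cr$length, x$cr$upstream, x$cr$downstream))
  invisible(x)
}

# ---- control region ----

#' Locate the control region
#'
#' An annotated control region (D-loop) takes precedence. Otherwise the
#' putative control region is the unannotated span from the end of rrnS to
#' the start of trnI walking the J strand (wrapping the origin if needed),
#' the canonical position of the A+T-rich region in insect mitogenomes. A
#' warning is raised if a longer unannotated span exists elsewhere.
#'
#' @param genome a [mito_genome] with rrnS and trnI annotated.
#' @return a [gene_feature] labelled `"CR"` (flag `"inferred"` when not
#'   annotated).
#' @export
locate_control_region <- function(genome) {
  ann <- get_feature(genome, "CR")
  if (!is.null(ann)) return(ann)
  rrnS <- get_feature(genome, "rrnS"); trnI <- get_feature(genome, "trnI")
  if (is.null(rrnS) || is.null(trnI))
    stop("rrnS and trnI must be annotated to locate the control region")
  n <- nchar(genome$sequence)
  from <- .feat_end(rrnS); to <- trnI$intervals[1, 1]
  len <- if (to >= from) to - from else (n - from) + to
  if (len == 0L) stop("no span between rrnS and trnI")
  intervals <- if (to > from) cbind(from, to)
    else if (to == 0L) cbind(from, n)
    else rbind(cbind(from, n), cbind(0L, to))
  cr <- gene_feature("CR", "J", intervals, class = "CR", flags = "inferred")
  jr <- junctions(genome)
  other <- jr$spacers[!(jr$spacers$gene_a == "rrnS" & jr$spacers$gene_b == "trnI"), ]
  if (nrow(other) && max(other$length) > len)
    warning(sprintf("a longer unannotated span (%d bp, %s-%s) exists elsewhere",
                    max(other$length),
                    other$gene_a[which.max(other$length)],
                    other$gene_b[which.max(other$length)]))
  cr
}

# ---- tandem repeats ----

#' Detect tandem repeats in a nucleotide region
#'
#' A k-mer seeded detector: exact k-mer matches at lag p propose candidate
#' periods; each candidate is extended greedily around its seed while the
#' running identity of aligned positions (s[i] vs s[i+p]) stays above the
#' identity threshold, then validated against a per-column majority consensus.
#' Candidate periods are reduced to their primitive period (a divisor that
#' already explains the region) so multiples are not reported; overlapping
#' candidates are resolved greedily by the score identity x copies x period.
#'
#' @param region nucleotide text (e.g. an extracted control region).
#' @param min_period minimum repeat unit length (bp).
#' @param min_copies minimum (fractional) number of copies.
#' @param min_identity minimum fraction of positions matching the consensus.
#' @param k seed k-mer length.
#' @return data.frame with columns `start` (0-based offset in `region`),
#'   `period`, `copies`, `identity`, `consensus`; zero rows when nothing is
#'   found.
#' @export
find_tandem_repeats <- function(region, min_period = 10L, min_copies = 1.8,
                                min_identity = 0.80, k = 12L) {
  empty <- data.frame(start = integer(), period = integer(), copies = numeric(),
                      identity = numeric(), consensus = character(),
                      stringsAsFactors = FALSE)
  region <- toupper(region)
  s <- s2c(region)
  n <- length(s)
  if (n < 2L * min_period) return(empty)
  k <- max(4L, min(as.integer(k), n %/% 2L))   # short regions need shorter seeds
  max_period <- floor(n / min_copies)

  # seed: positions sharing an exact k-mer
  nk <- n - k + 1L
  kmers <- substring(region, seq_len(nk), seq_len(nk) + k - 1L)
  grp <- split(seq_len(nk), kmers)
  grp <- grp[lengths(grp) >= 2L]
  cand <- list()
  for (pos in grp) {
    if (length(pos) > 50L) {  # low-complexity guard: consecutive lags only
      d <- cbind(pos[-length(pos)], pos[-1])
    } else {
      pr <- t(utils::combn(pos, 2L))
      d <- pr
    }
    lag <- d[, 2] - d[, 1]
    keep <- lag >= min_period & lag <= max_period
    if (any(keep))
      cand[[length(cand) + 1]] <- data.frame(i = d[keep, 1], p = lag[keep])
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)

  evaluate <- function(p, seed_i) {
    m <- s[seq_len(n - p)] == s[seq_len(n - p) + p]
    i <- min(seed_i, n - p); j <- min(seed_i + k - 1L, n - p)
    # maximal-scoring window containing the seed: match +1, mismatch penalized
    # so that windows below the identity threshold score negative
    pen <- min_identity / (1 - min_identity)
    v <- ifelse(m, 1, -pen)
    cv <- cumsum(v)
    # window sum = cv[j] - cv[i-1]: minimize cv[i-1] over i <= seed start,
    # maximize cv[j] over j >= seed end
    i <- which.min(c(0, cv)[seq_len(i)])      # index into cv[i-1], cv[0] = 0
    j <- (j - 1L) + which.max(cv[j:length(v)])
    cs <- cumsum(m)
    win_id <- function(a, b) (cs[b] - if (a > 1) cs[a - 1] else 0) / (b - a + 1L)
    if (win_id(i, j) < min_identity) return(NULL)
    span <- (j - i + 1L) + p
    copies <- span / p
    if (copies < min_copies) return(NULL)
    r <- s[i:(j + p)]
    col <- ((seq_along(r) - 1L) %% p) + 1L
    cons <- vapply(seq_len(p), function(cc) {
      tb <- tabulate(match(r[col == cc], .BASES), nbins = 4L)
      .BASES[which.max(tb)]
    }, "")
    identity <- mean(r == cons[col])
    if (identity < min_identity) return(NULL)
    list(start = i - 1L, period = p, copies = copies, identity = identity,
         consensus = c2s(cons), score = identity * copies * p, seed = seed_i)
  }

  # best seed per candidate period (limit work per period)
  res <- list()
  for (p in sort(unique(cand$p))) {
    seeds <- cand$i[cand$p == p]
    seeds <- unique(seeds[order(seeds)])
    if (length(seeds) > 20L)
      seeds <- seeds[unique(round(seq(1L, length(seeds), length.out = 20L)))]
    best <- NULL
    for (si in seeds) {
      ev <- evaluate(p, si)
      if (!is.null(ev) && (is.null(best) || ev$score > best$score)) best <- ev
    }
    if (is.null(best)) next
    # primitive-period reduction: prefer the smallest divisor that explains it
    divs <- which(p %% seq_len(p - 1L) == 0L)
    divs <- divs[divs >= min_period]
    for (q in divs) {
      evq <- evaluate(q, best$seed)
      if (!is.null(evq) && evq$identity >= min_identity &&
          (evq$copies * evq$period) >= 0.9 * (best$copies * best$period)) {
        best <- evq
        break
      }
    }
    res[[length(res) + 1]] <- best
  }
  if (!length(res)) return(empty)

  # greedy non-overlapping selection by score, ties to smaller period
  score <- vapply(res, `[[`, 0, "score")
  per <- vapply(res, `[[`, 0, "period")
  ord <- order(-score, per)
  chosen <- list()
  occupied <- rep(FALSE, n)
  for (idx in ord) {
    r <- res[[idx]]
    span <- r$start + seq_len(round(r$copies * r$period))
    span <- span[span <= n]
    if (any(occupied[span])) next
    # skip period multiples of an already chosen repeat at the same locus
    occupied[span] <- TRUE
    chosen[[length(chosen) + 1]] <- r
  }
  out <- do.call(rbind, lapply(chosen, function(r)
    data.frame(start = r$start, period = r$period, copies = r$copies,
               identity = r$identity, consensus = r$consensus,
               stringsAsFactors = FALSE)))
  out[order(out$start), , drop = FALSE]
}
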