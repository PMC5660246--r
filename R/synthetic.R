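# Synthetic data with known ground truth: annotated mitogenomes realizing a
# declared architecture and composition, and sequence pairs/sets diverged
# under a GTR model with known branch lengths. Everything is reproducible
# from the seed carried in the spec/model.

# base frequencies realizing A+T, AT-skew and GC-skew targets in expectation
target_freqs <- function(at, at_skew, gc_skew) {
  stopifnot(at > 0, at < 1, abs(at_skew) <= 1, abs(gc_skew) <= 1)
  c(A = at * (1 + at_skew) / 2, C = (1 - at) * (1 - gc_skew) / 2,
    G = (1 - at) * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
}

#' Specification for a synthetic annotated mitogenome
#'
#' Defaults emulate a typical leafhopper mitogenome: the 37-gene ancestral
#' insect arrangement, A+T 78%, slightly positive AT skew and negative GC skew
#' on the J strand, a 908 bp control region carrying a 239 bp tandem repeat
#' with two full copies and a 179 bp partial, the three overlaps commonly
#' annotated in this group (trnW-trnC 8 bp, atp8-atp6 7 bp, nad4-nad4l 7 bp),
#' ATG starts except TTG for nad5, TAA stops except TAG for nad5 and
#' incomplete T for cox2 and nad1.
#'
#' @param gene_order data.frame with columns `gene`, `strand` (default:
#'   ancestral insect order).
#' @param gene_lengths named bp vector (PCG lengths include the complete
#'   stop codon and are divisible by 3).
#' @param at_target,at_skew_target,gc_skew_target composition targets for the
#'   J strand (met in expectation, not forced exactly).
#' @param cr_spec `list(length, period, copies, noise)` for the control
#'   region, or `NULL` for no control region.
#' @param overlap_spec data.frame `gene_a`, `gene_b`, `bp` of planted
#'   overlaps between consecutive genes.
#' @param start_stop_spec named list per PCG: `list(start=, stop=)`, stop one
#'   of `"TAA"`, `"TAG"`, `"TA"`, `"T"` (the last two are incomplete stops,
#'   realized by truncating the stop codon and shortening the annotation).
#' @param accession,taxon identifying text for the synthetic record.
#' @param seed integer; fixes all randomness.
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(gene_order = NULL, gene_lengths = NULL,
                        at_target = 0.78, at_skew_target = 0.05,
                        gc_skew_target = -0.20,
                        cr_spec = list(length = 908L, period = 239L,
                                       copies = 657 / 239, noise = 0),
                        overlap_spec = data.frame(
                          gene_a = c("trnW", "atp8", "nad4"),
                          gene_b = c("trnC", "atp6", "nad4l"),
                          bp = c(8L, 7L, 7L), stringsAsFactors = FALSE),
                        start_stop_spec = NULL,
                        accession = "SYN000001", taxon = "synthetic mitogenome",
                        seed = 1L) {
  if (is.null(gene_order)) gene_order <- ancestral_gene_order()$entries
  if (is.null(gene_lengths)) gene_lengths <- default_gene_lengths()
  pcgs <- gene_order$gene[feature_class_of(gene_order$gene) == "PCG"]
  sss <- stats::setNames(lapply(pcgs, function(g) list(start = "ATG", stop = "TAA")),
                         pcgs)
  if ("nad5" %in% pcgs) sss$nad5 <- list(start = "TTG", stop = "TAG")
  if ("cox2" %in% pcgs) sss$cox2$stop <- "T"
  if ("nad1" %in% pcgs) sss$nad1$stop <- "T"
  if (!is.null(start_stop_spec)) sss[names(start_stop_spec)] <- start_stop_spec
  structure(list(gene_order = gene_order, gene_lengths = gene_lengths,
                 at_target = at_target, at_skew_target = at_skew_target,
                 gc_skew_target = gc_skew_target, cr_spec = cr_spec,
                 overlap_spec = overlap_spec, start_stop_spec = sss,
                 accession = accession, taxon = taxon, seed = as.integer(seed)),
            class = "genome_spec")
}

# sample stop-free codons with per-base probabilities proportional to freqs
sample_codons <- function(k, freqs, code = inv_mito_code()) {
  sense <- names(code)[code != "*"]
  w <- vapply(strsplit(sense, ""), function(ch) prod(freqs[ch]), 0)
  sample(sense, k, replace = TRUE, prob = w)
}

# expected A+T share of codons drawn proportionally to per-base freqs,
# restricted to sense codons (stops are A+T-rich, so exclusion biases AT down)
.sense_at_expectation <- function(freqs, code = inv_mito_code()) {
  sense <- names(code)[code != "*"]
  chars <- strsplit(sense, "")
  w <- vapply(chars, function(ch) prod(freqs[ch]), 0)
  at <- vapply(chars, function(ch) sum(ch %in% c("A", "T")) / 3, 0)
  sum(w * at) / sum(w)
}

# base frequencies for CDS sampling, inflated so the realized sense-codon
# A+T content matches the target despite stop-codon exclusion
cds_freqs <- function(at, at_skew, gc_skew, code = inv_mito_code()) {
  f <- function(at_adj) .sense_at_expectation(target_freqs(at_adj, at_skew, gc_skew),
                                              code) - at
  hi <- min(0.995, at + 0.1)
  if (f(hi) < 0) return(target_freqs(hi, at_skew, gc_skew))
  at_adj <- stats::uniroot(f, c(max(0.005, at - 0.05), hi), tol = 1e-6)$root
  target_freqs(at_adj, at_skew, gc_skew)
}

.stop_len <- function(stop) nchar(stop)

#' Generate a synthetic annotated mitogenome
#'
#' Realizes the gene order, lengths, overlaps, start/stop codons, control
#' region repeats and composition targets of a [genome_spec], and returns the
#' genome together with a truth record carrying every planted quantity.
#'
#' @param spec a [genome_spec].
#' @return list with elements `genome` (a [mito_genome]) and `truth`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  code <- inv_mito_code()
  freqs <- target_freqs(spec$at_target, spec$at_skew_target, spec$gc_skew_target)
  pcg_freqs <- cds_freqs(spec$at_target, spec$at_skew_target, spec$gc_skew_target,
                         code)
  ord <- spec$gene_order
  with_seed(spec$seed, {
    # annotated lengths (incomplete stops shorten the annotation)
    ann_len <- integer(nrow(ord))
    for (i in seq_len(nrow(ord))) {
      g <- ord$gene[i]
      gl <- spec$gene_lengths[[g]]
      if (is.null(gl) || is.na(gl)) stop("no length for gene ", g)
      if (feature_class_of(g) == "PCG") {
        st <- spec$start_stop_spec[[g]]$stop
        if (gl %% 3L != 0L) stop("PCG length for ", g, " not divisible by 3")
        gl <- gl - (3L - .stop_len(st))
      }
      ann_len[i] <- gl
    }
    # coordinates: walk, applying planted overlaps between consecutive genes
    ov_of <- function(a, b) {
      os <- spec$overlap_spec
      hit <- which((os$gene_a == a & os$gene_b == b) |
                   (os$gene_a == b & os$gene_b == a))
      if (length(hit)) os$bp[hit[1]] else 0L
    }
    starts <- integer(nrow(ord)); ends <- integer(nrow(ord))
    cur <- 0L
    for (i in seq_len(nrow(ord))) {
      ov <- if (i == 1L) 0L else ov_of(ord$gene[i - 1L], ord$gene[i])
      if (ov >= ann_len[i] || (i > 1L && ov >= ann_len[i - 1L]))
        stop("overlap between ", ord$gene[i - 1L], " and ", ord$gene[i],
             " longer than a gene")
      starts[i] <- cur - ov
      ends[i] <- starts[i] + ann_len[i]
      cur <- ends[i]
    }
    cr_len <- if (is.null(spec$cr_spec)) 0L else as.integer(spec$cr_spec$length)
    cr_after <- match("rrnS", ord$gene)
    if (is.na(cr_after)) cr_after <- nrow(ord)
    cr_start <- ends[cr_after]
    if (cr_len > 0L && cr_after < nrow(ord)) {   # shift genes past the CR
      later <- (cr_after + 1L):nrow(ord)
      starts[later] <- starts[later] + cr_len
      ends[later] <- ends[later] + cr_len
    }
    total <- cur + cr_len
    buf <- rep(NA_character_, total)

    # control region: planted tandem repeat then background
    cr_truth <- NULL
    if (cr_len > 0L) {
      cs <- spec$cr_spec
      period <- as.integer(cs$period)
      span <- round(cs$copies * period)
      if (span > cr_len) stop("control-region repeats longer than the region")
      unit <- sample(.BASES, period, replace = TRUE, prob = freqs)
      tiled <- rep(unit, length.out = span)
      noise <- cs$noise %||% 0
      if (noise > 0) {
        flip <- which(stats::runif(span) < noise)
        for (f in flip) tiled[f] <- sample(setdiff(.BASES, tiled[f]), 1L)
      }
      cr_seq <- c(tiled, sample(.BASES, cr_len - span, replace = TRUE, prob = freqs))
      buf[(cr_start + 1L):(cr_start + cr_len)] <- cr_seq
      cr_truth <- list(start = cr_start, length = cr_len, period = period,
                       copies = span / period, unit = c2s(unit), noise = noise)
    }

    # gene bodies (fill only unwritten positions, so overlaps share bases)
    for (i in seq_len(nrow(ord))) {
      g <- ord$gene[i]; cls <- feature_class_of(g)
      len <- ann_len[i]
      coding <- if (cls == "PCG") {
        ss <- spec$start_stop_spec[[g]]
        k <- (len - 3L - .stop_len(ss$stop)) / 3L
        paste0(ss$start, paste(sample_codons(k, pcg_freqs, code), collapse = ""),
               ss$stop)
      } else c2s(sample(.BASES, len, replace = TRUE, prob = freqs))
      jseq <- if (ord$strand[i] == "N") revcomp(coding) else coding
      idx <- (starts[i] + 1L):ends[i]
      fill <- is.na(buf[idx])
      buf[idx[fill]] <- s2c(jseq)[fill]
    }
    buf[is.na(buf)] <- sample(.BASES, sum(is.na(buf)), replace = TRUE, prob = freqs)

    # plant start/stop codons (they win inside overlap regions)
    locked <- rep(FALSE, total)
    for (i in seq_len(nrow(ord))) {
      g <- ord$gene[i]
      if (feature_class_of(g) != "PCG") next
      ss <- spec$start_stop_spec[[g]]
      sl <- .stop_len(ss$stop)
      if (ord$strand[i] == "J") {
        buf[(starts[i] + 1L):(starts[i] + 3L)] <- s2c(ss$start)
        buf[(ends[i] - sl + 1L):ends[i]] <- s2c(ss$stop)
        locked[c((starts[i] + 1L):(starts[i] + 3L), (ends[i] - sl + 1L):ends[i])] <- TRUE
      } else {
        buf[(ends[i] - 2L):ends[i]] <- s2c(revcomp(ss$start))
        buf[(starts[i] + 1L):(starts[i] + sl)] <- s2c(revcomp(ss$stop))
        locked[c((ends[i] - 2L):ends[i], (starts[i] + 1L):(starts[i] + sl))] <- TRUE
      }
    }

    # repair pass: a planted codon inside an overlap can induce an internal
    # stop in the partner gene's frame; mutate an unlocked base of any such
    # stop codon until every CDS body is stop-free
    is_pcg <- feature_class_of(ord$gene) == "PCG"
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (pass in seq_len(100L)) {
      fixed_any <- FALSE
      for (i in which(is_pcg)) {
        len <- ends[i] - starts[i]
        n_cod <- len %/% 3L
        n_body <- if (len %% 3L == 0L) n_cod - 1L else n_cod  # exclude complete stop
        coding <- if (ord$strand[i] == "J") buf[(starts[i] + 1L):ends[i]]
                  else unname(comp[buf[ends[i]:(starts[i] + 1L)]])
        cods <- vapply(seq_len(n_body), function(cd)
          c2s(coding[(3L * cd - 2L):(3L * cd)]), "")
        for (cd in which(code[cods] == "*")) {
          jpos <- if (ord$strand[i] == "J") starts[i] + (3L * cd - 2L):(3L * cd)
                  else ends[i] - (3L * cd - 2L):(3L * cd) + 1L
          codon <- cods[cd]
          free <- which(!locked[jpos])
          if (!length(free))
            stop("inconsistent spec: locked codons force an internal stop in ",
                 ord$gene[i])
          q <- free[1]
          ch <- s2c(codon)
          opts <- Filter(function(b) {
            cc <- ch; cc[q] <- b; code[[c2s(cc)]] != "*"
          }, setdiff(.BASES, ch[q]))
          nb <- sample(opts, 1L)
          buf[jpos[q]] <- if (ord$strand[i] == "J") nb else comp[[nb]]
          fixed_any <- TRUE
        }
      }
      if (!fixed_any) break
      if (pass == 100L) stop("inconsistent spec: could not remove internal stops")
    }

    features <- lapply(seq_len(nrow(ord)), function(i)
      gene_feature(ord$gene[i], ord$strand[i], cbind(starts[i], ends[i])))
    if (cr_len > 0L)
      features <- c(features, list(gene_feature("CR", "J",
                                                cbind(cr_start, cr_start + cr_len))))
    genome <- mito_genome(c2s(buf), features, accession = spec$accession,
                          taxon = spec$taxon)
    truth <- list(spec = spec, genome_length = total,
                  coordinates = data.frame(gene = ord$gene, strand = ord$strand,
                                           start = starts, end = ends,
                                           stringsAsFactors = FALSE),
                  cr = cr_truth, at_target = spec$at_target,
                  at_skew_target = spec$at_skew_target,
                  gc_skew_target = spec$gc_skew_target,
                  overlaps = spec$overlap_spec,
                  start_stops = spec$start_stop_spec, seed = spec$seed)
    list(genome = genome, truth = truth)
  })
}

# ---- GTR sequence evolution ----

#' Define a GTR substitution model
#'
#' @param exchangeabilities six rates in the order AC, AG, AT, CG, CT, GT
#'   (scale-free; Jukes-Cantor is all ones with uniform frequencies).
#' @param frequencies stationary base frequencies (A, C, G, T), summing to 1.
#' @param t branch length separating the pair, in expected
#'   substitutions/site.
#' @param site_rate_classes optional per-position rate multipliers recycled
#'   along the sequence (e.g. `c(1, 1, 5)` for fast third codon positions).
#' @param seed integer seed.
#' @return list of class `gtr_model` including the normalized rate matrix `Q`.
#' @export
gtr_model <- function(exchangeabilities = rep(1, 6),
                      frequencies = rep(0.25, 4), t = 0.1,
                      site_rate_classes = NULL, seed = 1L) {
  stopifnot(length(exchangeabilities) == 6, all(exchangeabilities > 0),
            length(frequencies) == 4, all(frequencies > 0),
            abs(sum(frequencies) - 1) < 1e-8, t >= 0)
  R <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  R["A", "C"] <- exchangeabilities[1]; R["A", "G"] <- exchangeabilities[2]
  R["A", "T"] <- exchangeabilities[3]; R["C", "G"] <- exchangeabilities[4]
  R["C", "T"] <- exchangeabilities[5]; R["G", "T"] <- exchangeabilities[6]
  R <- R + t(R)
  Q <- R * rep(frequencies, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(frequencies * diag(Q))
  Q <- Q / mu
  structure(list(exchangeabilities = exchangeabilities,
                 frequencies = stats::setNames(frequencies, .BASES),
                 t = t, site_rate_classes = site_rate_classes,
                 Q = Q, seed = as.integer(seed)),
            class = "gtr_model")
}

# transition probability matrix exp(Qt) via the reversible eigendecomposition
gtr_pmatrix <- function(model, t) {
  pi_ <- model$frequencies
  D <- sqrt(pi_)
  B <- diag(D) %*% model$Q %*% diag(1 / D)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  P <- diag(1 / D) %*% eg$vectors %*% (exp(eg$values * t) * t(eg$vectors)) %*% diag(D)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a diverged sequence pair under a GTR model
#'
#' The ancestor is drawn from the stationary frequencies; the descendant is
#' drawn per site from the exact transition probabilities `exp(Q t)` (times
#' any per-position rate multiplier). In codon mode the ancestor is stop-free
#' and any codon evolving into a stop is redrawn, so the output is usable for
#' Ka tests.
#'
#' @param length sequence length in bases (nucleotide mode) or codons (codon
#'   mode).
#' @param model a [gtr_model]; its `t` is the true branch length, the truth
#'   record of the simulation.
#' @param mode `"nucleotide"` or `"codon"`.
#' @param seed seed; defaults to the model's.
#' @return list: `ancestor`, `descendant` (character scalars), `t`, `model`.
#' @export
evolve_pair <- function(length, model, mode = c("nucleotide", "codon"),
                        seed = model$seed) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "gtr_model"), length >= 1)
  with_seed(seed, {
    if (mode == "nucleotide") {
      n <- as.integer(length)
      rates <- if (is.null(model$site_rate_classes)) rep(1, n)
        else rep_len(model$site_rate_classes, n)
      anc <- sample.int(4L, n, replace = TRUE, prob = model$frequencies)
      des <- integer(n)
      for (m in unique(rates)) {
        P <- gtr_pmatrix(model, model$t * m)
        idx <- which(rates == m)
        u <- stats::runif(length(idx))
        cp <- t(apply(P, 1, cumsum))
        des[idx] <- vapply(seq_along(idx), function(j)
          findInterval(u[j], cp[anc[idx[j]], ], left.open = TRUE) + 1L, 0L)
      }
      list(ancestor = c2s(.BASES[anc]), descendant = c2s(.BASES[des]),
           t = model$t, model = model)
    } else {
      code <- inv_mito_code()
      k <- as.integer(length)
      rates <- if (is.null(model$site_rate_classes)) rep(1, 3)
        else rep_len(model$site_rate_classes, 3)
      Ps <- lapply(rates, function(m) gtr_pmatrix(model, model$t * m))
      cps <- lapply(Ps, function(P) t(apply(P, 1, cumsum)))
      draw_codon <- function() {
        repeat {
          cd <- sample.int(4L, 3L, replace = TRUE, prob = model$frequencies)
          if (code[[c2s(.BASES[cd])]] != "*") return(cd)
        }
      }
      anc <- replicate(k, draw_codon())
      des <- matrix(0L, 3L, k)
      for (i in seq_len(k)) {
        tries <- 0L
        repeat {
          d <- vapply(1:3, function(p)
            findInterval(stats::runif(1), cps[[p]][anc[p, i], ],
                         left.open = TRUE) + 1L, 0L)
          if (code[[c2s(.BASES[d])]] != "*") break
          tries <- tries + 1L
          if (tries > 200L) { d <- anc[, i]; break }
        }
        des[, i] <- d
      }
      list(ancestor = c2s(.BASES[as.vector(anc)]),
           descendant = c2s(.BASES[as.vector(des)]),
           t = model$t, model = model)
    }
  })
}

#' Simulate a star-tree alignment under a GTR model
#'
#' One ancestor from the stationary distribution; each taxon evolved
#' independently from it at branch length `model$t` (so every pair is
#' separated by `2 t`). Convenience wrapper used to exercise the saturation
#' and distance machinery on data with known truth.
#'
#' @param n_taxa number of tips.
#' @param length sites (made divisible by 3 when `feature_class` is PCG).
#' @param model a [gtr_model].
#' @param feature_class,gene_name passed to [mito_alignment()].
#' @param seed seed; defaults to the model's.
#' @return a [mito_alignment] named `t1..tn`.
#' @export
evolve_star <- function(n_taxa, length, model, feature_class = "PCG",
                        gene_name = "sim", seed = model$seed) {
  if (feature_class == "PCG") length <- 3L * (as.integer(length) %/% 3L)
  with_seed(seed, {
    n <- as.integer(length)
    rates <- if (is.null(model$site_rate_classes)) rep(1, n)
      else rep_len(model$site_rate_classes, n)
    anc <- sample.int(4L, n, replace = TRUE, prob = model$frequencies)
    cps <- lapply(unique(rates), function(m) {
      P <- gtr_pmatrix(model, model$t * m)
      t(apply(P, 1, cumsum))
    })
    names(cps) <- as.character(unique(rates))
    seqs <- vapply(seq_len(n_taxa), function(tx) {
      des <- integer(n)
      for (m in unique(rates)) {
        idx <- which(rates == m)
        cp <- cps[[as.character(m)]]
        u <- stats::runif(length(idx))
        des[idx] <- vapply(seq_along(idx), function(j)
          findInterval(u[j], cp[anc[idx[j]], ], left.open = TRUE) + 1L, 0L)
      }
      c2s(.BASES[des])
    }, "")
    mito_alignment(stats::setNames(seqs, paste0("t", seq_len(n_taxa))),
                   gene_name = gene_name, feature_class = feature_class)
  })
}
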