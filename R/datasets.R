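# Phylogenetic dataset construction: concatenation into a supermatrix with
# charsets, codon-position subsetting, translation, and partition-file export.

#' Construct a supermatrix
#'
#' @param seqs named character vector of equal-length gapped rows.
#' @param charsets data.frame with columns `label`, `class` (`"PCG"` or
#'   `"rRNA"`), `start`, `end` (1-based inclusive column ranges tiling the
#'   matrix without overlap).
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return object of class `supermatrix`: `taxa`, `seqs`, `charsets`,
#'   `alphabet`, `column_count`.
#' @export
supermatrix <- function(seqs, charsets,
                        alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  lens <- nchar(seqs)
  stopifnot(length(unique(lens)) == 1L)
  ncol_ <- unname(lens[1])
  cs <- charsets[order(charsets$start), , drop = FALSE]
  if (nrow(cs)) {
    stopifnot(cs$start[1] == 1L, cs$end[nrow(cs)] == ncol_,
              all(cs$start <= cs$end),
              all(cs$start[-1] == cs$end[-nrow(cs)] + 1L))
  }
  structure(list(taxa = names(seqs), seqs = seqs, charsets = cs,
                 alphabet = alphabet, column_count = ncol_),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d %s columns, %d charsets\n",
              length(x$taxa), x$column_count, x$alphabet, nrow(x$charsets)))
  invisible(x)
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in the given order; a charset records each gene's
#' column range. Taxa missing from an alignment are filled with gaps, with a
#' warning.
#'
#' @param alignments list of [mito_alignment]s.
#' @param taxon_order optional row order; defaults to the union of taxa in
#'   first-appearance order.
#' @return a [supermatrix].
#' @export
concatenate_alignments <- function(alignments, taxon_order = NULL) {
  if (!length(alignments)) stop("no alignments to concatenate")
  all_taxa <- Reduce(union, lapply(alignments, `[[`, "taxa"))
  if (is.null(taxon_order)) taxon_order <- all_taxa
  if (!length(intersect(taxon_order, all_taxa))) stop("no shared taxa")
  seqs <- stats::setNames(rep("", length(taxon_order)), taxon_order)
  cs <- list(); at <- 0L
  for (aln in alignments) {
    missing <- setdiff(taxon_order, aln$taxa)
    if (length(missing))
      warning(sprintf("%s: taxa filled with gaps: %s", aln$gene_name,
                      paste(missing, collapse = ", ")))
    block <- stats::setNames(rep(strrep("-", aln$column_count),
                                 length(taxon_order)), taxon_order)
    present <- intersect(taxon_order, aln$taxa)
    block[present] <- aln$seqs[present]
    seqs <- paste0(seqs, block)
    names(seqs) <- taxon_order
    cs[[length(cs) + 1]] <- data.frame(
      label = aln$gene_name, class = aln$feature_class,
      start = at + 1L, end = at + aln$column_count, stringsAsFactors = FALSE)
    at <- at + aln$column_count
  }
  supermatrix(seqs, do.call(rbind, cs), "nucleotide")
}

#' Slice one charset back out of a supermatrix
#'
#' Inverse of [concatenate_alignments()] for a single gene block.
#'
#' @param sm a [supermatrix].
#' @param label charset label.
#' @return a [mito_alignment].
#' @export
slice_charset <- function(sm, label) {
  cs <- sm$charsets[sm$charsets$label == label, , drop = FALSE]
  if (nrow(cs) != 1L) stop("no unique charset ", label)
  mito_alignment(stats::setNames(substr(sm$seqs, cs$start, cs$end), sm$taxa),
                 gene_name = label, feature_class = cs$class)
}

#' Keep selected codon positions of a PCG supermatrix
#'
#' Codon position is defined gene-locally from each charset's start, so every
#' charset must be a PCG block with a column count divisible by 3. Charsets
#' are rewritten for the reduced matrix.
#'
#' @param sm nucleotide [supermatrix] whose charsets are all PCGs.
#' @param positions subset of `c(1, 2, 3)`.
#' @return a [supermatrix].
#' @export
codon_subset <- function(sm, positions) {
  stopifnot(all(positions %in% 1:3), sm$alphabet == "nucleotide")
  if (any(sm$charsets$class != "PCG"))
    stop("codon positions are only defined for PCG charsets")
  keep <- logical(sm$column_count)
  for (r in seq_len(nrow(sm$charsets))) {
    cols <- sm$charsets$start[r]:sm$charsets$end[r]
    if (length(cols) %% 3L != 0L)
      stop("charset ", sm$charsets$label[r], " not divisible by 3")
    keep[cols] <- rep(1:3, length.out = length(cols)) %in% positions
  }
  m <- do.call(rbind, strsplit(unname(sm$seqs), "", fixed = TRUE))
  seqs <- stats::setNames(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
                          sm$taxa)
  cs <- sm$charsets
  widths <- (cs$end - cs$start + 1L) / 3L * length(positions)
  cs$end <- cumsum(widths)
  cs$start <- cs$end - widths + 1L
  supermatrix(seqs, cs, "nucleotide")
}

#' Translate a PCG supermatrix to amino acids
#'
#' Codon-wise translation under the invertebrate mitochondrial code. All-gap
#' codons become a gap; codons containing a gap or N become `X`. A stop codon
#' anywhere is a hard error naming the taxon, gene and codon (stop codons are
#' removed upstream when alignments are built).
#'
#' @param sm nucleotide [supermatrix] over PCG charsets.
#' @return an amino-acid [supermatrix].
#' @export
translate_matrix <- function(sm) {
  stopifnot(sm$alphabet == "nucleotide")
  if (any(sm$charsets$class != "PCG")) stop("non-PCG charset present")
  code <- inv_mito_code()
  m <- do.call(rbind, strsplit(unname(sm$seqs), "", fixed = TRUE))
  n_codons <- sm$column_count %/% 3L
  if (sm$column_count %% 3L != 0L) stop("column count not divisible by 3")
  gene_of <- character(n_codons)
  for (r in seq_len(nrow(sm$charsets)))
    gene_of[((sm$charsets$start[r] - 1L) %/% 3L + 1L):(sm$charsets$end[r] %/% 3L)] <-
      sm$charsets$label[r]
  out <- matrix("", length(sm$taxa), n_codons)
  for (cd in seq_len(n_codons)) {
    block <- m[, (3L * cd - 2L):(3L * cd), drop = FALSE]
    cods <- apply(block, 1, paste, collapse = "")
    aa <- rep("X", length(cods))
    aa[cods == "---"] <- "-"
    clean <- !grepl("[^ACGT]", cods)
    aa[clean] <- unname(code[cods[clean]])
    if (any(aa == "*", na.rm = TRUE)) {
      bad <- which(aa == "*")[1]
      stop(sprintf("stop codon at codon %d (gene %s) in taxon %s",
                   cd, gene_of[cd], sm$taxa[bad]))
    }
    out[, cd] <- aa
  }
  cs <- sm$charsets
  cs$end <- cs$end %/% 3L
  cs$start <- (cs$start - 1L) %/% 3L + 1L
  supermatrix(stats::setNames(apply(out, 1, paste, collapse = ""), sm$taxa),
              cs, "amino-acid")
}

#' Build the five standard phylogenetic datasets
#'
#' From 13 PCG and 2 rRNA alignments: `P123` (all codon positions), `P12`
#' (first and second positions), `P123R` and `P12R` (with the rRNA blocks
#' appended), and `AA` (translated). Gene concatenation order is the canonical
#' order of the input list and recorded in the charsets.
#'
#' @param pcg_alignments list of PCG [mito_alignment]s.
#' @param rrna_alignments list of rRNA alignments (may be empty, in which case
#'   `P123R` equals `P123`).
#' @param taxon_order optional row order.
#' @return named list of [supermatrix] objects: P123, P12, P123R, P12R, AA.
#' @export
build_five_datasets <- function(pcg_alignments, rrna_alignments = list(),
                                taxon_order = NULL) {
  P123 <- concatenate_alignments(pcg_alignments, taxon_order)
  P12 <- codon_subset(P123, c(1, 2))
  withR <- function(base) {
    if (!length(rrna_alignments)) return(base)
    rr <- concatenate_alignments(rrna_alignments, base$taxa)
    cs <- rr$charsets
    cs$start <- cs$start + base$column_count
    cs$end <- cs$end + base$column_count
    supermatrix(stats::setNames(paste0(base$seqs, rr$seqs[base$taxa]), base$taxa),
                rbind(base$charsets, cs), "nucleotide")
  }
  list(P123 = P123, P12 = P12, P123R = withR(P123), P12R = withR(P12),
       AA = translate_matrix(P123))
}

#' Write a supermatrix with its partition scheme
#'
#' @param sm a [supermatrix].
#' @param path output file (alignment); partition files take `path` plus an
#'   extension.
#' @param format alignment format: `"fasta"`, `"phylip"` or `"nexus"` (DATA +
#'   SETS blocks).
#' @param partitions `"gene"` (one subset per charset), `"gene_codon"` (PCG
#'   charsets split by codon position, stride notation), or `"none"`.
#' @param dialect partition file dialect when `format` is not nexus:
#'   `"raxml"` plain text.
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(sm, path, format = c("fasta", "phylip", "nexus"),
                              partitions = c("gene", "gene_codon", "none"),
                              dialect = "raxml") {
  format <- match.arg(format)
  partitions <- match.arg(partitions)
  parts <- partition_lines(sm, partitions)
  if (format == "nexus") {
    con <- file(path, "w"); on.exit(close(con))
    dt <- if (sm$alphabet == "nucleotide") "DNA" else "PROTEIN"
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa),
                         sm$column_count),
                 sprintf("  FORMAT DATATYPE=%s GAP=- MISSING=?;", dt),
                 "  MATRIX"), con)
    writeLines(sprintf("    %s  %s", gsub("\\s", "_", sm$taxa), unname(sm$seqs)), con)
    writeLines(c("  ;", "END;"), con)
    if (partitions != "none") {
      writeLines("BEGIN SETS;", con)
      writeLines(sprintf("  CHARSET %s = %s;", parts$name, parts$range), con)
      writeLines(sprintf("  CHARPARTITION by_%s = %s;", partitions,
                         paste(sprintf("%s:%s", parts$name, parts$name),
                               collapse = ", ")), con)
      writeLines("END;", con)
    }
  } else {
    write_alignment(sm, path, format)
    if (partitions != "none") {
      dt <- if (sm$alphabet == "nucleotide") "DNA" else "PROT"
      writeLines(sprintf("%s, %s = %s", dt, parts$name, parts$range),
                 paste0(path, ".partitions"))
    }
  }
  invisible(path)
}

partition_lines <- function(sm, partitions) {
  if (partitions == "none") return(NULL)
  cs <- sm$charsets
  if (partitions == "gene" || sm$alphabet == "amino-acid") {
    data.frame(name = cs$label, range = sprintf("%d-%d", cs$start, cs$end),
               stringsAsFactors = FALSE)
  } else {
    rows <- list()
    for (r in seq_len(nrow(cs))) {
      if (cs$class[r] == "PCG") {
        for (p in 1:3)
          rows[[length(rows) + 1]] <- data.frame(
            name = sprintf("%s_pos%d", cs$label[r], p),
            range = sprintf("%d-%d\\3", cs$start[r] + p - 1L, cs$end[r]),
            stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          name = cs$label[r], range = sprintf("%d-%d", cs$start[r], cs$end[r]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
}

#' Strip all-gap and stop-codon columns from a PCG alignment
#'
#' A permissive utility for preparing matrices: removes columns that are gaps
#' in every taxon and codon columns containing a terminal stop in any taxon.
#' This is a simple cleaner, not a re-implementation of alignment-filtering
#' tools such as GBlocks.
#'
#' @param aln a PCG [mito_alignment].
#' @return a [mito_alignment].
#' @export
strip_gap_stop_columns <- function(aln) {
  code <- inv_mito_code()
  m <- aln_matrix(aln)
  all_gap_codon <- function(cols) all(m[, cols] == "-")
  keep <- rep(TRUE, ncol(m) %/% 3L)
  for (cd in seq_len(ncol(m) %/% 3L)) {
    cols <- (3L * cd - 2L):(3L * cd)
    cods <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    clean <- !grepl("[^ACGT]", cods)
    if (any(code[cods[clean]] == "*") || all_gap_codon(cols)) keep[cd] <- FALSE
  }
  cols_keep <- as.vector(vapply(which(keep), function(cd) (3L * cd - 2L):(3L * cd),
                                integer(3)))
  mito_alignment(matrix_to_seqs(m[, cols_keep, drop = FALSE]),
                 gene_name = aln$gene_name, feature_class = aln$feature_class)
}
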