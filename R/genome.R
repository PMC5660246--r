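# Internal data model: annotated circular mitogenome.
#
# Coordinates are 0-based half-open on the J strand throughout the package;
# conversion to/from GenBank 1-based inclusive happens only at I/O boundaries.
# A feature has one interval, or two when it wraps the origin of the circle.

#' Construct a gene feature
#'
#' @param gene canonical gene label (see [canonical_genes()]) or `"CR"`; other
#'   labels are allowed but flagged as unmappable by the GenBank reader.
#' @param strand `"J"` (majority strand) or `"N"` (minority; coding sense is
#'   the reverse complement of the J-strand slice).
#' @param intervals integer matrix with columns `start`, `end`: 0-based
#'   half-open J-strand coordinates; more than one row only for features that
#'   wrap the origin, in feature (5' to 3' on J) order.
#' @param class feature class, one of `"PCG","tRNA","rRNA","CR"`; inferred
#'   from `gene` when `NULL`.
#' @param flags character scalar of semicolon-separated flags (e.g.
#'   `"inferred"`, `"unmappable"`).
#' @return an object of class `gene_feature`.
#' @export
gene_feature <- function(gene, strand, intervals, class = NULL, flags = "") {
  if (is.vector(intervals)) intervals <- matrix(intervals, ncol = 2, byrow = TRUE)
  storage.mode(intervals) <- "integer"
  colnames(intervals) <- c("start", "end")
  stopifnot(length(gene) == 1L, strand %in% c("J", "N"),
            all(intervals[, 1] < intervals[, 2]), all(intervals[, 1] >= 0))
  if (is.null(class)) class <- feature_class_of(gene)
  if (is.na(class)) class <- "other"
  structure(list(gene = gene, class = class, strand = strand,
                 intervals = intervals,
                 length = sum(intervals[, 2] - intervals[, 1]),
                 flags = flags),
            class = "gene_feature")
}

#' @export
print.gene_feature <- function(x, ...) {
  iv <- paste(apply(x$intervals, 1, function(r) sprintf("[%d,%d)", r[1], r[2])),
              collapse = "+")
  cat(sprintf("<%s> %s strand %s %s (%d bp)%s\n", x$class, x$gene, x$strand,
              iv, x$length, if (nzchar(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' Construct an annotated mitochondrial genome
#'
#' @param sequence J-strand nucleotide sequence (character scalar over
#'   `{A,C,G,T,N}`; other ambiguity codes are mapped to N with a warning).
#' @param features list of [gene_feature] objects.
#' @param accession,taxon identifying text.
#' @param circular logical; mitogenomes are circular.
#' @return an object of class `mito_genome`: fields `accession`, `taxon`,
#'   `sequence`, `features` (sorted by start, stably), `is_circular`.
#' @export
mito_genome <- function(sequence, features, accession = "", taxon = "",
                        circular = TRUE) {
  sequence <- clean_dna(sequence, "genome sequence")
  n <- nchar(sequence)
  if (n == 0L) stop("empty genome sequence")
  for (f in features) {
    stopifnot(inherits(f, "gene_feature"))
    if (any(f$intervals[, 2] > n))
      stop(sprintf("feature %s extends beyond the %d bp sequence", f$gene, n))
  }
  canon <- vapply(features, function(f) f$gene, "")
  mappable <- canon %in% c(canonical_genes(), "CR")
  dup <- canon[mappable][duplicated(canon[mappable])]
  if (length(dup))
    stop("duplicate canonical gene name(s): ", paste(unique(dup), collapse = ", "))
  ord <- order(vapply(features, function(f) f$intervals[1, 1], 0L))
  structure(list(accession = accession, taxon = taxon, sequence = sequence,
                 features = features[ord], is_circular = circular),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cls <- vapply(x$features, function(f) f$class, "")
  cat(sprintf("mito_genome %s (%s): %d bp %s, %d features (%d PCG, %d tRNA, %d rRNA%s)\n",
              x$accession, x$taxon, nchar(x$sequence),
              if (x$is_circular) "circular" else "linear",
              length(x$features), sum(cls == "PCG"), sum(cls == "tRNA"),
              sum(cls == "rRNA"),
              if (any(cls == "CR")) ", CR" else ""))
  invisible(x)
}

# fetch a feature by canonical name, or NULL
get_feature <- function(genome, gene) {
  for (f in genome$features) if (f$gene == gene) return(f)
  NULL
}

#' Tabulate the features of a genome
#'
#' @param genome a [mito_genome].
#' @return data.frame with columns accession, gene, class, strand, start, end,
#'   length, wraps, flags (coordinates 0-based half-open; for origin-wrapping
#'   features start/end are those of the first/last interval).
#' @export
feature_table <- function(genome) {
  fs <- genome$features
  data.frame(
    accession = genome$accession,
    gene = vapply(fs, function(f) f$gene, ""),
    class = vapply(fs, function(f) f$class, ""),
    strand = vapply(fs, function(f) f$strand, ""),
    start = vapply(fs, function(f) f$intervals[1, 1], 0L),
    end = vapply(fs, function(f) f$intervals[nrow(f$intervals), 2], 0L),
    length = vapply(fs, function(f) f$length, 0L),
    wraps = vapply(fs, function(f) nrow(f$intervals) > 1L, TRUE),
    flags = vapply(fs, function(f) f$flags, ""),
    stringsAsFactors = FALSE)
}

#' Extract the coding-sense sequence of a feature
#'
#' Concatenates the feature's interval slices of the J strand in feature
#' order, then reverse-complements if the feature lies on the N strand.
#'
#' @param genome a [mito_genome].
#' @param feature a [gene_feature] belonging to `genome`, or a canonical gene
#'   name to look up.
#' @return character scalar; `nchar()` equals the feature length.
#' @export
extract_region <- function(genome, feature) {
  if (is.character(feature)) {
    f <- get_feature(genome, feature)
    if (is.null(f)) stop("no feature named ", feature)
    feature <- f
  }
  n <- nchar(genome$sequence)
  if (any(feature$intervals[, 2] > n)) stop("interval outside sequence")
  parts <- apply(feature$intervals, 1, function(r)
    substr(genome$sequence, r[1] + 1L, r[2]))
  out <- paste(parts, collapse = "")
  if (feature$strand == "N") out <- revcomp(out)
  out
}
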