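# Nucleotide composition, A+T content and strand-skew statistics.
#
# AT skew = (A - T) / (A + T), GC skew = (G - C) / (G + C): strand
# compositional asymmetry on the strand the sequence is given on. Skews are
# undefined (NA, flagged) when the denominator is zero.

#' Composition profile of a sequence region
#'
#' @param sequence nucleotide text over `{A,C,G,T,N}` (case-insensitive;
#'   gaps are ignored). N does not contribute to counts or `length_used`.
#' @param region_label label carried into the output.
#' @return object of class `composition_profile`: `counts` (named A/C/G/T),
#'   `length_used`, `at_percent`, `at_skew`, `gc_skew`, and logical
#'   `at_skew_defined` / `gc_skew_defined`.
#' @examples
#' composition_profile("AAAT")$at_skew   # (3-1)/4 = 0.5
#' @export
composition_profile <- function(sequence, region_label = "region") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("empty sequence for region ", region_label)
  chars <- s2c(toupper(sequence))
  chars <- chars[chars != "-"]
  counts <- vapply(.BASES, function(b) sum(chars == b), 0L)
  n <- sum(counts)
  if (n == 0L) stop("no unambiguous bases in region ", region_label)
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    region_label = region_label,
    counts = counts,
    length_used = n,
    at_percent = 100 * at / n,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_,
    at_skew_defined = at > 0,
    gc_skew_defined = gc > 0),
    class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("%s: %d bp, A+T %.1f%%, AT-skew %s, GC-skew %s\n",
              x$region_label, x$length_used, x$at_percent,
              if (x$at_skew_defined) sprintf("%.3f", x$at_skew) else "undefined",
              if (x$gc_skew_defined) sprintf("%.3f", x$gc_skew) else "undefined"))
  invisible(x)
}

#' @export
as.data.frame.composition_profile <- function(x, ...) {
  data.frame(region = x$region_label, length_used = x$length_used,
             A = x$counts[["A"]], C = x$counts[["C"]], G = x$counts[["G"]],
             T = x$counts[["T"]], at_percent = x$at_percent,
             at_skew = x$at_skew, gc_skew = x$gc_skew,
             stringsAsFactors = FALSE)
}

#' Per-region composition table for a genome
#'
#' Profiles the regions conventionally tabulated in mitogenome descriptions:
#' the whole genome, the 13 PCGs concatenated in genome order, rrnL, rrnS and
#' the control region. All slices are taken on the J strand by default
#' (including N-strand genes) for cross-taxon comparability; overlapping CDS
#' bases are counted once per gene, as annotated. Regions absent from the
#' annotation are omitted with a warning; an unannotated control region is
#' inferred with [locate_control_region()] when possible.
#'
#' @param genome a [mito_genome].
#' @param strand `"J"` (default) or `"coding"`: which strand per-gene slices
#'   are read on.
#' @return data.frame, one row per region (columns as
#'   [as.data.frame.composition_profile()]).
#' @export
region_profiles <- function(genome, strand = c("J", "coding")) {
  strand <- match.arg(strand)
  slice <- function(f) {
    if (strand == "coding") extract_region(genome, f)
    else {
      parts <- apply(f$intervals, 1, function(r)
        substr(genome$sequence, r[1] + 1L, r[2]))
      paste(parts, collapse = "")
    }
  }
  out <- list(composition_profile(genome$sequence, "whole"))
  pcgs <- Filter(function(f) f$class == "PCG", genome$features)
  if (length(pcgs)) {
    cat_pcg <- paste(vapply(pcgs, slice, ""), collapse = "")
    out <- c(out, list(composition_profile(cat_pcg, "PCGs")))
  } else warning(genome$accession, ": no PCGs annotated; PCG region omitted")
  for (g in c("rrnL", "rrnS")) {
    f <- get_feature(genome, g)
    if (is.null(f)) warning(genome$accession, ": ", g, " absent; region omitted")
    else out <- c(out, list(composition_profile(slice(f), g)))
  }
  cr <- get_feature(genome, "CR")
  if (is.null(cr)) cr <- tryCatch(locate_control_region(genome),
                                  error = function(e) NULL)
  if (is.null(cr)) warning(genome$accession, ": control region absent; omitted")
  else out <- c(out, list(composition_profile(slice(cr), "CR")))
  do.call(rbind, lapply(out, as.data.frame))
}

#' Pooled composition by codon position
#'
#' Pools columns congruent to positions 1, 2, 3 (gene-locally, so every
#' alignment must be a PCG matrix with columns divisible by 3) across all
#' genes and taxa; gaps and N are excluded.
#'
#' @param alignments list of PCG [mito_alignment] objects.
#' @return data.frame with rows `pos1`, `pos2`, `pos3`.
#' @export
codon_position_composition <- function(alignments) {
  if (!length(alignments)) stop("no alignments supplied")
  pooled <- c(pos1 = "", pos2 = "", pos3 = "")
  for (aln in alignments) {
    if (aln$feature_class != "PCG")
      stop("codon positions are only defined for PCG alignments")
    m <- aln_matrix(aln)
    pos <- rep(1:3, length.out = ncol(m))
    for (p in 1:3)
      pooled[p] <- paste0(pooled[p], paste(m[, pos == p], collapse = ""))
  }
  do.call(rbind, lapply(1:3, function(p)
    as.data.frame(composition_profile(pooled[p], paste0("pos", p)))))
}
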