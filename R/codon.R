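# Codon bookkeeping under the invertebrate mitochondrial genetic code
# (NCBI transl_table 5): codon extraction in frame, start/stop classification
# including incomplete stops, codon-usage counts and RSCU.

#' The invertebrate mitochondrial genetic code
#'
#' @return named character vector mapping the 64 DNA codons to one-letter
#'   amino acids, stops as `"*"` (NCBI transl_table 5; its only stops are
#'   TAA and TAG, leaving 62 sense codons).
#' @export
inv_mito_code <- function() {
  if (is.null(.mitocomp_env$code5))
    .mitocomp_env$code5 <- Biostrings::getGeneticCode("5")
  .mitocomp_env$code5
}

# split a coding-sense CDS string into complete codons (trailing partial kept
# separately)
split_codons <- function(cds) {
  n <- nchar(cds)
  k <- n %/% 3L
  list(codons = if (k > 0) substring(cds, 3 * seq_len(k) - 2, 3 * seq_len(k)) else character(),
       tail = if (n %% 3L) substr(cds, 3 * k + 1L, n) else "")
}

#' Codon usage over the protein-coding genes of a genome
#'
#' Codons are read in frame from each CDS coding-sense sequence; a trailing
#' incomplete codon (annotation arithmetic: CDS length mod 3 in {1,2}) is the
#' incomplete stop and is not counted; complete stop codons (TAA/TAG) at the
#' CDS end are tallied separately and excluded from `total_codons`. The start
#' codon is counted as its literal triplet. A CDS with an internal stop is
#' still counted, with a warning.
#'
#' @param genome a [mito_genome] with at least one PCG.
#' @param drop_first_codon drop each gene's start codon from the counts.
#' @param alphabet `"DNA"` (default) or `"RNA"` (codons reported with U).
#' @return object of class `codon_usage`: `counts` (named over 64 codons),
#'   `total_codons`, `stop_counts`, `taxon`, `genetic_code`.
#' @export
codon_usage <- function(genome, drop_first_codon = FALSE,
                        alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  code <- inv_mito_code()
  stops <- names(code)[code == "*"]
  pcgs <- Filter(function(f) f$class == "PCG", genome$features)
  if (!length(pcgs)) stop("genome has no annotated PCGs")
  counts <- stats::setNames(integer(64), names(code))
  stop_counts <- stats::setNames(integer(length(stops)), stops)
  for (f in pcgs) {
    cds <- extract_region(genome, f)
    sc <- split_codons(cds)
    codons <- sc$codons
    if (length(codons) && codons[length(codons)] %in% stops) {
      last <- codons[length(codons)]
      stop_counts[last] <- stop_counts[last] + 1L
      codons <- codons[-length(codons)]
    }
    if (drop_first_codon && length(codons)) codons <- codons[-1L]
    if (any(code[codons] == "*"))
      warning(sprintf("%s: internal stop codon(s) in %s", genome$accession, f$gene))
    ok <- codons %in% names(code) & !grepl("[^ACGT]", codons)
    tab <- table(codons[ok])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  if (alphabet == "RNA") names(counts) <- chartr("T", "U", names(counts))
  structure(list(taxon = if (nzchar(genome$taxon)) genome$taxon else genome$accession,
                 counts = counts, total_codons = sum(counts),
                 stop_counts = stop_counts, alphabet = alphabet,
                 genetic_code = "transl_table_5"),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("codon_usage (%s): %d codons over 13 PCGs, %s; missing codons: %s\n",
              x$taxon, x$total_codons, x$genetic_code,
              paste(names(x$counts)[x$counts == 0 &
                !(chartr("U", "T", names(x$counts)) %in%
                  names(inv_mito_code())[inv_mito_code() == "*"])],
                collapse = " ")))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its count divided by the mean count of its synonymous
#' family under the invertebrate mitochondrial code; 1 means no bias within
#' the family. Families with zero total usage get RSCU 0 for every member
#' (flagged in `zero_families`).
#'
#' @param usage a [codon_usage] object.
#' @return object of class `rscu_table`: `values` (codon -> RSCU),
#'   `amino_acid` (codon -> one-letter AA), `counts`, `family_sizes`,
#'   `zero_families`.
#' @export
rscu <- function(usage) {
  stopifnot(inherits(usage, "codon_usage"))
  if (usage$total_codons <= 0) stop("empty usage table")
  code <- inv_mito_code()
  counts <- usage$counts
  names(counts) <- chartr("U", "T", names(counts))
  sense <- names(code)[code != "*"]
  fam <- split(sense, code[sense])
  values <- stats::setNames(numeric(length(sense)), sense)
  zero <- character()
  for (aa in names(fam)) {
    members <- fam[[aa]]
    tot <- sum(counts[members])
    if (tot == 0) { values[members] <- 0; zero <- c(zero, aa); next }
    values[members] <- counts[members] / (tot / length(members))
  }
  if (usage$alphabet == "RNA") names(values) <- chartr("T", "U", names(values))
  structure(list(values = values,
                 amino_acid = stats::setNames(unname(code[sense]),
                                              names(values)),
                 counts = counts[sense],
                 family_sizes = vapply(fam, length, 0L),
                 zero_families = zero,
                 taxon = usage$taxon),
            class = "rscu_table")
}

#' @export
print.rscu_table <- function(x, ...) {
  cat(sprintf("rscu_table (%s): %d sense codons, %d amino-acid families\n",
              x$taxon, length(x$values), length(x$family_sizes)))
  invisible(x)
}

#' @export
as.data.frame.rscu_table <- function(x, ...) {
  data.frame(codon = names(x$values), amino_acid = unname(x$amino_acid),
             count = unname(x$counts), rscu = unname(x$values),
             stringsAsFactors = FALSE)
}

#' Start and stop codon classification for all PCGs
#'
#' Start codons are classed as ATN / TTG / GTG / other; stops are complete
#' (TAA or TAG) or incomplete (trailing T or TA, annotation length mod 3 in
#' {1,2}), completed to TAA by post-transcriptional polyadenylation.
#'
#' @param genome a [mito_genome].
#' @return data.frame with one row per PCG: gene, start_codon, start_class,
#'   stop_codon, stop_class; plus attribute `summary` (named counts of
#'   TAA / TAG / incomplete).
#' @export
start_stop_report <- function(genome) {
  code <- inv_mito_code()
  stops <- names(code)[code == "*"]
  pcgs <- Filter(function(f) f$class == "PCG", genome$features)
  if (!length(pcgs)) stop("genome has no annotated PCGs")
  rows <- lapply(pcgs, function(f) {
    cds <- extract_region(genome, f)
    if (nchar(cds) < 6L) stop("CDS of ", f$gene, " shorter than 6 nt")
    start <- substr(cds, 1, 3)
    start_class <- if (grepl("^AT[ACGT]$", start)) "ATN"
      else if (start == "TTG") "TTG" else if (start == "GTG") "GTG" else "other"
    rem <- nchar(cds) %% 3L
    if (rem == 0L) {
      last <- substr(cds, nchar(cds) - 2L, nchar(cds))
      stop_codon <- last
      stop_class <- if (last %in% stops) "complete" else "none"
    } else {
      stop_codon <- substr(cds, nchar(cds) - rem + 1L, nchar(cds))
      stop_class <- "incomplete"
    }
    data.frame(gene = f$gene, start_codon = start, start_class = start_class,
               stop_codon = stop_codon, stop_class = stop_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    TAA = sum(out$stop_codon == "TAA"),
    TAG = sum(out$stop_codon == "TAG"),
    incomplete = sum(out$stop_class == "incomplete"))
  out
}
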