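# Canonical mitochondrial gene names and the ancestral insect gene order.
#
# The 37-gene alphabet: 13 protein-coding genes, 22 tRNAs (trnL and trnS each
# come in two isoacceptor copies, disambiguated as trnL1/trnL2, trnS1/trnS2),
# two rRNAs; "CR" labels the control region (A+T-rich region), which is not a
# gene but participates in architecture bookkeeping.

.PCGS  <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
            "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")
.RRNAS <- c("rrnL", "rrnS")
.TRNAS <- paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                          "L1", "L2", "M", "N", "P", "Q", "R",
                          "S1", "S2", "T", "V", "W", "Y"))

#' Canonical mitochondrial gene labels
#'
#' @return character vector of the 37 canonical gene labels (13 PCGs, 22
#'   tRNAs, 2 rRNAs). The control region is labelled `"CR"` but is not a gene
#'   and is not included.
#' @export
canonical_genes <- function() c(.PCGS, .RRNAS, .TRNAS)

#' Feature class of a canonical label
#'
#' @param name character vector of canonical labels (may include `"CR"`).
#' @return character vector over `{"PCG","tRNA","rRNA","CR"}`; `NA` for
#'   unrecognized labels.
#' @export
feature_class_of <- function(name) {
  out <- rep(NA_character_, length(name))
  out[name %in% .PCGS]  <- "PCG"
  out[name %in% .RRNAS] <- "rRNA"
  out[name %in% .TRNAS] <- "tRNA"
  out[name == "CR"]     <- "CR"
  out
}

# synonym table cache
.mitocomp_env <- new.env(parent = emptyenv())

synonym_table <- function() {
  if (is.null(.mitocomp_env$synonyms)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocomp")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    key <- .norm_label(tab$synonym)
    keep <- !duplicated(key)
    .mitocomp_env$synonyms <- stats::setNames(tab$canonical[keep], key[keep])
  }
  .mitocomp_env$synonyms
}

# Normalize a raw gene/product label from an annotation to a lookup key:
# uppercase, strip punctuation/spaces ("tRNA-Leu (UUR)" -> "TRNALEUUUR").
.norm_label <- function(x) gsub("[^A-Z0-9]", "", toupper(x))

#' Map an annotated gene name to its canonical label
#'
#' Uses the bundled synonym table (`inst/extdata/gene_synonyms.tsv`, editable)
#' to map common GenBank spellings (COI, COX1, ND4L, 16S, l-rRNA, tRNA-Trp,
#' ...) to the canonical 37-gene alphabet. Leucine and serine tRNAs are
#' returned as the ambiguous placeholders `"trnL?"` / `"trnS?"` unless the
#' label itself carries the codon family (e.g. "tRNA-Leu(UUR)") or an
#' `anticodon` hint is supplied.
#'
#' @param raw character vector of raw labels (gene, product or note text).
#' @param anticodon optional character vector of anticodons (e.g. `"tag"`),
#'   used to disambiguate trnL1/trnL2 and trnS1/trnS2.
#' @return character vector of canonical labels; `NA` where unmappable.
#' @export
canonical_gene_name <- function(raw, anticodon = NULL) {
  syn <- synonym_table()
  key <- .norm_label(raw)
  out <- unname(syn[key])
  if (!is.null(anticodon)) {
    ac <- toupper(gsub("[^A-Za-z]", "", anticodon))
    ac[is.na(anticodon)] <- ""
    amb <- !is.na(out) & out %in% c("trnL?", "trnS?")
    out[amb & out == "trnL?" & ac == "TAG"] <- "trnL1"
    out[amb & out == "trnL?" & ac == "TAA"] <- "trnL2"
    out[amb & out == "trnS?" & ac %in% c("GCT", "TCT")] <- "trnS1"
    out[amb & out == "trnS?" & ac == "TGA"] <- "trnS2"
  }
  out
}

#' The ancestral insect mitochondrial gene order
#'
#' The 37-gene arrangement of *Drosophila yakuba*, the standard reference for
#' insect mitogenome rearrangement analysis, anchored at `trnI` and walking
#' the majority (J) strand 5' to 3'. Bundled as an editable TSV.
#'
#' @return a [gene_order] object with 37 entries.
#' @export
ancestral_gene_order <- function() {
  if (is.null(.mitocomp_env$ancestral)) {
    path <- system.file("extdata", "ancestral_order.tsv", package = "mitocomp")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    .mitocomp_env$ancestral <- new_gene_order(tab$gene, tab$strand,
                                              anchor = "trnI")
  }
  .mitocomp_env$ancestral
}

# default gene lengths (bp) for the synthetic generator: typical insect
# mitogenome values; PCG lengths include the complete stop codon
default_gene_lengths <- function() {
  c(nad2 = 978, cox1 = 1536, cox2 = 684, atp8 = 156, atp6 = 672, cox3 = 786,
    nad3 = 351, nad5 = 1716, nad4 = 1338, nad4l = 288, nad6 = 516, cob = 1137,
    nad1 = 924, rrnL = 1217, rrnS = 745,
    stats::setNames(rep(66L, length(.TRNAS)), .TRNAS))
}
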