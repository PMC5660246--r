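#!/usr/bin/env Rscript
# Build per-gene alignments from downloaded GenBank records for the
# saturation analysis: PCGs are aligned codon-wise (translate under the
# invertebrate mitochondrial code, align the proteins with mafft,
# back-translate), rRNAs are aligned as nucleotide with mafft. No column
# filtering is applied, so downstream numbers are approximate relative to
# pipelines that filter ambiguous blocks.
#
# Usage: Rscript scripts/build_alignments.R [accession_dir] [out_dir]
# Requires the mafft executable on PATH and records fetched by
# scripts/download_accessions.R.

suppressMessages(library(mitocomp))

args <- commandArgs(trailingOnly = TRUE)
acc_dir <- if (length(args) >= 1) args[1] else file.path("tests", "testthat", "accessions")
out_dir <- if (length(args) >= 2) args[2] else file.path(acc_dir, "alignments")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
if (Sys.which("mafft") == "") stop("mafft not found on PATH")

files <- list.files(acc_dir, pattern = "\\.gb$", full.names = TRUE)
if (!length(files)) stop("no GenBank records in ", acc_dir)
genomes <- lapply(files, function(f) suppressWarnings(read_genbank(f)))
names(genomes) <- vapply(genomes, `[[`, "", "accession")

code <- inv_mito_code()
stops <- names(code)[code == "*"]

strip_cds <- function(genome, gene) {
  f <- tryCatch(mitocomp:::get_feature(genome, gene), error = function(e) NULL)
  if (is.null(f)) return(NULL)
  cds <- extract_region(genome, f)
  cds <- substr(cds, 1, 3 * (nchar(cds) %/% 3))
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  if (last %in% stops) cds <- substr(cds, 1, nchar(cds) - 3)
  cds
}

translate5 <- function(cds) {
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- code[cods]
  aa[is.na(aa)] <- "X"
  aa[aa == "*"] <- "X"    # rare annotation slippage; keep the column
  paste(aa, collapse = "")
}

mafft <- function(infile) {
  outfile <- tempfile(fileext = ".fasta")
  system2("mafft", c("--auto", "--quiet", infile), stdout = outfile)
  outfile
}

read_fasta_plain <- function(path) {
  dn <- ape::read.FASTA(path, type = "AA")
  vapply(as.character(dn), function(x) toupper(paste(x, collapse = "")), "")
}

pcg_genes <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3", "nad1", "nad2",
               "nad3", "nad4", "nad4l", "nad5", "nad6")
for (gene in pcg_genes) {
  cds <- Filter(Negate(is.null), lapply(genomes, strip_cds, gene = gene))
  if (length(cds) < 4) { message("skipping ", gene, ": too few sequences"); next }
  aa <- vapply(cds, translate5, "")
  fa <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(aa)), aa)), fa)
  aligned <- read_fasta_plain(mafft(fa))
  # back-translate: gaps become codon gaps
  nt <- vapply(names(aligned), function(taxon) {
    cods <- substring(cds[[taxon]], seq(1, nchar(cds[[taxon]]), 3),
                      seq(3, nchar(cds[[taxon]]), 3))
    out <- character(nchar(aligned[[taxon]]))
    j <- 0
    for (i in seq_len(nchar(aligned[[taxon]]))) {
      ch <- substr(aligned[[taxon]], i, i)
      if (ch == "-") out[i] <- "---"
      else { j <- j + 1; out[i] <- cods[j] }
    }
    paste(out, collapse = "")
  }, "")
  aln <- mito_alignment(nt, gene_name = gene, feature_class = "PCG")
  write_alignment(aln, file.path(out_dir, paste0(gene, ".fasta")), "fasta")
  message("wrote ", gene, " (", aln$column_count, " columns, ",
          length(aln$taxa), " taxa)")
}

for (gene in c("rrnL", "rrnS")) {
  seqs <- Filter(Negate(is.null), lapply(genomes, function(g) {
    f <- mitocomp:::get_feature(g, gene)
    if (is.null(f)) NULL else extract_region(g, f)
  }))
  if (length(seqs) < 4) next
  fa <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unlist(seqs))), fa)
  dn <- ape::read.FASTA(mafft(fa))
  aligned <- vapply(as.character(dn), function(x) toupper(paste(x, collapse = "")), "")
  aln <- mito_alignment(aligned, gene_name = gene, feature_class = "rRNA")
  write_alignment(aln, file.path(out_dir, paste0(gene, ".fasta")), "fasta")
  message("wrote ", gene, " (", aln$column_count, " columns)")
}
message("alignments in ", normalizePath(out_dir))
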