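# Aligned-matrix I/O and the alignment container.

#' Construct an alignment object
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (names are taxa; alphabet `{A,C,G,T,N,-}`, case-insensitive).
#' @param gene_name gene label.
#' @param feature_class `"PCG"` or `"rRNA"`; PCG alignments must have a column
#'   count divisible by 3 (stop codons removed upstream).
#' @return object of class `mito_alignment` with fields `gene_name`,
#'   `feature_class`, `taxa`, `seqs`, `column_count`.
#' @export
mito_alignment <- function(seqs, gene_name = "", feature_class = c("PCG", "rRNA")) {
  feature_class <- match.arg(feature_class)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment rows must be named by taxon")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(sprintf("ragged alignment for %s: row lengths %s", gene_name,
                 paste(unique(lens), collapse = ", ")))
  if (feature_class == "PCG" && lens[1] %% 3L != 0L)
    stop(sprintf("PCG alignment %s has %d columns, not divisible by 3",
                 gene_name, lens[1]))
  seqs <- toupper(seqs)
  structure(list(gene_name = gene_name, feature_class = feature_class,
                 taxa = names(seqs), seqs = seqs,
                 column_count = unname(lens[1])),
            class = "mito_alignment")
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat(sprintf("mito_alignment %s (%s): %d taxa x %d columns\n",
              x$gene_name, x$feature_class, length(x$taxa), x$column_count))
  invisible(x)
}

# character matrix view (taxa x columns)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$taxa
  m
}

matrix_to_seqs <- function(m) {
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

#' Read an aligned matrix (FASTA or relaxed PHYLIP)
#'
#' Format is sniffed from the first non-blank character (`>` means FASTA).
#' Relaxed PHYLIP means whitespace-delimited taxon names of any length,
#' sequential layout.
#'
#' @param path input file.
#' @param gene_name gene label to attach.
#' @param feature_class `"PCG"` or `"rRNA"`.
#' @return a [mito_alignment]; ragged input, and PCG column counts not
#'   divisible by 3, are hard errors.
#' @export
read_alignment <- function(path, gene_name = "", feature_class = c("PCG", "rRNA")) {
  feature_class <- match.arg(feature_class)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (!length(first)) stop("empty alignment file: ", path)
  if (startsWith(trimws(first[1]), ">")) {
    dn <- ape::read.FASTA(path)
    seqs <- vapply(as.character(dn), function(ch) toupper(paste(ch, collapse = "")), "")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    if (length(hdr) < 2L || anyNA(hdr))
      stop("not FASTA and no PHYLIP header in ", path)
    ntax <- hdr[1]
    body <- lines[-1]
    toks <- strsplit(trimws(body), "\\s+")
    nm <- vapply(toks, `[[`, "", 1L)
    sq <- vapply(toks, function(t) paste(t[-1], collapse = ""), "")
    if (length(nm) != ntax) {         # wrapped sequential: fold extra lines
      nm <- nm[seq_len(ntax)]
      per <- split(seq_along(body), rep(seq_len(ntax), length.out = length(body)))
      sq <- vapply(seq_len(ntax), function(i) {
        rows <- body[per[[i]]]
        rows[1] <- sub("^\\s*\\S+\\s*", "", rows[1])
        gsub("\\s", "", paste(rows, collapse = ""))
      }, "")
    }
    seqs <- stats::setNames(toupper(sq), nm)
  }
  mito_alignment(seqs, gene_name = gene_name, feature_class = feature_class)
}

#' Write an alignment or supermatrix to FASTA or relaxed PHYLIP
#'
#' @param x a [mito_alignment] or `supermatrix`.
#' @param path output file.
#' @param format `"fasta"` or `"phylip"` (relaxed, sequential, one line per
#'   taxon).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- x$seqs
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_along(seqs))
      writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  } else {
    writeLines(sprintf("%d %d", length(seqs), nchar(seqs[[1]])), con)
    writeLines(sprintf("%s  %s", names(seqs), unname(seqs)), con)
  }
  invisible(path)
}
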