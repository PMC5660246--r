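# GenBank flat-file I/O.
#
# Reads LOCUS/FEATURES/ORIGIN records into the internal model, canonicalizing
# gene names through the bundled synonym table, converting 1-based inclusive
# coordinates to 0-based half-open, and folding join() locations that span the
# origin into multi-interval features. The writer emits the same dialect, so
# read -> write -> read is the identity on all model fields.

# ---- coordinate conversion (the only place the two conventions meet) ----

gb_to_internal <- function(start1, end1) cbind(start = start1 - 1L, end = end1)
internal_to_gb <- function(intervals) cbind(start1 = intervals[, 1] + 1L,
                                            end1 = intervals[, 2])

# parse a GenBank location string -> list(strand, intervals 0-based half-open)
parse_location <- function(loc) {
  loc <- gsub("[ <>]", "", loc)
  strand <- "J"
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  inner_comp <- grepl("^complement\\(", parts)
  if (any(inner_comp)) {           # join(complement(..),..): segments in coding order
    strand <- "N"
    parts <- sub("^complement\\((.*)\\)$", "\\1", parts)
    parts <- rev(parts)            # restore J-strand order
  }
  iv <- t(vapply(parts, function(p) {
    xs <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(xs) == 1L) xs <- c(xs, xs)
    xs
  }, integer(2)))
  list(strand = strand, intervals = gb_to_internal(iv[, 1], iv[, 2]))
}

format_location <- function(feature) {
  gb <- internal_to_gb(feature$intervals)
  segs <- apply(gb, 1, function(r)
    if (r[1] == r[2]) as.character(r[1]) else sprintf("%d..%d", r[1], r[2]))
  loc <- if (length(segs) > 1L) sprintf("join(%s)", paste(segs, collapse = ",")) else segs
  if (feature$strand == "N") loc <- sprintf("complement(%s)", loc)
  loc
}

# ---- reader ----

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Annotated genes (CDS, tRNA, rRNA, D-loop/misc_feature) are mapped to
#' canonical names via the bundled synonym table; trnL1/trnL2 and trnS1/trnS2
#' are disambiguated by anticodon qualifier when present, otherwise by
#' position relative to rrnL / nad3 (flagged `"inferred"`). Features whose
#' names cannot be mapped are retained with an `"unmappable"` flag and a
#' warning. `gene` and `source` feature keys are skipped (redundant with the
#' typed features).
#'
#' @param path path to a GenBank flat file.
#' @return a [mito_genome].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  circular <- any(tolower(toks) == "circular")
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) strsplit(trimws(acc_line[1]), "\\s+")[[1]][2] else toks[2]
  if (is.na(accession)) accession <- toks[2]
  org_line <- grep("^\\s{2}ORGANISM", lines, value = TRUE)
  taxon <- if (length(org_line)) trimws(sub("^\\s*ORGANISM\\s*", "", org_line[1])) else ""
  if (!nzchar(taxon)) {
    def <- grep("^DEFINITION", lines, value = TRUE)
    if (length(def)) taxon <- trimws(sub("^DEFINITION\\s*", "", def[1]))
  }

  feat_start <- grep("^FEATURES", lines)[1]
  origin <- grep("^ORIGIN", lines)[1]
  if (is.na(origin)) stop("no ORIGIN block in ", path)
  seq_lines <- lines[(origin + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("empty sequence in ", path)

  feats <- list()
  if (!is.na(feat_start)) {
    block <- lines[(feat_start + 1):(origin - 1)]
    cur <- NULL
    flush <- function(cur, feats) { if (!is.null(cur)) feats[[length(feats) + 1]] <- cur; feats }
    for (ln in block) {
      if (grepl("^\\s{5}\\S", ln) && !grepl("^\\s{6,}", ln)) {   # new feature key
        feats <- flush(cur, feats)
        key <- sub("^\\s+(\\S+).*$", "\\1", ln)
        loc <- trimws(substring(ln, 22))
        cur <- list(key = key, loc = loc, quals = character())
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
        else cur$loc <- paste0(cur$loc, txt)    # wrapped location
      }
    }
    feats <- flush(cur, feats)
  }

  qual_value <- function(quals, name) {
    hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
  }

  features <- list()
  n_unmappable <- 0L
  for (ft in feats) {
    if (ft$key %in% c("source", "gene")) next
    pl <- parse_location(ft$loc)
    raw <- qual_value(ft$quals, "gene")
    if (is.na(raw)) raw <- qual_value(ft$quals, "product")
    if (is.na(raw)) raw <- qual_value(ft$quals, "note")
    ac <- qual_value(ft$quals, "anticodon")
    if (!is.na(ac) && grepl("seq:", ac)) ac <- sub(".*seq:([A-Za-z]+).*", "\\1", ac)
    note <- qual_value(ft$quals, "note")
    if (is.na(ac) && !is.na(note) && grepl("anticodon", note, ignore.case = TRUE))
      ac <- sub(".*anticodon[:= ]*([A-Za-z]{3}).*", "\\1", note, ignore.case = TRUE)
    canon <- if (!is.na(raw)) canonical_gene_name(raw, ac) else NA_character_
    # also try the product line for family-qualified tRNA names
    if ((is.na(canon) || canon %in% c("trnL?", "trnS?"))) {
      prod <- qual_value(ft$quals, "product")
      if (!is.na(prod)) {
        alt <- canonical_gene_name(prod, ac)
        if (!is.na(alt) && !(alt %in% c("trnL?", "trnS?"))) canon <- alt
        else if (is.na(canon)) canon <- alt
      }
    }
    cls <- switch(ft$key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                  "D-loop" = "CR", misc_feature = NA_character_, NA_character_)
    flags <- ""
    if (is.na(canon)) {
      if (identical(cls, "CR")) canon <- "CR"
      else { canon <- if (is.na(raw)) ft$key else raw; flags <- "unmappable"
             n_unmappable <- n_unmappable + 1L }
    } else if (canon == "CR" && is.na(cls)) cls <- "CR"
    if (is.na(cls)) cls <- feature_class_of(canon)
    if (is.na(cls)) cls <- "other"
    features[[length(features) + 1]] <-
      gene_feature(canon, pl$strand, pl$intervals, class = cls, flags = flags)
  }
  if (n_unmappable > 0L)
    warning(sprintf("%s: %d feature(s) could not be mapped to canonical names",
                    accession, n_unmappable))
  features <- disambiguate_ls(features, nchar(sequence))
  mito_genome(sequence, features, accession = accession, taxon = taxon,
              circular = circular)
}

# positional fallback for leucine/serine tRNA copies left ambiguous
disambiguate_ls <- function(features, genome_len) {
  starts <- vapply(features, function(f) f$intervals[1, 1], 0L)
  names_ <- vapply(features, function(f) f$gene, "")
  circ_dist <- function(a, b) { d <- abs(a - b); pmin(d, genome_len - d) }
  anchor_pos <- function(g) { i <- match(g, names_); if (is.na(i)) NA_integer_ else starts[i] }
  fix <- function(placeholder, near_gene, name_near, name_far) {
    idx <- which(names_ == placeholder)
    if (!length(idx)) return()
    ap <- anchor_pos(near_gene)
    taken <- names_ %in% c(name_near, name_far)
    if (is.na(ap)) {  # no anchor: assign arbitrarily but deterministically
      lab <- setdiff(c(name_near, name_far), names_[taken])
      for (j in seq_along(idx)) {
        features[[idx[j]]]$gene <<- lab[min(j, length(lab))]
        features[[idx[j]]]$flags <<- "inferred"
      }
      return()
    }
    d <- circ_dist(starts[idx], ap)
    ord <- idx[order(d)]
    lab <- c(name_near, name_far)
    for (j in seq_along(ord)) {
      features[[ord[j]]]$gene <<- lab[min(j, 2L)]
      features[[ord[j]]]$flags <<- "inferred"
    }
  }
  fix("trnL?", "rrnL", "trnL1", "trnL2")
  fix("trnS?", "nad3", "trnS1", "trnS2")
  features
}

# ---- writer ----

#' Write a genome as a GenBank flat file
#'
#' Emits the dialect [read_genbank()] parses: canonical names in `/gene`,
#' PCGs as CDS, the control region as D-loop, N-strand features as
#' `complement(...)`, origin-wrapping features as `join(...)`.
#'
#' @param genome a [mito_genome].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %s %d bp    DNA     %s INV 01-JAN-2000",
    genome$accession, n, if (genome$is_circular) "circular" else "linear")
  w("DEFINITION  %s mitochondrion, complete genome.", genome$taxon)
  w("ACCESSION   %s", genome$accession)
  w("SOURCE      %s", genome$taxon)
  w("  ORGANISM  %s", genome$taxon)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", n)
  w("                     /organism=\"%s\"", genome$taxon)
  for (f in genome$features) {
    key <- switch(f$class, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop", "misc_feature")
    w("     %-16s%s", key, format_location(f))
    w("                     /gene=\"%s\"", f$gene)
    if (f$class == "PCG") w("                     /transl_table=5")
  }
  w("ORIGIN")
  seq <- tolower(genome$sequence)
  for (i in seq(1L, n, by = 60L)) {
    chunk <- substr(seq, i, min(i + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    w("%9d %s", i, paste(groups, collapse = " "))
  }
  w("//")
  invisible(path)
}

#' Write the feature table of a genome as TSV
#'
#' @param genome a [mito_genome].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  utils::write.table(feature_table(genome), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
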