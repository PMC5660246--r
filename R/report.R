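# Orchestration: run the full comparative analysis over a set of genomes and
# emit plain-TSV summary tables plus a JSON manifest. Reports are
# deterministic for fixed inputs and configuration (timestamps live only in
# the manifest).

#' Run the comparative mitogenome analysis
#'
#' For every readable genome: per-region composition (lengths, A+T%, skews),
#' junction totals, control-region length and tandem repeats, and the
#' gene-order comparison against the ancestral insect arrangement. Every cell
#' equals the value returned by the corresponding analysis function called
#' directly. Failures on individual genomes are logged as warnings and the
#' run continues.
#'
#' @param inputs character vector of GenBank file paths, a directory
#'   containing them, or a list of [mito_genome] objects.
#' @param out_dir output directory; created if needed. TSV tables
#'   (`composition.tsv`, `junctions.tsv`, `gene_order.tsv`, `repeats.tsv`,
#'   `overlaps_spacers.tsv`) and `manifest.json` are written there; pass
#'   `NULL` to skip writing.
#' @param reference gene order compared against (default ancestral insect).
#' @param repeat_args list of arguments for [find_tandem_repeats()].
#' @return invisibly, a list of the report data.frames.
#' @export
run_compare <- function(inputs, out_dir = NULL,
                        reference = ancestral_gene_order(),
                        repeat_args = list()) {
  files <- NULL
  if (is.character(inputs)) {
    files <- inputs
    if (length(inputs) == 1L && dir.exists(inputs))
      files <- list.files(inputs, pattern = "\\.(gb|gbk|genbank)$",
                          full.names = TRUE)
    if (!length(files)) stop("no genomes found in input")
    genomes <- list()
    for (f in sort(files)) {
      g <- tryCatch(read_genbank(f), error = function(e) {
        warning("skipping ", f, ": ", conditionMessage(e)); NULL })
      if (!is.null(g)) genomes[[length(genomes) + 1]] <- g
    }
  } else genomes <- inputs
  if (!length(genomes)) stop("no readable genomes")

  comp <- list(); junc <- list(); ords <- list(); reps <- list(); ovsp <- list()
  for (g in genomes) {
    acc <- g$accession
    res <- tryCatch({
      rp <- region_profiles(g)
      wide <- data.frame(accession = acc, taxon = g$taxon,
                         stringsAsFactors = FALSE)
      for (r in seq_len(nrow(rp))) {
        wide[[paste0(rp$region[r], "_length")]] <- rp$length_used[r]
        wide[[paste0(rp$region[r], "_at_percent")]] <- round(rp$at_percent[r], 1)
        wide[[paste0(rp$region[r], "_at_skew")]] <- round(rp$at_skew[r], 3)
        wide[[paste0(rp$region[r], "_gc_skew")]] <- round(rp$gc_skew[r], 3)
      }
      jr <- junctions(g)
      jrow <- data.frame(accession = acc, t(jr$totals),
                         cr_length = if (is.null(jr$cr)) NA_integer_ else jr$cr$length,
                         stringsAsFactors = FALSE)
      ov <- jr$overlaps; sp <- jr$spacers
      ovdf <- if (nrow(ov)) cbind(accession = acc, kind = "overlap", ov) else NULL
      spdf <- if (nrow(sp)) cbind(accession = acc, kind = "spacer", sp) else NULL
      rr <- compare_orders(gene_order(g), reference)
      orow <- data.frame(accession = acc,
                         breakpoint_count = rr$breakpoint_count,
                         rearranged = paste(vapply(rr$differing_blocks, function(b)
                           paste(b$observed, collapse = "-"), ""), collapse = "; "),
                         stringsAsFactors = FALSE)
      cr <- tryCatch(locate_control_region(g), error = function(e) NULL)
      rdf <- NULL
      if (!is.null(cr)) {
        tr <- do.call(find_tandem_repeats,
                      c(list(extract_region(g, cr)), repeat_args))
        if (nrow(tr)) rdf <- cbind(accession = acc,
                                   tr[, c("start", "period", "copies", "identity")])
      }
      list(wide = wide, jrow = jrow, orow = orow, rdf = rdf,
           ovsp = rbind(ovdf, spdf))
    }, error = function(e) {
      warning("analysis failed for ", acc, ": ", conditionMessage(e)); NULL })
    if (is.null(res)) next
    comp[[length(comp) + 1]] <- res$wide
    junc[[length(junc) + 1]] <- res$jrow
    ords[[length(ords) + 1]] <- res$orow
    if (!is.null(res$rdf)) reps[[length(reps) + 1]] <- res$rdf
    if (!is.null(res$ovsp)) ovsp[[length(ovsp) + 1]] <- res$ovsp
  }
  rbind_fill <- function(lst) {
    if (!length(lst)) return(data.frame())
    cols <- Reduce(union, lapply(lst, names))
    do.call(rbind, lapply(lst, function(d) {
      for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
      d[, cols, drop = FALSE]
    }))
  }
  tables <- list(composition = rbind_fill(comp), junctions = rbind_fill(junc),
                 gene_order = rbind_fill(ords), repeats = rbind_fill(reps),
                 overlaps_spacers = rbind_fill(ovsp))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      utils::write.table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    manifest <- list(
      package = "mitocomp",
      version = as.character(utils::packageVersion("mitocomp")),
      created = format(Sys.time(), tz = "UTC"),
      n_genomes = length(genomes),
      inputs = if (is.null(files)) "in-memory genomes" else files,
      input_md5 = if (is.null(files)) NULL else as.list(tools::md5sum(sort(files))),
      repeat_args = repeat_args)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(tables)
}

#' One-line linear gene map of a genome
#'
#' Renders the gene order anchored at trnI as a text map: N-strand genes are
#' prefixed `-`, and genes inside blocks that differ from the reference
#' arrangement are bracketed.
#'
#' @param genome a [mito_genome].
#' @param reference gene order to highlight rearrangements against.
#' @return character scalar.
#' @export
linear_map <- function(genome, reference = ancestral_gene_order()) {
  ord <- tryCatch(gene_order(genome, "trnI"), error = function(e) {
    warning("trnI absent; anchoring at first annotated gene")
    gene_order(genome, anchor = {
      fs <- Filter(function(f) f$class %in% c("PCG", "tRNA", "rRNA"),
                   genome$features)
      fs[[1]]$gene
    })
  })
  rr <- tryCatch(compare_orders(ord, reference), error = function(e) NULL)
  moved <- unique(unlist(lapply(rr$differing_blocks, `[[`, "observed")))
  lab <- ifelse(ord$entries$strand == "N", paste0("-", ord$entries$gene),
                ord$entries$gene)
  lab <- ifelse(ord$entries$gene %in% moved, paste0("[", lab, "]"), lab)
  paste(lab, collapse = " ")
}
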