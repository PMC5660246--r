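#!/usr/bin/env Rscript
# Fetch the GenBank flat files of the study accessions from NCBI E-utilities
# into tests/testthat/accessions/ (or a directory given as the first
# argument). Requires network access; the package itself never downloads.

accessions <- c(
  "KX786285",  # Maiestas dorsalis
  "KY129954",  # Japananus hyalinus
  "JF801955", "KX495488", "KP316404", "AY875213", "KJ815009", "KR024406",
  "KP749836", "KR349344", "KT827824",  # other Membracoidea
  "KM000130", "JX844628")              # outgroups

args <- commandArgs(trailingOnly = TRUE)
dest <- if (length(args) >= 1) args[1] else file.path("tests", "testthat", "accessions")
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nucleotide&rettype=gb&retmode=text&id=")
for (acc in accessions) {
  out <- file.path(dest, paste0(acc, ".gb"))
  if (file.exists(out)) { message(acc, " already present"); next }
  message("fetching ", acc)
  ok <- tryCatch({
    utils::download.file(paste0(base, acc), out, quiet = TRUE, mode = "wb")
    TRUE
  }, error = function(e) { message("  failed: ", conditionMessage(e)); FALSE })
  if (ok && file.size(out) < 1000) { message("  truncated, removing"); unlink(out) }
  Sys.sleep(0.4)   # E-utilities rate limit
}
message("done; records in ", normalizePath(dest))
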