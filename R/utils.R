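# internal sequence / RNG helpers

.BASES <- c("A", "C", "G", "T")

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
c2s <- function(x) paste(x, collapse = "")

#' Reverse complement of a nucleotide string
#'
#' Complements over the alphabet {A,C,G,T,N} (gaps `-` are preserved) and
#' reverses. Input and output are plain character scalars on the DNA alphabet.
#'
#' @param x character scalar, nucleotide sequence.
#' @return character scalar, the reverse complement.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  c2s(rev(s2c(chartr("ACGTNacgtn", "TGCANtgcan", x))))
}

# run code with a local RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# uppercase and map IUPAC ambiguity codes other than N to N (with a warning)
clean_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  chars <- s2c(x)
  bad <- !(chars %in% c(.BASES, "N", "-"))
  if (any(bad)) {
    warning(sprintf("%s: %d ambiguity code(s) mapped to N", what, sum(bad)))
    chars[bad] <- "N"
    x <- c2s(chars)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
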