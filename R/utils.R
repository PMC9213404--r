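# Small shared helpers: sequence primitives, seeded RNG scoping, validation.

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_REGEX <- "^[ACGTRYSWKMBDHVN]*$"

#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences (IUPAC alphabet).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Random DNA string with a given GC fraction.
random_dna <- function(n, gc = 0.41) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Fraction of G+C in a sequence.
gc_fraction <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  mean(b %in% c("G", "C"))
}

check_dna <- function(x, what = "sequence") {
  bad <- !grepl(IUPAC_REGEX, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-IUPAC characters (first offender: record %d)",
                 what, which(bad)[1]), call. = FALSE)
  }
  invisible(x)
}

# substr() over vectors of (start, end) on a single subject string.
substr_many <- function(seq, start, end) {
  substring(seq, start, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
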