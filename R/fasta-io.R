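# FASTA / FASTQ readers and writers.
#
# Sequence sets are represented throughout the package as named character
# vectors (upper-case IUPAC alphabet). Biostrings does the on-disk parsing;
# validation on top enforces the package's contracts (unique names, IUPAC
# alphabet, upper-casing).

#' Read a FASTA file into a named character vector
#'
#' Lower-case bases are upper-cased; IUPAC ambiguity codes are accepted.
#' Duplicate record names and non-IUPAC characters are rejected.
#'
#' @param path path to a FASTA file. An empty file yields an empty set.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(as.character(set))
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  check_dna(seqs, paste0("FASTA ", basename(path)))
  stats::setNames(seqs, nm)
}

#' Write a named sequence set to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param wrap line width for sequence wrapping.
#' @export
write_fasta <- function(seqs, path, wrap = 60) {
  stopifnot(is.character(seqs))
  if (length(seqs) > 0 && (is.null(names(seqs)) || any(names(seqs) == "")))
    stop("all sequences must be named", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) > 0) {
      starts <- seq(1L, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Write paired reads to a pair of FASTQ files
#'
#' Mate 1 goes to `<prefix>_1.fastq`, mate 2 to `<prefix>_2.fastq`, with
#' `/1` and `/2` name suffixes. Qualities are constant (the simulator does
#' not model quality scores).
#'
#' @param names read-pair names (without mate suffix).
#' @param seq1,seq2 mate sequences as sequenced (5'->3').
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(names, seq1, seq2, prefix) {
  stopifnot(length(names) == length(seq1), length(seq1) == length(seq2))
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    s <- if (m == 1) seq1 else seq2
    qual <- vapply(nchar(s), function(n) strrep("I", n), character(1))
    out <- as.vector(rbind(paste0("@", names, "/", m), s, "+", qual))
    writeLines(out, paths[m])
  }
  invisible(paths)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fastq")
  stats::setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}
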