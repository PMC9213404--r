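# Plain-text SAM parsing and writing.
#
# The pipeline's native alignment dialect is text SAM (BAM input is expected
# to be converted externally, e.g. `samtools view -h`). Reads are held as a
# data.frame with decoded flag bits and CIGAR-derived clip/span columns,
# which is what every downstream stage consumes.

SAM_FLAG_BITS <- c(
  paired = 1L, proper = 2L, unmapped = 4L, munmapped = 8L,
  rev = 16L, mrev = 32L, first = 64L, second = 128L
)

#' Decode SAM flag integers into logical columns
#'
#' @param flag integer vector of SAM FLAG values.
#' @return data.frame with one logical column per decoded bit
#'   (paired, proper, unmapped, munmapped, rev, mrev, first, second).
#' @export
sam_flags <- function(flag) {
  out <- lapply(SAM_FLAG_BITS, function(b) bitwAnd(as.integer(flag), b) > 0L)
  as.data.frame(out)
}

# Parse CIGAR strings. Returns a data.frame aligned with `cigars` containing
# qlen (query-consuming length), rlen (reference-consuming length),
# clip_left, clip_right (soft clips). Parsing is done once per unique CIGAR.
cigar_info <- function(cigars) {
  u <- unique(cigars)
  parse1 <- function(cg) {
    if (cg == "*") return(c(qlen = NA_integer_, rlen = NA_integer_,
                            clip_left = 0L, clip_right = 0L))
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHPX=]", cg))[[1]]
    if (length(toks) == 0 || nchar(paste(toks, collapse = "")) != nchar(cg))
      stop("malformed CIGAR: ", cg, call. = FALSE)
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    qlen <- sum(n[op %in% c("M", "I", "S", "=", "X")])
    rlen <- sum(n[op %in% c("M", "D", "N", "=", "X")])
    cl <- if (op[1] == "S") n[1] else 0L
    cr <- if (length(op) > 1 && op[length(op)] == "S") n[length(n)] else 0L
    if (length(op) == 1 && op[1] == "S") cr <- 0L
    c(qlen = qlen, rlen = rlen, clip_left = cl, clip_right = cr)
  }
  tab <- t(vapply(u, parse1, c(qlen = 0L, rlen = 0L, clip_left = 0L, clip_right = 0L)))
  tab <- tab[match(cigars, u), , drop = FALSE]
  rownames(tab) <- NULL
  as.data.frame(tab)
}

#' Read a text SAM file
#'
#' Decodes flags, derives soft-clip lengths per side and the reference span,
#' and validates that query-consuming CIGAR lengths sum to the sequence
#' length (with the offending line number reported on failure).
#'
#' @param path path to a SAM file.
#' @return data.frame of reads (one row per record) with columns
#'   qname, flag, chrom, pos, mapq, cigar, mchrom, mpos, tlen, seq plus
#'   decoded flag columns and clip_left/clip_right/end. The `@SQ` reference
#'   names/lengths are attached as attribute `sq`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  body_line_no <- which(!is_hdr)
  sq <- parse_sq_header(hdr)
  if (length(body) == 0) {
    out <- empty_read_frame()
    attr(out, "sq") <- sq
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11)) {
    stop(sprintf("SAM line %d has %d fields (need >= 11)",
                 body_line_no[which(nf < 11)[1]], min(nf)), call. = FALSE)
  }
  m <- matrix(unlist(lapply(f, `[`, 1:11)), ncol = 11, byrow = TRUE)
  reads <- data.frame(
    qname = m[, 1], flag = as.integer(m[, 2]), chrom = m[, 3],
    pos = as.integer(m[, 4]), mapq = as.integer(m[, 5]), cigar = m[, 6],
    mchrom = m[, 7], mpos = as.integer(m[, 8]), tlen = as.integer(m[, 9]),
    seq = toupper(m[, 10]), stringsAsFactors = FALSE
  )
  reads <- cbind(reads, sam_flags(reads$flag))
  ci <- cigar_info(reads$cigar)
  has_seq <- reads$seq != "*"
  bad <- !reads$unmapped & has_seq & !is.na(ci$qlen) & ci$qlen != nchar(reads$seq)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("SAM line %d: CIGAR consumes %d query bases but SEQ has %d",
                 body_line_no[i], ci$qlen[i], nchar(reads$seq[i])), call. = FALSE)
  }
  reads$clip_left <- ifelse(reads$unmapped, 0L, ci$clip_left)
  reads$clip_right <- ifelse(reads$unmapped, 0L, ci$clip_right)
  reads$end <- ifelse(reads$unmapped, NA_integer_, reads$pos + ci$rlen - 1L)
  # unmapped reads make no coordinate claims
  reads$pos[reads$unmapped] <- NA_integer_
  attr(reads, "sq") <- sq
  reads
}

parse_sq_header <- function(hdr) {
  sq_lines <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq_lines) == 0)
    return(data.frame(name = character(0), length = integer(0)))
  nm <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq_lines)
  ln <- as.integer(sub("^.*\tLN:([0-9]+).*$", "\\1", sq_lines))
  data.frame(name = nm, length = ln, stringsAsFactors = FALSE)
}

empty_read_frame <- function() {
  out <- data.frame(
    qname = character(0), flag = integer(0), chrom = character(0),
    pos = integer(0), mapq = integer(0), cigar = character(0),
    mchrom = character(0), mpos = integer(0), tlen = integer(0),
    seq = character(0)
  )
  out <- cbind(out, sam_flags(integer(0)))
  out$clip_left <- integer(0); out$clip_right <- integer(0); out$end <- integer(0)
  out
}

#' Write reads to a text SAM file
#'
#' @param reads data.frame as produced by [read_sam()] or the simulator
#'   (columns qname, flag, chrom, pos, mapq, cigar, mchrom, mpos, tlen, seq).
#' @param path output path.
#' @param sq data.frame with columns name, length for the `@SQ` header; taken
#'   from `attr(reads, "sq")` when missing.
#' @export
write_sam <- function(reads, path, sq = NULL) {
  sq <- sq %||% attr(reads, "sq")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           if (!is.null(sq) && nrow(sq) > 0)
             sprintf("@SQ\tSN:%s\tLN:%d", sq$name, sq$length))
  pos <- ifelse(is.na(reads$pos), 0L, reads$pos)
  body <- paste(reads$qname, reads$flag, reads$chrom, pos, reads$mapq,
                reads$cigar, reads$mchrom, reads$mpos, reads$tlen,
                reads$seq, "*", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Split a read frame into mate pairs by name. Returns a list with the frame
# reordered so mates are adjacent and an index (pair id per row). Errors on
# orphan reads.
pair_reads <- function(reads) {
  ord <- order(reads$qname, reads$second)
  reads <- reads[ord, , drop = FALSE]
  cnt <- table(reads$qname)
  if (any(cnt != 2)) {
    bad <- names(cnt)[cnt != 2][1]
    stop("read without its mate: ", bad, call. = FALSE)
  }
  reads$pair_id <- rep(seq_len(nrow(reads) / 2L), each = 2L)
  reads
}
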