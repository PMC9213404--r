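# Discovery stage: read-pair classification and anchor evidence collection.
#
# A pair supports a non-reference insertion when its anchored mate localizes
# the locus while the other mate (or the clipped read tail) matches the LTR
# element library. Local alignment is Smith-Waterman with affine gaps
# (Biostrings' C implementation behind the package's scoring surface).

#' Discovery stage parameters
#'
#' @param insert_mean,insert_sd expected template (insert) size in bp.
#' @param proper_span_k multiplier: pairs within
#'   `insert_mean +/- k * insert_sd` are proper.
#' @param min_identity minimum alignment identity for library evidence.
#' @param min_hit_length minimum alignment length for mate hits in bp.
#' @param min_clip minimum soft-clip (and clip-hit alignment) length in bp.
#' @param min_mapq anchors below this mapping quality are discarded.
#' @return object of class `discovery_params`.
#' @export
discovery_params <- function(insert_mean = 350, insert_sd = 50,
                             proper_span_k = 3, min_identity = 0.80,
                             min_hit_length = 36L, min_clip = 10L,
                             min_mapq = 20L) {
  vals <- c(insert_mean, insert_sd, proper_span_k, min_identity,
            min_hit_length, min_clip, min_mapq)
  if (any(vals <= 0)) stop("all discovery parameters must be positive",
                           call. = FALSE)
  structure(list(insert_mean = insert_mean, insert_sd = insert_sd,
                 proper_span_k = proper_span_k, min_identity = min_identity,
                 min_hit_length = as.integer(min_hit_length),
                 min_clip = as.integer(min_clip),
                 min_mapq = as.integer(min_mapq)),
            class = "discovery_params")
}

default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = 2, gap_ext = 1)
}

sub_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D",
               "H", "V", "N")
  m <- matrix(scoring$mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch  # N never matches
  m
}

#' Best local alignment of a query against a target
#'
#' Smith-Waterman semantics with affine gaps (default scoring: match +1,
#' mismatch -1, gap of length k costs 2 + k). Identity is matches over
#' alignment columns. When no positive-scoring cell exists, an empty
#' alignment (score 0, length 0) is reported.
#'
#' @param query,target DNA sequences (character).
#' @param scoring list with match, mismatch, gap_open, gap_ext (penalties
#'   positive).
#' @return list with score, identity, length, q_start, q_end, t_start,
#'   t_end.
#' @export
local_align <- function(query, target, scoring = default_scoring()) {
  if (!nzchar(query) || !nzchar(target))
    stop("sequences must be non-empty", call. = FALSE)
  df <- local_align_many(query, target, scoring)
  as.list(df[1, ])
}

# Vectorized local alignment: many queries against one target.
# Returns a data.frame with one row per query.
local_align_many <- function(queries, target, scoring = default_scoring()) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), target, type = "local",
    substitutionMatrix = sub_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext
  )
  sc <- BiocGenerics::score(pa)
  len <- Biostrings::nchar(pa)
  nm <- Biostrings::nmatch(pa)
  out <- data.frame(
    score = sc, identity = ifelse(len > 0, nm / len, 0), length = len,
    q_start = BiocGenerics::start(Biostrings::pattern(pa)),
    q_end = BiocGenerics::end(Biostrings::pattern(pa)),
    t_start = BiocGenerics::start(Biostrings::subject(pa)),
    t_end = BiocGenerics::end(Biostrings::subject(pa))
  )
  empty <- out$score <= 0
  out$length[empty] <- 0L
  out$identity[empty] <- 0
  out$q_start[empty] <- out$q_end[empty] <- 0L
  out$t_start[empty] <- out$t_end[empty] <- 0L
  out
}

#' Classify read pairs by mapping signature
#'
#' One label per pair: `proper` (both mapped, same chromosome, FR
#' orientation, template within `insert_mean +/- k * insert_sd`),
#' `singleton` (exactly one mate mapped), `unmapped_pair` (neither mapped),
#' `soft_clipped` (a mapped mate carries a soft clip of at least
#' `min_clip`; takes precedence over proper/discordant for evidence
#' collection), otherwise `discordant`.
#'
#' @param reads read data.frame from [read_sam()] (both mates present).
#' @param params a [discovery_params()].
#' @return data.frame with one row per pair: qname, class, and row indices
#'   of the two mates in `reads`.
#' @export
classify_pairs <- function(reads, params = discovery_params()) {
  paired <- pair_reads(reads)
  i1 <- which(!duplicated(paired$pair_id))
  i2 <- i1 + 1L
  m1 <- paired[i1, , drop = FALSE]
  m2 <- paired[i2, , drop = FALSE]
  mapped1 <- !m1$unmapped; mapped2 <- !m2$unmapped
  both <- mapped1 & mapped2
  same_chrom <- both & m1$chrom == m2$chrom
  left_first <- ifelse(both, m1$pos <= m2$pos, NA)
  fwd <- ifelse(left_first, !m1$rev & m2$rev, !m2$rev & m1$rev)
  tl <- ifelse(both,
               pmax(m1$end, m2$end) - pmin(m1$pos, m2$pos) + 1L, NA_integer_)
  lo <- params$insert_mean - params$proper_span_k * params$insert_sd
  hi <- params$insert_mean + params$proper_span_k * params$insert_sd
  proper <- both & same_chrom & fwd & !is.na(tl) & tl >= lo & tl <= hi
  clip <- pmax(m1$clip_left, m1$clip_right, m2$clip_left, m2$clip_right)
  cls <- ifelse(!mapped1 & !mapped2, "unmapped_pair",
         ifelse(xor(mapped1, mapped2), "singleton",
         ifelse(clip >= params$min_clip, "soft_clipped",
         ifelse(proper, "proper", "discordant"))))
  data.frame(qname = m1$qname, class = cls,
             row1 = as.integer(rownames(m1)), row2 = as.integer(rownames(m2)),
             stringsAsFactors = FALSE)
}

#' Collect anchor evidence against an LTR element library
#'
#' For singleton and discordant pairs, the non-anchoring mate is aligned
#' (both orientations) to every library element; for soft-clipped reads the
#' clipped tail is aligned. Evidence is kept when identity reaches
#' `min_identity` over `min_hit_length` bases (clip hits: `min_clip`).
#' Anchors on the forward strand point at a downstream insertion (side
#' `5p`, anchor position = alignment end); reverse-strand anchors are the
#' mirror case (`3p`, anchor position = alignment start).
#'
#' @param reads read data.frame from [read_sam()].
#' @param library named character vector: the LTR element library.
#' @param params a [discovery_params()].
#' @return data.frame of anchor evidence: chrom, pos, strand, kind,
#'   element, identity, length, side, qname.
#' @export
collect_anchors <- function(reads, library, params = discovery_params()) {
  if (length(library) == 0) stop("element library is empty", call. = FALSE)
  rownames(reads) <- NULL
  pairs <- classify_pairs(reads, params)

  # mate-hit candidates: the non-anchoring mate's sequence, keyed by the
  # mapped anchor mate (both mates of a discordant pair can anchor)
  sel <- pairs$class %in% c("singleton", "discordant")
  mate_cand <- function(anchor_rows, other_rows) {
    a <- reads[anchor_rows, , drop = FALSE]
    o <- reads[other_rows, , drop = FALSE]
    ok <- !a$unmapped & a$mapq >= params$min_mapq
    if (!any(ok)) return(NULL)
    data.frame(
      query = o$seq[ok], kind = "mate_hit", chrom = a$chrom[ok],
      pos = ifelse(!a$rev[ok], a$end[ok], a$pos[ok]),
      strand = ifelse(!a$rev[ok], "+", "-"),
      side = ifelse(!a$rev[ok], "5p", "3p"),
      qname = a$qname[ok], min_len = params$min_hit_length,
      stringsAsFactors = FALSE)
  }
  cand <- rbind(mate_cand(pairs$row1[sel], pairs$row2[sel]),
                mate_cand(pairs$row2[sel], pairs$row1[sel]))
  # clip-hit candidates: clipped tails of mapped reads
  anchored <- !reads$unmapped & reads$mapq >= params$min_mapq
  rsel <- which(anchored & reads$clip_right >= params$min_clip)
  if (length(rsel)) {
    r <- reads[rsel, , drop = FALSE]
    cand <- rbind(cand, data.frame(
      query = substr(r$seq, nchar(r$seq) - r$clip_right + 1L, nchar(r$seq)),
      kind = "clip_hit", chrom = r$chrom, pos = r$end, strand = "+",
      side = "5p", qname = r$qname, min_len = params$min_clip,
      stringsAsFactors = FALSE))
  }
  lsel <- which(anchored & reads$clip_left >= params$min_clip)
  if (length(lsel)) {
    r <- reads[lsel, , drop = FALSE]
    cand <- rbind(cand, data.frame(
      query = substr(r$seq, 1L, r$clip_left), kind = "clip_hit",
      chrom = r$chrom, pos = r$pos, strand = "-", side = "3p",
      qname = r$qname, min_len = params$min_clip, stringsAsFactors = FALSE))
  }
  if (is.null(cand) || nrow(cand) == 0) return(empty_anchor_frame())

  hits <- best_library_hit(cand$query, library)
  keep <- hits$identity >= params$min_identity & hits$length >= cand$min_len
  out <- data.frame(
    chrom = cand$chrom[keep], pos = cand$pos[keep],
    strand = cand$strand[keep], kind = cand$kind[keep],
    element = hits$element[keep], identity = hits$identity[keep],
    length = hits$length[keep], side = cand$side[keep],
    qname = cand$qname[keep], stringsAsFactors = FALSE
  )
  sort_by_locus(out, "pos")
}

# Best local-alignment hit of each query across all library elements and
# both query orientations.
best_library_hit <- function(queries, library) {
  n <- length(queries)
  best <- data.frame(element = rep(NA_character_, n), score = rep(-Inf, n),
                     identity = rep(0, n), length = rep(0L, n))
  uq <- unique(queries)
  map <- match(queries, uq)
  orientations <- list(fwd = uq, rev = revcomp(uq))
  ubest <- data.frame(element = rep(NA_character_, length(uq)),
                      score = rep(-Inf, length(uq)),
                      identity = rep(0, length(uq)),
                      length = rep(0L, length(uq)))
  for (el in names(library)) {
    for (o in orientations) {
      al <- local_align_many(o, library[[el]])
      upd <- al$score > ubest$score
      ubest$element[upd] <- el
      ubest$score[upd] <- al$score[upd]
      ubest$identity[upd] <- al$identity[upd]
      ubest$length[upd] <- al$length[upd]
    }
  }
  best$element <- ubest$element[map]
  best$score <- ubest$score[map]
  best$identity <- ubest$identity[map]
  best$length <- ubest$length[map]
  best
}

empty_anchor_frame <- function() {
  data.frame(chrom = character(0), pos = integer(0), strand = character(0),
             kind = character(0), element = character(0),
             identity = numeric(0), length = integer(0), side = character(0),
             qname = character(0), stringsAsFactors = FALSE)
}
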