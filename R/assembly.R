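# Local junction assembly: read extraction around the TSD, greedy
# overlap-layout-consensus contigs, junction analysis against reference and
# library, and reconstruction of the inserted LTR as the TSD-to-TSD region.
#
# The assembler is gapless (the simulator models substitution errors only)
# and deterministic: unique reads are canonically ordered, the best
# (longest) overlap is merged first, and all tie-breaks are lexicographic,
# so shuffling the input reads cannot change the contig set.

#' Assembly parameters
#'
#' @param min_overlap minimum read overlap in bp for a merge.
#' @param min_overlap_identity minimum identity within the overlap.
#' @param window extraction window around the TSD in bp.
#' @param min_remainder minimum non-reference contig remainder submitted to
#'   library matching, in bp.
#' @param ref_window reference window around the call used for junction
#'   analysis, in bp.
#' @return object of class `assembly_params`.
#' @export
assembly_params <- function(min_overlap = 40L, min_overlap_identity = 0.90,
                            window = 150L, min_remainder = 30L,
                            ref_window = 1000L) {
  structure(list(min_overlap = as.integer(min_overlap),
                 min_overlap_identity = min_overlap_identity,
                 window = as.integer(window),
                 min_remainder = as.integer(min_remainder),
                 ref_window = as.integer(ref_window)),
            class = "assembly_params")
}

#' Extract junction reads around a TSD or breakpoint
#'
#' Mapped reads whose alignment ends within `window` bp upstream of the TSD
#' feed the 5' set; reads starting within `window` bp downstream feed the
#' 3' set. Unmapped mates of in-window reads join their anchor's set.
#'
#' @param reads read data.frame from [read_sam()].
#' @param chrom chromosome name.
#' @param tsd_start,tsd_end 1-based TSD interval (for a one-sided call pass
#'   the breakpoint position as both).
#' @param params an [assembly_params()].
#' @return list with `reads_5p` and `reads_3p`: character vectors of read
#'   sequences (reference orientation; the assembler tries both strands).
#' @export
extract_junction_reads <- function(reads, chrom, tsd_start, tsd_end,
                                   params = assembly_params()) {
  w <- params$window
  on_ch <- reads[reads$chrom == chrom, , drop = FALSE]
  mapped <- !on_ch$unmapped & !is.na(on_ch$pos)
  in5 <- mapped & on_ch$end >= tsd_start - w & on_ch$end <= tsd_end
  in3 <- mapped & on_ch$pos >= tsd_start & on_ch$pos <= tsd_end + w
  # unmapped mates of in-window anchors
  um <- on_ch$unmapped
  mate5 <- um & on_ch$qname %in% on_ch$qname[in5]
  mate3 <- um & on_ch$qname %in% on_ch$qname[in3]
  list(reads_5p = on_ch$seq[in5 | mate5], reads_3p = on_ch$seq[in3 | mate3])
}

# One-hot count matrix (rows A, C, G, T) for a sequence, weighted by `mult`.
seq_counts <- function(seq, mult = 1L) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- matrix(0L, 4L, length(b), dimnames = list(DNA_BASES, NULL))
  hit <- match(b, DNA_BASES)
  ok <- !is.na(hit)
  m[cbind(hit[ok], which(ok))] <- mult
  m
}

counts_consensus <- function(counts) {
  paste(DNA_BASES[max.col(t(counts), ties.method = "first")], collapse = "")
}

counts_revcomp <- function(counts) {
  counts[4:1, rev(seq_len(ncol(counts))), drop = FALSE]
}

new_contig <- function(seq, counts, n_reads) {
  list(sequence = seq, counts = counts, n_reads = n_reads,
       coverage = colSums(counts))
}

#' Greedy overlap-layout-consensus assembly
#'
#' Reads (used in both orientations) are merged best-overlap-first:
#' the longest gapless overlap of at least `min_overlap` bases at
#' `min_overlap_identity` identity wins each round. Consensus is per-column
#' coverage-weighted majority with lexicographic tie-breaks (A<C<G<T).
#'
#' @param reads character vector of read sequences (>= 1).
#' @param params an [assembly_params()].
#' @return list of contigs, longest first; each has `sequence`, `counts`
#'   (4 x L base-count matrix), `coverage` and `n_reads`.
#' @export
assemble <- function(reads, params = assembly_params()) {
  reads <- toupper(reads[nzchar(reads)])
  if (length(reads) == 0) stop("no reads to assemble", call. = FALSE)
  tab <- table(reads)
  seqs <- names(tab)                      # lexicographically sorted, unique
  mult <- as.integer(tab)
  contigs <- mapply(function(s, m) new_contig(s, seq_counts(s, m), m),
                    seqs, mult, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  active <- rep(TRUE, length(contigs))
  rcs <- revcomp(seqs)
  cseqs <- as.list(seqs)
  crcs <- as.list(rcs)
  cand <- C_overlap_pairs(seqs, rcs, params$min_overlap,
                          params$min_overlap_identity)
  cand <- as.data.frame(cand)
  repeat {
    if (nrow(cand) == 0) break
    best <- cand[order(-cand$len, cand$i, cand$j, cand$orient, cand$dir), ][1, ]
    i <- best$i; j <- best$j
    cj <- contigs[[j]]
    if (best$orient == 1L) {
      cj <- new_contig(crcs[[j]], counts_revcomp(cj$counts), cj$n_reads)
    }
    pair <- if (best$dir == 0L) list(contigs[[i]], cj) else
      list(cj, contigs[[i]])
    merged <- merge_contigs(pair[[1]], pair[[2]], best$len)
    active[c(i, j)] <- FALSE
    contigs[[length(contigs) + 1L]] <- merged
    active <- c(active, TRUE)
    cseqs[[length(contigs)]] <- merged$sequence
    crcs[[length(contigs)]] <- revcomp(merged$sequence)
    cand <- cand[cand$i != i & cand$j != i & cand$i != j & cand$j != j, ,
                 drop = FALSE]
    others <- which(active)
    others <- others[others != length(contigs)]
    if (length(others)) {
      nc <- C_overlap_one(merged$sequence, crcs[[length(contigs)]],
                          unlist(cseqs[others]), unlist(crcs[others]),
                          params$min_overlap, params$min_overlap_identity)
      if (nrow(nc)) {
        nc <- as.data.frame(nc)
        # Re-express (new-vs-other) rows in the pair-table vocabulary
        # (i = other, j = new, orient flips j). For forward rows the merge
        # order flips with the index swap; orient-1 rows map to the
        # reverse complement of the same merge, where the order is kept.
        add <- data.frame(i = others[nc$j], j = length(contigs),
                          orient = nc$orient,
                          dir = ifelse(nc$orient == 1L, nc$dir,
                                       1L - nc$dir),
                          len = nc$len, mism = nc$mism)
        cand <- rbind(cand, add)
      }
    }
  }
  out <- contigs[active]
  lens <- vapply(out, function(c) nchar(c$sequence), integer(1))
  out[order(-lens, vapply(out, `[[`, character(1), "sequence"))]
}

# Merge left + right contigs over a gapless overlap of `ov` columns.
merge_contigs <- function(left, right, ov) {
  ll <- ncol(left$counts); lr <- ncol(right$counts)
  counts <- cbind(
    left$counts[, seq_len(ll - ov), drop = FALSE],
    left$counts[, (ll - ov + 1L):ll, drop = FALSE] +
      right$counts[, seq_len(ov), drop = FALSE],
    right$counts[, setdiff(seq_len(lr), seq_len(ov)), drop = FALSE]
  )
  new_contig(counts_consensus(counts), counts, left$n_reads + right$n_reads)
}

# Orientation note: C_overlap_one scans a (the new contig) against each
# other contig; dir there is 0 for "a then other". The cand table stores
# dir relative to (i, j) ordering, hence the 1 - dir flip above.

#' Analyse a contig for an LTR-genome junction
#'
#' The contig (both orientations) is locally aligned to the reference
#' window around the call; the unaligned remainder (at least
#' `min_remainder` bp) is aligned to the element library. A junction contig
#' is returned when the remainder hits the library at `min_identity`; the
#' side is `5p` when the reference-matching end is 5' of the element
#' remainder.
#'
#' @param contig a contig from [assemble()].
#' @param reference named character vector of chromosomes.
#' @param call one-row call data.frame.
#' @param library named character vector: LTR element library.
#' @param params an [assembly_params()].
#' @param disc_params a [discovery_params()] (for `min_identity`).
#' @return list (junction contig) with `contig`, `ref_segment`,
#'   `nonref_range`, `nonref_seq`, `nonref_counts`, `nonref_hit`,
#'   `junction_side`, or `NULL`.
#' @export
analyze_junction <- function(contig, reference, call, library,
                             params = assembly_params(),
                             disc_params = discovery_params()) {
  chrom_seq <- reference[[call$chrom]]
  lo <- max(1L, call$breakpoint_pos - params$ref_window)
  hi <- min(nchar(chrom_seq), call$breakpoint_pos + params$ref_window)
  ref_win <- substr(chrom_seq, lo, hi)
  cand <- list(
    fwd = contig,
    rev = new_contig(revcomp(contig$sequence), counts_revcomp(contig$counts),
                     contig$n_reads)
  )
  al <- lapply(cand, function(ct) local_align(ct$sequence, ref_win))
  use <- if (al$fwd$score >= al$rev$score) "fwd" else "rev"
  ct <- cand[[use]]; a <- al[[use]]
  if (a$length < 30) return(NULL)
  len <- nchar(ct$sequence)
  left_rem <- a$q_start - 1L
  right_rem <- len - a$q_end
  if (max(left_rem, right_rem) < params$min_remainder) return(NULL)
  # The maximal local alignment can absorb element bases that match the
  # reference by chance past the junction (or vice versa), so the boundary
  # is re-anchored exactly: the reference bases flanking the detected TSD
  # must occur literally in the contig consensus at the junction.
  tsd_start <- call$tsd_start; tsd_end <- call$tsd_end
  ref_end <- lo + a$t_end - 1L; ref_start <- lo + a$t_start - 1L
  probe_len <- 20L
  nearest_match <- function(probe, near) {
    occ <- gregexpr(probe, ct$sequence, fixed = TRUE)[[1]]
    if (occ[1] < 0) return(NA_integer_)
    occ[which.min(abs(occ - near))]
  }
  if (right_rem >= left_rem) {
    q_end <- a$q_end
    if (!is.na(tsd_end)) {
      occ <- nearest_match(substr(chrom_seq, tsd_end - probe_len + 1L,
                                  tsd_end),
                           a$q_end - probe_len + 1L)
      if (!is.na(occ)) q_end <- occ + probe_len - 1L
      else if (ref_end > tsd_end) q_end <- q_end - (ref_end - tsd_end)
    }
    nonref_range <- c(q_end + 1L, len)
    side <- "5p"
  } else {
    q_start <- a$q_start
    if (!is.na(tsd_start)) {
      occ <- nearest_match(substr(chrom_seq, tsd_start,
                                  tsd_start + probe_len - 1L), a$q_start)
      if (!is.na(occ)) q_start <- occ
      else if (ref_start < tsd_start) q_start <- q_start +
          (tsd_start - ref_start)
    }
    nonref_range <- c(1L, q_start - 1L)
    side <- "3p"
  }
  nonref_range <- pmin(pmax(nonref_range, 1L), len)
  if (nonref_range[2] - nonref_range[1] + 1L < params$min_remainder)
    return(NULL)
  nonref_seq <- substr(ct$sequence, nonref_range[1], nonref_range[2])
  hit <- best_library_hit(nonref_seq, library)
  if (is.na(hit$element[1]) || hit$identity[1] < disc_params$min_identity)
    return(NULL)
  list(
    contig = ct,
    ref_segment = c(lo + a$t_start - 1L, lo + a$t_end - 1L),
    nonref_range = nonref_range,
    nonref_seq = nonref_seq,
    nonref_counts = ct$counts[, nonref_range[1]:nonref_range[2],
                              drop = FALSE],
    nonref_hit = list(element = hit$element[1], identity = hit$identity[1],
                      length = hit$length[1]),
    junction_side = side
  )
}

#' Reconstruct the inserted LTR from junction contigs
#'
#' With both sides available their non-reference segments are merged over
#' their best gapless overlap; columns where the two contigs' consensus
#' bases disagree are counted into `overlap_mismatches` (they are reported,
#' never silently resolved; the merged consensus is coverage-weighted
#' majority). The reported sequence spans TSD to TSD inclusive. Sides that
#' cannot be joined are reported one-sided rather than guessed.
#'
#' @param j5,j3 junction contigs from [analyze_junction()] (either may be
#'   `NULL`, not both).
#' @param tsd TSD result list from [detect_tsd()], or `NULL`.
#' @param call one-row call data.frame.
#' @param params an [assembly_params()].
#' @return object of class `reconstructed_ltr`: list with `sequence`,
#'   `length_with_tsd`, `tsd5`, `tsd3`, `completeness`,
#'   `overlap_mismatches`, `chrom`, `breakpoint_pos`, `element`.
#' @export
reconstruct_ltr <- function(j5, j3 = NULL, tsd = NULL, call,
                            params = assembly_params()) {
  if (is.null(j5) && is.null(j3))
    stop("at least one junction contig is required", call. = FALSE)
  tsd_seq <- if (!is.null(tsd)) tsd$tsd_seq else NULL
  element <- unique(c(if (!is.null(j5)) j5$nonref_hit$element,
                      if (!is.null(j3)) j3$nonref_hit$element))[1]
  finish <- function(seq, completeness, mism) {
    structure(list(
      sequence = seq, length_with_tsd = nchar(seq),
      tsd5 = if (completeness %in% c("both", "5p_only")) tsd_seq else NULL,
      tsd3 = if (completeness %in% c("both", "3p_only")) tsd_seq else NULL,
      completeness = completeness, overlap_mismatches = mism,
      chrom = call$chrom, breakpoint_pos = call$breakpoint_pos,
      element = element
    ), class = "reconstructed_ltr")
  }
  one_sided <- function() {
    if (!is.null(j5) &&
        (is.null(j3) || ncol(j5$nonref_counts) >= ncol(j3$nonref_counts))) {
      finish(paste0(tsd_seq %||% "", j5$nonref_seq), "5p_only", 0L)
    } else {
      finish(paste0(j3$nonref_seq, tsd_seq %||% ""), "3p_only", 0L)
    }
  }
  if (is.null(j5) || is.null(j3) || is.null(tsd)) return(one_sided())
  e5 <- j5$nonref_seq; e3 <- j3$nonref_seq
  ov <- C_overlap_one(e5, revcomp(e5), e3, revcomp(e3),
                      params$min_overlap, params$min_overlap_identity)
  ov <- as.data.frame(ov)
  ov <- ov[ov$orient == 0L & ov$dir == 0L, , drop = FALSE]
  if (nrow(ov) == 0) return(one_sided())
  merged <- merge_contigs(
    new_contig(e5, j5$nonref_counts, j5$contig$n_reads),
    new_contig(e3, j3$nonref_counts, j3$contig$n_reads), ov$len[1])
  finish(paste0(tsd_seq, merged$sequence, tsd_seq), "both", ov$mism[1])
}

#' Assemble and reconstruct every called locus
#'
#' @param reads read data.frame.
#' @param calls call data.frame from [call_insertions()].
#' @param reference named character vector of chromosomes.
#' @param library named character vector: LTR element library.
#' @param params an [assembly_params()].
#' @param disc_params a [discovery_params()].
#' @param min_contig_reads contigs built from fewer reads are not analysed
#'   (singletons are uninformative against a ~600-bp LTR).
#' @return list of `reconstructed_ltr` objects (loci with no junction
#'   contig are omitted).
#' @export
reconstruct_insertions <- function(reads, calls, reference, library,
                                   params = assembly_params(),
                                   disc_params = discovery_params(),
                                   min_contig_reads = 2L) {
  out <- list()
  for (k in seq_len(nrow(calls))) {
    call <- calls[k, , drop = FALSE]
    ts <- if (!is.na(call$tsd_start)) call$tsd_start else call$breakpoint_pos
    te <- if (!is.na(call$tsd_end)) call$tsd_end else call$breakpoint_pos
    sets <- extract_junction_reads(reads, call$chrom, ts, te, params)
    tsd <- if (!is.na(call$tsd_start))
      list(tsd_start = call$tsd_start, tsd_end = call$tsd_end,
           tsd_seq = call$tsd_seq) else NULL
    pick <- function(read_set, want_side) {
      if (length(read_set) == 0) return(NULL)
      contigs <- assemble(read_set, params)
      contigs <- Filter(function(ct) ct$n_reads >= min_contig_reads, contigs)
      for (ct in contigs) {
        jc <- analyze_junction(ct, reference, call, library, params,
                               disc_params)
        if (!is.null(jc) && jc$junction_side == want_side) return(jc)
      }
      NULL
    }
    j5 <- pick(sets$reads_5p, "5p")
    j3 <- pick(sets$reads_3p, "3p")
    if (is.null(j5) && is.null(j3)) next
    out[[length(out) + 1L]] <- reconstruct_ltr(j5, j3, tsd, call, params)
  }
  out
}
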