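# Paired-end read simulation with truth alignments against the original
# reference. The simulator stands in for the sequencer plus aligner: each
# read's donor interval is mapped back through the insertion events, so
# reads fully inside reference sequence become proper pairs, reads inside
# an inserted element become (mate-anchored) unmapped records, and reads
# spanning a junction are soft-clipped at the junction.

#' Read simulation parameters
#'
#' @param read_length read length in bp.
#' @param fragment_mean,fragment_sd fragment (insert) size distribution in
#'   bp; defaults model a 350-bp PCR-free library sequenced as 150-bp
#'   paired-end reads.
#' @param coverage fold coverage of the donor genome.
#' @param per_base_error substitution error probability per base (0 for the
#'   error-free mode used in verification; indels are not modelled).
#' @param min_anchor minimum aligned bases for a junction-spanning read to
#'   be reported mapped (shorter anchors are reported unmapped, as a seed
#'   aligner would).
#' @param proper_span_k template-length multiplier defining proper pairs
#'   (within `fragment_mean +/- k * fragment_sd`).
#' @param seed integer seed.
#' @return object of class `readsim_params`.
#' @export
readsim_params <- function(read_length = 150L, fragment_mean = 350L,
                           fragment_sd = 50L, coverage = 50,
                           per_base_error = 0, min_anchor = 20L,
                           proper_span_k = 3, seed = 1L) {
  if (fragment_mean <= read_length)
    stop("fragment_mean must exceed read_length", call. = FALSE)
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  if (per_base_error < 0 || per_base_error > 1)
    stop("per_base_error must be in [0, 1]", call. = FALSE)
  structure(list(read_length = as.integer(read_length),
                 fragment_mean = as.integer(fragment_mean),
                 fragment_sd = fragment_sd, coverage = coverage,
                 per_base_error = per_base_error,
                 min_anchor = as.integer(min_anchor),
                 proper_span_k = proper_span_k, seed = as.integer(seed)),
            class = "readsim_params")
}

# Donor segment map for one chromosome: alternating reference and element
# segments with donor start/end and, for reference segments, the reference
# coordinate of their first base.
segment_map <- function(truth_ch, ref_len) {
  segs <- NULL
  cur_ref <- 1L
  cur_don <- 1L
  if (nrow(truth_ch) > 0) {
    for (k in seq_len(nrow(truth_ch))) {
      p <- truth_ch$pos[k]; tl <- truth_ch$tsd_len[k]
      left_len <- (p + tl - 1L) - cur_ref + 1L
      segs <- rbind(segs, data.frame(
        type = "ref", don_start = cur_don, don_end = cur_don + left_len - 1L,
        ref_start = cur_ref, event = NA_integer_))
      cur_don <- cur_don + left_len
      elen <- truth_ch$element_length[k]
      segs <- rbind(segs, data.frame(
        type = "elem", don_start = cur_don, don_end = cur_don + elen - 1L,
        ref_start = NA_integer_, event = k))
      cur_don <- cur_don + elen
      cur_ref <- p
    }
  }
  tail_len <- ref_len - cur_ref + 1L
  segs <- rbind(segs, data.frame(
    type = "ref", don_start = cur_don, don_end = cur_don + tail_len - 1L,
    ref_start = cur_ref, event = NA_integer_))
  segs
}

# Truth-map one batch of read intervals [a, b] (all on one chromosome)
# through the segment map. Returns pos, cigar, junction (reference
# coordinate of the clip boundary, NA if unclipped) per read; pos NA when
# unmapped.
map_reads_to_ref <- function(a, b, segs, read_length, min_anchor) {
  si <- findInterval(a, segs$don_start)
  sj <- findInterval(b, segs$don_start)
  n <- length(a)
  pos <- rep(NA_integer_, n)
  cigar <- rep("*", n)
  junction <- rep(NA_integer_, n)
  same <- si == sj
  refseg <- segs$type[si] == "ref"
  # fully inside a reference segment
  idx <- which(same & refseg)
  pos[idx] <- segs$ref_start[si[idx]] + (a[idx] - segs$don_start[si[idx]])
  cigar[idx] <- paste0(read_length, "M")
  # spanning a junction
  idx <- which(!same)
  for (i in idx) {
    if (segs$type[si[i]] == "ref") {
      # left junction: anchored on the left, clipped on the right
      anchor <- segs$don_end[si[i]] - a[i] + 1L
      if (anchor >= min_anchor) {
        pos[i] <- segs$ref_start[si[i]] + (a[i] - segs$don_start[si[i]])
        cigar[i] <- paste0(anchor, "M", read_length - anchor, "S")
        junction[i] <- pos[i] + anchor - 1L
      }
    } else if (segs$type[sj[i]] == "ref") {
      # right junction: clipped on the left, anchored on the right
      anchor <- b[i] - segs$don_start[sj[i]] + 1L
      if (anchor >= min_anchor) {
        pos[i] <- segs$ref_start[sj[i]]
        cigar[i] <- paste0(read_length - anchor, "S", anchor, "M")
        junction[i] <- pos[i]
      }
    }
    # element-to-element spans (two junctions inside one read) stay unmapped
  }
  list(pos = pos, cigar = cigar, junction = junction)
}

#' Simulate paired-end reads from a donor genome with truth alignments
#'
#' Fragments are sampled uniformly along each donor chromosome at the
#' requested coverage. Each pair is emitted in FR orientation with the
#' first-in-pair mate chosen at random. Truth alignments are computed by
#' mapping donor intervals back through the insertion events.
#'
#' @param donor_set result of [insert_elements()] (donor, truth,
#'   ref_lengths).
#' @param params a [readsim_params()].
#' @return list of class `read_simulation`: `reads` (SAM-style data.frame
#'   with truth columns `junction` and `truth_class`), `sq` (reference
#'   names/lengths), `params`.
#' @export
simulate_reads <- function(donor_set, params) {
  stopifnot(inherits(params, "readsim_params"))
  donor <- donor_set$donor
  truth <- donor_set$truth
  ref_lengths <- donor_set$ref_lengths
  rl <- params$read_length
  with_seed(params$seed, {
    all_reads <- vector("list", length(donor))
    for (ci in seq_along(donor)) {
      ch <- names(donor)[ci]
      dlen <- nchar(donor[[ch]])
      segs <- segment_map(truth[truth$chrom == ch, , drop = FALSE],
                          ref_lengths[[ch]])
      n <- as.integer(round(params$coverage * dlen / (2 * rl)))
      if (n == 0L) next
      flen <- pmin(pmax(as.integer(round(
        stats::rnorm(n, params$fragment_mean, params$fragment_sd))), rl),
        dlen)
      s <- 1L + as.integer(floor(stats::runif(n) * (dlen - flen + 1)))
      a1 <- s; b1 <- s + rl - 1L               # left (+) mate
      a2 <- s + flen - rl; b2 <- s + flen - 1L # right (-) mate
      seq1 <- substring(donor[[ch]], a1, b1)
      seq2 <- substring(donor[[ch]], a2, b2)
      if (params$per_base_error > 0) {
        seq1 <- add_substitution_errors(seq1, params$per_base_error)
        seq2 <- add_substitution_errors(seq2, params$per_base_error)
      }
      m1 <- map_reads_to_ref(a1, b1, segs, rl, params$min_anchor)
      m2 <- map_reads_to_ref(a2, b2, segs, rl, params$min_anchor)
      qname <- sprintf("f%s_%07d", ch, seq_len(n))
      all_reads[[ci]] <- build_pair_records(
        qname, ch, seq1, seq2, m1, m2, params)
    }
    reads <- do.call(rbind, all_reads)
    sq <- data.frame(name = names(ref_lengths),
                     length = as.integer(ref_lengths))
    structure(list(reads = reads, sq = sq, params = params),
              class = "read_simulation")
  })
}

add_substitution_errors <- function(seqs, p) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), p)
  hit <- which(n_err > 0)
  for (i in hit) {
    posn <- sample.int(nchar(seqs[i]), n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p1 in posn) ch[p1] <- sample(setdiff(DNA_BASES, ch[p1]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Assemble SAM-style records for n pairs (vectorized over pairs).
build_pair_records <- function(qname, chrom, seq1, seq2, m1, m2, params) {
  n <- length(qname)
  mapped1 <- !is.na(m1$pos); mapped2 <- !is.na(m2$pos)
  span_lo <- params$fragment_mean - params$proper_span_k * params$fragment_sd
  span_hi <- params$fragment_mean + params$proper_span_k * params$fragment_sd
  # reference template length when both mapped (left mate is +, right is -)
  ci1 <- cigar_info(m1$cigar); ci2 <- cigar_info(m2$cigar)
  end1 <- m1$pos + ci1$rlen - 1L; end2 <- m2$pos + ci2$rlen - 1L
  tstart <- pmin(m1$pos, m2$pos); tend <- pmax(end1, end2)
  tlen <- ifelse(mapped1 & mapped2, tend - tstart + 1L, 0L)
  fr <- mapped1 & mapped2 & m1$pos <= m2$pos
  proper <- mapped1 & mapped2 & fr & tlen >= span_lo & tlen <= span_hi
  clip1 <- pmax(ci1$clip_left, ci1$clip_right, na.rm = TRUE)
  clip2 <- pmax(ci2$clip_left, ci2$clip_right, na.rm = TRUE)
  clip1[is.na(clip1)] <- 0L; clip2[is.na(clip2)] <- 0L
  truth_class <- ifelse(!mapped1 & !mapped2, "unmapped_pair",
                 ifelse(xor(mapped1, mapped2), "singleton",
                 ifelse(pmax(clip1, clip2) >= 10L, "soft_clipped",
                 ifelse(proper, "proper", "discordant"))))
  # the SAM proper flag is stricter than the geometric pair class: a
  # junction-overlapping (clipped) record is never marked proper
  proper <- proper & clip1 == 0L & clip2 == 0L
  # first-in-pair is the left mate for a random half of the pairs
  r1_left <- stats::runif(n) < 0.5
  flag <- function(mapped, mate_mapped, rev, mrev, first, prop) {
    1L + ifelse(prop, 2L, 0L) + ifelse(mapped, 0L, 4L) +
      ifelse(mate_mapped, 0L, 8L) + ifelse(rev, 16L, 0L) +
      ifelse(mrev, 32L, 0L) + ifelse(first, 64L, 128L)
  }
  rec <- function(mapped, mate_mapped, m, m_mate, seqs, rev, mrev, first,
                  tl) {
    data.frame(
      qname = qname, flag = flag(mapped, mate_mapped, rev, mrev, first,
                                 proper),
      chrom = ifelse(mapped | mate_mapped, chrom, "*"),
      pos = ifelse(mapped, m$pos, ifelse(mate_mapped, m_mate$pos, 0L)),
      mapq = ifelse(mapped, 60L, 0L),
      cigar = ifelse(mapped, m$cigar, "*"),
      mchrom = ifelse(mapped | mate_mapped, "=", "*"),
      mpos = ifelse(mate_mapped, m_mate$pos, ifelse(mapped, m$pos, 0L)),
      tlen = tl, seq = seqs,
      junction = m$junction, truth_class = truth_class,
      stringsAsFactors = FALSE
    )
  }
  # SEQ is stored in reference (donor-forward) orientation; the right mate
  # carries the reverse flag. FASTQ output reverse-complements it back.
  r1 <- rec(mapped1, mapped2, m1, m2, seq1, rev = FALSE, mrev = TRUE,
            first = r1_left, tl = tlen)
  r2 <- rec(mapped2, mapped1, m2, m1, seq2, rev = TRUE, mrev = FALSE,
            first = !r1_left, tl = -tlen)
  out <- rbind(r1, r2)
  out[order(rep(seq_len(n), 2L)), , drop = FALSE]
}

#' Write a read simulation to disk (truth SAM plus paired FASTQ)
#'
#' @param sim a `read_simulation` from [simulate_reads()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the paths written.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- sim$reads
  sam_path <- file.path(dir, paste0(prefix, ".sam"))
  sam_reads <- reads[order(reads$chrom, ifelse(is.na(reads$pos) | reads$pos == 0L,
                                               .Machine$integer.max, reads$pos),
                           reads$qname, reads$flag), , drop = FALSE]
  write_sam(sam_reads[, c("qname", "flag", "chrom", "pos", "mapq", "cigar",
                          "mchrom", "mpos", "tlen", "seq")],
            sam_path, sq = sim$sq)
  first <- reads[sam_flags(reads$flag)$first, , drop = FALSE]
  second <- reads[sam_flags(reads$flag)$second, , drop = FALSE]
  second <- second[match(first$qname, second$qname), , drop = FALSE]
  as_sequenced <- function(df) ifelse(sam_flags(df$flag)$rev,
                                      revcomp(df$seq), df$seq)
  fq <- write_fastq_pairs(first$qname, as_sequenced(first),
                          as_sequenced(second),
                          file.path(dir, prefix))
  c(sam = sam_path, fastq1 = fq[1], fastq2 = fq[2])
}
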