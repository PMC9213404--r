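# Breakpoint calling: anchor clustering, support filtering, filter levels,
# 500-bp call merging, and TSD detection from soft-clip stacks.

#' Breakpoint calling parameters
#'
#' Defaults encode the published pipeline settings: read support >= 10,
#' 500-bp call merging, filter level >= 7, maximum depth 10,000 per call.
#'
#' @param min_support minimum total anchor support for a call.
#' @param merge_window calls within this distance are considered identical.
#' @param cluster_window single-linkage clustering window in bp
#'   (defaults to `insert_mean + 2 * insert_sd`).
#' @param min_filter_level calls below this level are flagged (not deleted).
#' @param max_depth clusters with more supporting reads than this are
#'   dropped as repeat artifacts.
#' @param insert_mean,insert_sd insert-size model used for the default
#'   cluster window.
#' @param read_length read length in bp (used by the filter-level
#'   tightness bonus).
#' @param tsd_window window around the breakpoint searched for clip stacks.
#' @return object of class `calling_params`.
#' @export
calling_params <- function(min_support = 10L, merge_window = 500L,
                           cluster_window = NULL, min_filter_level = 7L,
                           max_depth = 10000L, insert_mean = 350,
                           insert_sd = 50, read_length = 150L,
                           tsd_window = 150L) {
  cluster_window <- cluster_window %||% (insert_mean + 2 * insert_sd)
  vals <- c(min_support, merge_window, cluster_window, min_filter_level,
            max_depth, read_length, tsd_window)
  if (any(vals <= 0)) stop("all calling parameters must be positive",
                           call. = FALSE)
  structure(list(min_support = as.integer(min_support),
                 merge_window = as.integer(merge_window),
                 cluster_window = as.integer(cluster_window),
                 min_filter_level = as.integer(min_filter_level),
                 max_depth = as.integer(max_depth),
                 read_length = as.integer(read_length),
                 tsd_window = as.integer(tsd_window)),
            class = "calling_params")
}

#' Cluster anchors into candidate insertion loci
#'
#' Single-linkage clustering of anchor positions within `cluster_window`,
#' per chromosome, tracking 5'-side (forward) and 3'-side (reverse) anchors
#' separately. Clusters supported by more than `max_depth` anchors are
#' dropped.
#'
#' @param anchors anchor data.frame from [collect_anchors()], sorted by
#'   (chrom, pos).
#' @param params a [calling_params()].
#' @return list of clusters; each is a list with chrom, fwd (data.frame),
#'   rev (data.frame), interval (innermost anchor range), n_anchors.
#' @export
cluster_anchors <- function(anchors, params = calling_params()) {
  if (nrow(anchors) == 0) return(list())
  anchors <- sort_by_locus(anchors, "pos")
  out <- list()
  for (ch in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    brk <- c(0L, which(diff(a$pos) > params$cluster_window), nrow(a))
    for (k in seq_len(length(brk) - 1L)) {
      cl <- a[(brk[k] + 1L):brk[k + 1L], , drop = FALSE]
      if (nrow(cl) > params$max_depth) next
      out[[length(out) + 1L]] <- list(
        chrom = ch,
        fwd = cl[cl$side == "5p", , drop = FALSE],
        rev = cl[cl$side == "3p", , drop = FALSE],
        interval = range(cl$pos),
        n_anchors = nrow(cl)
      )
    }
  }
  out
}

#' Call a breakpoint from an anchor cluster
#'
#' Emitted when total support reaches `min_support`. The breakpoint is the
#' midpoint between the innermost 5' anchor end and the innermost 3' anchor
#' start (or the single side's innermost end for one-sided clusters).
#'
#' @param cluster one cluster from [cluster_anchors()].
#' @param params a [calling_params()].
#' @return one-row call data.frame, or `NULL` below threshold.
#' @export
call_breakpoint <- function(cluster, params = calling_params()) {
  s5 <- nrow(cluster$fwd); s3 <- nrow(cluster$rev)
  if (s5 + s3 < params$min_support) return(NULL)
  bp <- if (s5 > 0 && s3 > 0) {
    as.integer(floor((max(cluster$fwd$pos) + min(cluster$rev$pos)) / 2))
  } else if (s5 > 0) {
    max(cluster$fwd$pos)
  } else {
    min(cluster$rev$pos)
  }
  data.frame(chrom = cluster$chrom, breakpoint_pos = bp,
             support_5p = s5, support_3p = s3, filter_level = NA_integer_,
             tsd_start = NA_integer_, tsd_end = NA_integer_,
             tsd_seq = NA_character_, status = "candidate",
             stringsAsFactors = FALSE)
}

#' Assign a filter level (1-8) to a call
#'
#' Levels are a declared re-interpretation of RetroSeq's evidence tiers that
#' preserves the operational rule "keep levels >= 7": a base level of 5 plus
#' one bonus each for (a) both sides holding >= 2 anchors, (b) >= 2
#' soft-clip reads abutting the breakpoint within 10 bp, and (c) an anchor
#' interval no wider than twice the read length.
#'
#' @param call one-row call data.frame from [call_breakpoint()].
#' @param cluster the cluster the call came from.
#' @param clip_positions integer vector of clip-boundary reference
#'   positions near the call (right-clip ends and left-clip starts).
#' @param params a [calling_params()].
#' @return integer filter level.
#' @export
assign_filter_level <- function(call, cluster, clip_positions,
                                params = calling_params()) {
  two_sided <- nrow(cluster$fwd) >= 2 && nrow(cluster$rev) >= 2
  clip_near <- sum(abs(clip_positions - call$breakpoint_pos) <= 10L)
  tight <- diff(cluster$interval) <= 2L * params$read_length
  5L + as.integer(two_sided) + as.integer(clip_near >= 2L) +
    as.integer(tight)
}

#' Merge calls within the merge window
#'
#' Calls chained within `merge_window` bp of one another are considered the
#' same insertion; the best call of each chain is kept (highest filter
#' level, then total support, then leftmost position).
#'
#' @param calls call data.frame, sorted by (chrom, breakpoint_pos).
#' @param params a [calling_params()].
#' @return deduplicated call data.frame.
#' @export
merge_calls <- function(calls, params = calling_params()) {
  if (nrow(calls) <= 1) return(calls)
  calls <- sort_by_locus(calls, "breakpoint_pos")
  keep <- NULL
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    brk <- c(0L, which(diff(cc$breakpoint_pos) > params$merge_window),
             nrow(cc))
    for (k in seq_len(length(brk) - 1L)) {
      chain <- cc[(brk[k] + 1L):brk[k + 1L], , drop = FALSE]
      best <- order(-chain$filter_level,
                    -(chain$support_5p + chain$support_3p),
                    chain$breakpoint_pos)[1]
      keep <- rbind(keep, chain[best, , drop = FALSE])
    }
  }
  rownames(keep) <- NULL
  sort_by_locus(keep, "breakpoint_pos")
}

#' Detect a 4-5 bp target site duplication from soft-clip stacks
#'
#' Reads approaching the insertion from the 5' side are clipped on the
#' right and their alignments end at the last base of the duplicated target
#' site; reads from the 3' side are clipped on the left and start at its
#' first base. With `L` the modal right-clip end and `R` the modal
#' left-clip start (each supported by >= 2 reads), a TSD is called when
#' `L - R + 1` is 4 or 5; its sequence is taken from the reference (never
#' from read bases). When several mode-tied combinations qualify, the one
#' with more supporting reads wins, then the shorter.
#'
#' @param call one-row call data.frame.
#' @param clip_reads read data.frame near the call with soft clips >=
#'   `min_clip` (see [collect_anchors()]'s clip rule).
#' @param reference named character vector of chromosomes.
#' @param params a [calling_params()].
#' @param min_clip minimum informative clip length.
#' @param min_stack minimum reads per clip stack.
#' @return list(tsd_start, tsd_end, tsd_seq, support_left, support_right)
#'   or `NULL`.
#' @export
detect_tsd <- function(call, clip_reads, reference,
                       params = calling_params(), min_clip = 10L,
                       min_stack = 2L) {
  cr <- clip_reads[!clip_reads$unmapped &
                   clip_reads$chrom == call$chrom &
                   !is.na(clip_reads$pos), , drop = FALSE]
  near <- abs(ifelse(cr$clip_right >= min_clip, cr$end, cr$pos) -
              call$breakpoint_pos) <= params$tsd_window
  cr <- cr[near, , drop = FALSE]
  right_ends <- cr$end[cr$clip_right >= min_clip]
  left_starts <- cr$pos[cr$clip_left >= min_clip]
  modes <- function(x) {
    if (!length(x)) return(NULL)
    t <- table(x)
    t <- t[t >= min_stack]
    if (!length(t)) return(NULL)
    t[t == max(t)]
  }
  mL <- modes(right_ends); mR <- modes(left_starts)
  if (is.null(mL) || is.null(mR)) return(NULL)
  combos <- expand.grid(L = as.integer(names(mL)), R = as.integer(names(mR)))
  combos$len <- combos$L - combos$R + 1L
  combos$support <- as.integer(mL[as.character(combos$L)]) +
    as.integer(mR[as.character(combos$R)])
  combos <- combos[combos$len %in% c(4L, 5L), , drop = FALSE]
  if (nrow(combos) == 0) return(NULL)
  best <- combos[order(-combos$support, combos$len, combos$R), ][1, ]
  list(tsd_start = best$R, tsd_end = best$L,
       tsd_seq = substr(reference[[call$chrom]], best$R, best$L),
       support_left = as.integer(mL[as.character(best$L)]),
       support_right = as.integer(mR[as.character(best$R)]))
}

#' Run the full calling stage
#'
#' Clusters anchors, emits supported calls, detects TSDs, assigns filter
#' levels and merges nearby calls. Calls below `min_filter_level` are
#' flagged in the `status` column (`low_level`), not deleted.
#'
#' @param anchors anchor data.frame from [collect_anchors()].
#' @param reads read data.frame (for clip stacks).
#' @param reference named character vector of chromosomes.
#' @param params a [calling_params()].
#' @return call data.frame (one row per retained locus).
#' @export
call_insertions <- function(anchors, reads, reference,
                            params = calling_params()) {
  clusters <- cluster_anchors(anchors, params)
  calls <- NULL
  clip_idx <- !reads$unmapped &
    (reads$clip_left >= 10L | reads$clip_right >= 10L)
  clips <- reads[clip_idx, , drop = FALSE]
  for (cl in clusters) {
    call <- call_breakpoint(cl, params)
    if (is.null(call)) next
    ch_clips <- clips[clips$chrom == cl$chrom, , drop = FALSE]
    tsd <- detect_tsd(call, ch_clips, reference, params)
    if (!is.null(tsd)) {
      call$tsd_start <- tsd$tsd_start
      call$tsd_end <- tsd$tsd_end
      call$tsd_seq <- tsd$tsd_seq
    }
    clip_pos <- c(ch_clips$end[ch_clips$clip_right >= 10L],
                  ch_clips$pos[ch_clips$clip_left >= 10L])
    call$filter_level <- assign_filter_level(call, cl, clip_pos, params)
    calls <- rbind(calls, call)
  }
  if (is.null(calls)) {
    return(validate_calls(data.frame(
      chrom = character(0), breakpoint_pos = integer(0),
      support_5p = integer(0), support_3p = integer(0),
      filter_level = integer(0), tsd_start = integer(0),
      tsd_end = integer(0), tsd_seq = character(0), status = character(0),
      stringsAsFactors = FALSE)))
  }
  calls$status <- ifelse(calls$filter_level < params$min_filter_level,
                         "low_level", "LTR")
  merge_calls(calls, params)
}
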