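# LTR classification: progressive multiple alignment, Kimura 3-parameter
# distances, neighbor-joining clustering into the LTR-A / LTR-B families,
# U3 tandem-repeat detection, subtype assignment (A1/A2/B1/B2/B3) and
# PERV A/B/C typing against a pol-region panel.

#' Progressive multiple sequence alignment
#'
#' Guide tree from 6-mer count distances (UPGMA), profiles merged by global
#' alignment with affine gaps (match +1, mismatch -1, gap open -4, gap
#' extend -1). Deterministic.
#'
#' @param seqs named character vector of sequences.
#' @return object of class `msa`: list with `names`, `rows` (aligned
#'   sequences, gap character `-`, input order), `width`.
#' @export
align_progressive <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n == 1)
    return(structure(list(names = names(seqs), rows = unname(seqs),
                          width = nchar(seqs[[1]])), class = "msa"))
  kf <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(gsub("[^ACGT]", "A", toupper(seqs))), 6)
  kf <- kf / pmax(rowSums(kf), 1)
  hc <- stats::hclust(stats::dist(kf), method = "average")
  # each node holds a sub-alignment (list of row indices + aligned strings)
  nodes <- lapply(seq_len(n), function(i)
    list(idx = i, rows = toupper(unname(seqs[i]))))
  inner <- vector("list", nrow(hc$merge))
  getn <- function(k) if (k < 0) nodes[[-k]] else inner[[k]]
  for (m in seq_len(nrow(hc$merge))) {
    a <- getn(hc$merge[m, 1]); b <- getn(hc$merge[m, 2])
    inner[[m]] <- merge_alignments(a, b)
  }
  final <- inner[[nrow(hc$merge)]]
  ord <- order(final$idx)
  structure(list(names = names(seqs), rows = final$rows[ord],
                 width = nchar(final$rows[1])), class = "msa")
}

profile_freq <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  f <- vapply(seq_len(ncol(mat)), function(j) {
    tabulate(match(mat[, j], DNA_BASES), 4L)
  }, integer(4))
  matrix(f / length(rows), nrow = 4)
}

merge_alignments <- function(a, b) {
  ops <- C_profile_align(profile_freq(a$rows), profile_freq(b$rows),
                         1, -1, 4, 1)
  expand <- function(rows, take) {
    n <- nchar(rows[1])
    src <- integer(length(take))
    k <- 0L
    for (t in seq_along(take)) {
      if (take[t]) { k <- k + 1L; src[t] <- k } else src[t] <- 0L
    }
    chars <- strsplit(rows, "", fixed = TRUE)
    vapply(chars, function(ch)
      paste(ifelse(src == 0L, "-", ch[pmax(src, 1L)]), collapse = ""),
      character(1))
  }
  list(idx = c(a$idx, b$idx),
       rows = c(expand(a$rows, ops != 2L), expand(b$rows, ops != 1L)))
}

#' Degap an alignment row
#' @param row aligned sequence string.
#' @return the input sequence without gap characters.
#' @export
degap <- function(row) gsub("-", "", row, fixed = TRUE)

#' Kimura three-parameter distance between two aligned rows
#'
#' Columns with a gap or ambiguity code in either row are excluded. With P
#' the transition proportion, Q the A:T/G:C transversion proportion and R
#' the A:C/G:T transversion proportion,
#' `d = -(1/4) ln[(1-2P-2Q)(1-2P-2R)(1-2Q-2R)]`. When any factor is
#' non-positive the distance is saturated and reported as `ceiling` with
#' attribute `saturated`.
#'
#' @param row_a,row_b aligned rows of equal length.
#' @param ceiling distance reported for saturated pairs.
#' @return numeric distance (substitutions/site).
#' @export
k3p_distance <- function(row_a, row_b, ceiling = 5.0) {
  a <- strsplit(toupper(row_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(row_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("rows must be aligned to equal length", call. = FALSE)
  keep <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(keep)
  if (n == 0) stop("no comparable columns between rows", call. = FALSE)
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  pair <- paste0(pmin(a, b), pmax(a, b))[diff]
  P <- sum(pair %in% c("AG", "CT")) / n   # transitions
  Q <- sum(pair %in% c("AT", "CG")) / n   # A<->T / G<->C transversions
  R <- sum(pair %in% c("AC", "GT")) / n   # A<->C / G<->T transversions
  f <- c(1 - 2 * P - 2 * Q, 1 - 2 * P - 2 * R, 1 - 2 * Q - 2 * R)
  if (any(f <= 0)) {
    return(structure(ceiling, saturated = TRUE))
  }
  structure(-0.25 * sum(log(f)), saturated = FALSE)
}

#' Pairwise K3P distance matrix over an alignment
#'
#' @param msa an `msa` object from [align_progressive()].
#' @param ceiling saturation ceiling passed to [k3p_distance()].
#' @return list with `dist` (symmetric matrix, zero diagonal) and
#'   `saturated` (logical matrix).
#' @export
k3p_matrix <- function(msa, ceiling = 5.0) {
  n <- length(msa$rows)
  d <- matrix(0, n, n, dimnames = list(msa$names, msa$names))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        v <- k3p_distance(msa$rows[i], msa$rows[j], ceiling)
        d[i, j] <- d[j, i] <- as.numeric(v)
        sat[i, j] <- sat[j, i] <- isTRUE(attr(v, "saturated"))
      }
    }
  }
  list(dist = d, saturated = sat)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ (Q-matrix minimization). Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch.
#'
#' @param dist symmetric distance matrix with taxon names, >= 3 taxa.
#' @param saturated optional logical matrix; an error is raised when every
#'   off-diagonal entry is saturated.
#' @return an [ape::nj()]-style `phylo` tree.
#' @export
nj_tree <- function(dist, saturated = NULL) {
  if (nrow(dist) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!is.null(saturated) &&
      all(saturated[upper.tri(saturated)]))
    stop("all pairwise distances are saturated", call. = FALSE)
  tree <- ape::nj(stats::as.dist(dist))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sib)) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Detect fixed-period tandem repeats
#'
#' For each unit length every phase is scanned: a seed window extends into
#' a tandem array while the next block matches the running consensus with
#' at most `max_unit_mismatch` mismatches. Arrays reaching `min_copies`
#' full copies are reported; overlapping arrays of the same unit length are
#' deduplicated keeping the longest.
#'
#' @param seq DNA sequence.
#' @param unit_lengths integer vector of repeat periods to scan.
#' @param min_copies minimum number of full tandem copies.
#' @param max_unit_mismatch mismatch tolerance per copy against the running
#'   consensus.
#' @return data.frame: unit_length, copies, start, end, consensus,
#'   mean_identity.
#' @export
detect_repeats <- function(seq, unit_lengths = c(18L, 21L), min_copies = 2L,
                           max_unit_mismatch = 3L) {
  b <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
  L <- length(b)
  if (L < 2 * min(unit_lengths))
    stop("sequence shorter than two repeat units", call. = FALSE)
  b0 <- b
  b0[is.na(b0)] <- 0L
  out <- list()
  for (u in as.integer(unit_lengths)) {
    if (L < 2 * u) next
    cands <- C_tandem_scan(b0, u, as.integer(min_copies),
                           as.integer(max_unit_mismatch))
    if (nrow(cands) == 0) next
    # equal-copy candidates at shifted phases can pass the mismatch budget
    # across the array boundary; prefer the cleanest phase, then leftmost
    ord <- order(-cands[, "copies"], cands[, "mism"], cands[, "start"])
    kept_iv <- NULL
    for (k in ord) {
      s <- cands[k, "start"]; copies <- cands[k, "copies"]
      iv <- c(s, s + copies * u - 1L)
      if (!is.null(kept_iv) &&
          any(iv[1] <= kept_iv[, 2] & iv[2] >= kept_iv[, 1])) next
      kept_iv <- rbind(kept_iv, iv)
      # rebuild the per-column counts for the kept array's consensus
      blocks <- matrix(b[s:(s + copies * u - 1L)], nrow = u)
      counts <- vapply(seq_len(u), function(r)
        tabulate(blocks[r, ], 4L), integer(4))
      cons <- paste(DNA_BASES[max.col(t(counts), ties.method = "first")],
                    collapse = "")
      out[[length(out) + 1L]] <- data.frame(
        unit_length = u, copies = copies, start = iv[1], end = iv[2],
        consensus = cons,
        mean_identity = if (copies > 1)
          1 - cands[k, "mism"] / ((copies - 1) * u) else 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(unit_length = integer(0), copies = integer(0),
                      start = integer(0), end = integer(0),
                      consensus = character(0), mean_identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_length), , drop = FALSE]
}

#' Subtype classifier configuration
#'
#' @param tier_b1,tier_b2 copy-number tier boundaries: total 18+21 copies
#'   up to `tier_b1` is B1, up to `tier_b2` B2, above B3.
#' @param min_copies minimum full copies for an array to count.
#' @param max_unit_mismatch per-copy mismatch tolerance for 18/21-bp arrays.
#' @param sub_units candidate unit lengths for A-type sub-repeats.
#' @param sub_max_mismatch mismatch tolerance for sub-repeat arrays (exact
#'   by default: short units match random sequence too easily otherwise).
#' @param u3_fallback U3 fraction of the LTR used when no TATA box is found.
#' @param u3_slack how far past the U3 boundary an array may extend.
#' @param auto_orient consider both strands and classify the better-oriented
#'   one (TATA box present, then more arrays in U3).
#' @return list of configuration values.
#' @export
subtype_config <- function(tier_b1 = 4L, tier_b2 = 6L, min_copies = 2L,
                           max_unit_mismatch = 3L, sub_units = 8:15,
                           sub_max_mismatch = 0L, u3_fallback = 0.65,
                           u3_slack = 10L, auto_orient = TRUE) {
  list(tier_b1 = tier_b1, tier_b2 = tier_b2, min_copies = min_copies,
       max_unit_mismatch = max_unit_mismatch, sub_units = sub_units,
       sub_max_mismatch = sub_max_mismatch, u3_fallback = u3_fallback,
       u3_slack = u3_slack, auto_orient = auto_orient)
}

#' Locate the U3 region of an LTR
#'
#' U3 runs from the LTR start to the base before the TATA box, located as
#' the first `TATAWA` motif in the 3' half of the sequence; without a match
#' U3 defaults to the first `u3_fallback` fraction of the LTR.
#'
#' @param seq LTR sequence.
#' @param config a [subtype_config()].
#' @return integer vector `c(start, end)` (1-based inclusive).
#' @export
u3_region <- function(seq, config = subtype_config()) {
  L <- nchar(seq)
  half <- as.integer(floor(L / 2)) + 1L
  m <- regexpr("TATA[AT]A", substr(toupper(seq), half, L))
  if (m > 0) c(1L, half + as.integer(m) - 2L)
  else c(1L, as.integer(floor(config$u3_fallback * L)))
}

repeats_in_u3 <- function(seq, u3, units, min_copies, max_mism, config) {
  reps <- detect_repeats(seq, units, min_copies, max_mism)
  reps[reps$start >= u3[1] & reps$end <= u3[2] + config$u3_slack, ,
       drop = FALSE]
}

# Orientation score used when auto_orient is on: TATA box found, then total
# full 18/21 copies in U3, then sub-repeat arrays in U3. All components are
# computed per physical strand, so the choice is strand-symmetric; the
# final tie-break (lexicographically smaller sequence) keeps
# classify(seq) == classify(revcomp(seq)).
orient_score <- function(seq, config) {
  u3 <- u3_region(seq, config)
  tata <- as.integer(regexpr("TATA[AT]A",
                             substr(toupper(seq),
                                    floor(nchar(seq) / 2) + 1, nchar(seq))) > 0)
  full <- repeats_in_u3(seq, u3, c(18L, 21L), config$min_copies,
                        config$max_unit_mismatch, config)
  sub <- repeats_in_u3(seq, u3, config$sub_units, config$min_copies,
                       config$sub_max_mismatch, config)
  c(tata, sum(full$copies), nrow(sub))
}

#' Classify an LTR into subtype A1/A2/B1/B2/B3
#'
#' Major type B requires both an 18-bp and a 21-bp tandem array (>= 2 full
#' copies each) in U3; the minor B tier follows the total 18+21 copy
#' number. A-type LTRs are A2 when any shorter sub-repeat array (8-15 bp
#' unit, >= 2 copies) is present in U3, else A1.
#'
#' @param ltr_seq LTR sequence.
#' @param repeats optional precomputed [detect_repeats()] table (restricted
#'   to U3 by the caller); scanned internally when `NULL`.
#' @param config a [subtype_config()].
#' @return list with `major`, `minor`, `evidence` (the repeat table used),
#'   `u3`, `oriented_seq`.
#' @export
classify_subtype <- function(ltr_seq, repeats = NULL,
                             config = subtype_config()) {
  seq <- toupper(ltr_seq)
  if (config$auto_orient && is.null(repeats)) {
    rc <- revcomp(seq)
    sf <- orient_score(seq, config)
    sr <- orient_score(rc, config)
    cmp <- c(sign(sf - sr), if (seq <= rc) 1 else -1)
    first <- cmp[cmp != 0][1]
    if (!is.na(first) && first < 0) seq <- rc
  }
  u3 <- u3_region(seq, config)
  if (is.null(repeats)) {
    repeats <- repeats_in_u3(seq, u3, c(18L, 21L), config$min_copies,
                             config$max_unit_mismatch, config)
  }
  n18 <- sum(repeats$copies[repeats$unit_length == 18L])
  n21 <- sum(repeats$copies[repeats$unit_length == 21L])
  if (n18 >= config$min_copies && n21 >= config$min_copies) {
    total <- n18 + n21
    minor <- if (total <= config$tier_b1) "B1"
      else if (total <= config$tier_b2) "B2" else "B3"
    return(list(major = "B", minor = minor, evidence = repeats, u3 = u3,
                oriented_seq = seq))
  }
  sub <- repeats_in_u3(seq, u3, config$sub_units, config$min_copies,
                       config$sub_max_mismatch, config)
  list(major = "A", minor = if (nrow(sub) > 0) "A2" else "A1",
       evidence = sub, u3 = u3, oriented_seq = seq)
}

#' Type an element against the PERV pol panel
#'
#' The best local-alignment hit against the typed pol-region panel decides
#' the type; `unknown` when the best qualifying hit falls below
#' `min_identity`, is shorter than `min_hit_length`, or the top two types
#' tie within `tie_margin` identity.
#'
#' @param element_seq element (or contig) sequence.
#' @param panel named character vector of typed references; names carry the
#'   type as `PERV-A` / `PERV-B` / `PERV-C` (or bare `A`/`B`/`C`).
#' @param min_identity identity floor.
#' @param min_hit_length minimum alignment length for a qualifying hit.
#' @param tie_margin identity margin under which the call is ambiguous.
#' @return list with `type` (`A`, `B`, `C` or `unknown`), `identity`,
#'   `length`.
#' @export
classify_perv_type <- function(element_seq, panel, min_identity = 0.80,
                               min_hit_length = 50L, tie_margin = 0.005) {
  if (length(panel) == 0) stop("typing panel is empty", call. = FALSE)
  types <- sub("^PERV-", "", names(panel))
  if (!all(types %in% c("A", "B", "C")))
    stop("panel entries must be labelled A, B or C", call. = FALSE)
  hits <- lapply(seq_along(panel), function(i) {
    h_f <- local_align(element_seq, panel[[i]])
    h_r <- local_align(revcomp(element_seq), panel[[i]])
    h <- if (h_f$score >= h_r$score) h_f else h_r
    data.frame(type = types[i], score = h$score, identity = h$identity,
               length = h$length, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  best_by_type <- do.call(rbind, lapply(split(hits, hits$type), function(h)
    h[order(-h$score), ][1, ]))
  best_by_type <- best_by_type[order(-best_by_type$score), , drop = FALSE]
  qual <- best_by_type[best_by_type$identity >= min_identity &
                       best_by_type$length >= min_hit_length, , drop = FALSE]
  if (nrow(qual) == 0)
    return(list(type = "unknown", identity = best_by_type$identity[1],
                length = best_by_type$length[1]))
  if (nrow(qual) >= 2 &&
      abs(qual$identity[1] - qual$identity[2]) < tie_margin)
    return(list(type = "unknown", identity = qual$identity[1],
                length = qual$length[1]))
  list(type = qual$type[1], identity = qual$identity[1],
       length = qual$length[1])
}

#' Classify a set of reconstructed LTRs
#'
#' Runs subtype classification per sequence and, for three or more
#' sequences, builds the progressive alignment, K3P distance matrix and NJ
#' tree.
#'
#' @param seqs named character vector of LTR sequences.
#' @param config a [subtype_config()].
#' @return list with `table` (name, major, minor, n18, n21, u3_start,
#'   u3_end), `alignment`, `dist`, `tree` (NULL when fewer than 3
#'   sequences).
#' @export
classify_ltrs <- function(seqs, config = subtype_config()) {
  calls <- lapply(seqs, classify_subtype, config = config)
  tab <- data.frame(
    name = names(seqs),
    major = vapply(calls, `[[`, character(1), "major"),
    minor = vapply(calls, `[[`, character(1), "minor"),
    n18 = vapply(calls, function(x)
      sum(x$evidence$copies[x$evidence$unit_length == 18L]), numeric(1)),
    n21 = vapply(calls, function(x)
      sum(x$evidence$copies[x$evidence$unit_length == 21L]), numeric(1)),
    u3_start = vapply(calls, function(x) x$u3[1], integer(1)),
    u3_end = vapply(calls, function(x) x$u3[2], integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  aln <- NULL; dm <- NULL; tree <- NULL
  if (length(seqs) >= 3) {
    aln <- align_progressive(
      stats::setNames(vapply(calls, `[[`, character(1), "oriented_seq"),
                      names(seqs)))
    dm <- k3p_matrix(aln)
    tree <- tryCatch(nj_tree(dm$dist, dm$saturated), error = function(e) NULL)
  }
  list(table = tab, alignment = aln, dist = dm, tree = tree)
}
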