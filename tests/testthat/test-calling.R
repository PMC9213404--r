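anchor_frame <- function(pos, side = "5p", chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             strand = ifelse(side == "5p", "+", "-"), kind = "mate_hit",
             element = "LTR_B1", identity = 1.0, length = 150L,
             side = side, qname = paste0("q", seq_along(pos)),
             stringsAsFactors = FALSE)
}

test_that("anchor clustering chains within the window", {
  params <- calling_params(cluster_window = 400L)
  two <- anchor_frame(c(1000L, 11000L))
  expect_length(cluster_anchors(two, params), 2)
  chain <- anchor_frame(c(5000L, 5050L, 5090L))
  cl <- cluster_anchors(chain, params)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$n_anchors, 3)
  expect_equal(cl[[1]]$interval, c(5000L, 5090L))
})

test_that("clustering equals an exhaustive single-linkage oracle", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    anc <- anchor_frame(sort(sample(1e5, n)),
                        side = sample(c("5p", "3p"), n, replace = TRUE))
    w <- sample(c(200L, 450L), 1)
    clusters <- cluster_anchors(anc, calling_params(cluster_window = w))
    got <- lapply(clusters, function(cl)
      sort(c(cl$fwd$pos, cl$rev$pos)))
    want_id <- cluster_oracle(anc$chrom, anc$pos, w)
    want <- lapply(split(anc$pos, want_id), sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("calls require the minimum support and sit between sides", {
  params <- calling_params(min_support = 10L)
  low <- cluster_anchors(anchor_frame(5000L + 0:8 * 10L), params)[[1]]
  expect_null(call_breakpoint(low, params))

  anc <- rbind(anchor_frame(5000L + 0:5 * 8L, "5p"),
               anchor_frame(5100L + 0:5 * 8L, "3p"))
  cl <- cluster_anchors(anc, params)[[1]]
  call <- call_breakpoint(cl, params)
  expect_equal(call$support_5p, 6L)
  expect_equal(call$support_3p, 6L)
  # midpoint of innermost 5' end (5040) and innermost 3' start (5100)
  expect_equal(call$breakpoint_pos, 5070L)
})

test_that("filter levels add evidence bonuses onto a base of five", {
  params <- calling_params()
  anc <- rbind(anchor_frame(5000L + 0:5 * 8L, "5p"),
               anchor_frame(5100L + 0:5 * 8L, "3p"))
  cl <- cluster_anchors(anc, params)[[1]]
  call <- call_breakpoint(cl, params)
  # two-sided, tight, with two clip reads at the breakpoint: all bonuses
  expect_equal(assign_filter_level(call, cl, rep(call$breakpoint_pos, 2),
                                   params), 8L)
  # no clip support
  expect_equal(assign_filter_level(call, cl, integer(0), params), 7L)

  one_sided <- cluster_anchors(anchor_frame(5000L + 0:11 * 60L, "5p"),
                               params)[[1]]
  call1 <- call_breakpoint(one_sided, params)
  # one-sided, wide interval, no clips: no bonuses
  expect_equal(assign_filter_level(call1, one_sided, integer(0), params),
               5L)
})

test_that("call merging keeps the best call per 500-bp chain", {
  base <- data.frame(chrom = "chr1", support_5p = 10L, support_3p = 10L,
                     tsd_start = NA_integer_, tsd_end = NA_integer_,
                     tsd_seq = NA_character_, status = "LTR",
                     stringsAsFactors = FALSE)
  two <- rbind(cbind(base, breakpoint_pos = 1000L, filter_level = 8L),
               cbind(base, breakpoint_pos = 1120L, filter_level = 7L))
  merged <- merge_calls(two, calling_params())
  expect_equal(nrow(merged), 1)
  expect_equal(merged$filter_level, 8L)

  apart <- rbind(cbind(base, breakpoint_pos = 1000L, filter_level = 7L),
                 cbind(base, breakpoint_pos = 1501L, filter_level = 7L))
  expect_equal(nrow(merge_calls(apart, calling_params())), 2)
})

test_that("merging equals the exhaustive interval-graph oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    calls <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      breakpoint_pos = sort(sample(20000L, n)),
      support_5p = sample(5:40, n, replace = TRUE),
      support_3p = sample(5:40, n, replace = TRUE),
      filter_level = sample(5:8, n, replace = TRUE),
      tsd_start = NA_integer_, tsd_end = NA_integer_,
      tsd_seq = NA_character_, status = "LTR", stringsAsFactors = FALSE)
    got <- merge_calls(calls, calling_params())
    want <- nrltr:::sort_by_locus(merge_oracle(calls, 500L),
                                  "breakpoint_pos")
    expect_equal(got$breakpoint_pos, want$breakpoint_pos)
    expect_equal(got$filter_level, want$filter_level)
  }
})

test_that("TSD detection reads the duplication off the clip stacks", {
  set.seed(41)
  refseq <- random_dna_str(3000)
  substr(refseq, 1501, 1504) <- "CTAT"
  ref <- c(chr1 = refseq)
  call <- data.frame(chrom = "chr1", breakpoint_pos = 1502L)
  # 5' reads clipped right, alignments ending at 1504; 3' reads clipped
  # left, starting at 1501: a 4-bp overlap
  clip_reads <- make_reads(
    list(qname = "a", pos = 1375L, cigar = "130M20S"),
    list(qname = "b", pos = 1385L, cigar = "120M30S"),
    list(qname = "c", pos = 1501L, cigar = "40S110M"),
    list(qname = "d", pos = 1501L, cigar = "25S125M")
  )
  tsd <- detect_tsd(call, clip_reads, ref)
  expect_equal(tsd$tsd_start, 1501L)
  expect_equal(tsd$tsd_end, 1504L)
  expect_identical(tsd$tsd_seq, "CTAT")
  # the sequence always comes from the reference over the interval
  expect_identical(tsd$tsd_seq, substr(ref[[1]], 1501, 1504))

  # stacks overlapping by 6 bp are rejected
  clip6 <- make_reads(
    list(qname = "a", pos = 1375L, cigar = "132M18S"),
    list(qname = "b", pos = 1385L, cigar = "122M28S"),
    list(qname = "c", pos = 1501L, cigar = "40S110M"),
    list(qname = "d", pos = 1501L, cigar = "25S125M")
  )
  expect_null(detect_tsd(call, clip6, ref))

  # a lone read per stack is not enough
  expect_null(detect_tsd(call, clip_reads[c(1, 3), ], ref))
})

test_that("planted TSDs are recovered exactly on simulated data", {
  s <- shared_sim()
  calls <- shared_calls()
  expect_equal(nrow(calls), nrow(s$truth))
  hit <- vapply(seq_len(nrow(s$truth)), function(k) {
    m <- calls[calls$chrom == s$truth$chrom[k] &
               abs(calls$breakpoint_pos - s$truth$pos[k]) <= 10, ]
    nrow(m) == 1 && m$tsd_seq == s$truth$tsd_seq[k] &&
      m$tsd_start == s$truth$pos[k] && m$filter_level >= 7
  }, logical(1))
  expect_true(all(hit))
})

test_that("calling is deterministic", {
  s <- shared_sim()
  again <- call_insertions(shared_anchors(), s$reads, s$reference)
  expect_identical(shared_calls(), again)
})
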