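test_that("greedy overlap merging respects the minimum overlap", {
  set.seed(51)
  donor <- random_dna_str(300)
  a <- substr(donor, 1, 150)
  b60 <- substr(donor, 91, 240)    # 60-base overlap with a
  contigs <- assemble(c(a, b60))
  expect_length(contigs, 1)
  expect_equal(nchar(contigs[[1]]$sequence), 240)
  expect_identical(contigs[[1]]$sequence, substr(donor, 1, 240))

  b39 <- substr(donor, 112, 261)   # 39-base overlap: below min_overlap
  expect_length(assemble(c(a, b39)), 2)
})

test_that("tiling reads assemble into the exact donor substring", {
  set.seed(52)
  donor <- random_dna_str(700)
  starts <- seq(1, 551, by = 50)
  reads <- substring(donor, starts, starts + 149)
  # some reads arrive reverse-complemented
  reads[c(3, 7)] <- revcomp(reads[c(3, 7)])
  contigs <- assemble(reads)
  expect_length(contigs, 1)
  seq <- contigs[[1]]$sequence
  expect_true(seq == donor || seq == revcomp(donor))
  expect_equal(contigs[[1]]$n_reads, length(reads))
})

test_that("assembly is invariant to read order", {
  set.seed(53)
  donor <- random_dna_str(500)
  starts <- sample(1:350, 30, replace = TRUE)
  reads <- substring(donor, starts, starts + 149)
  c1 <- assemble(reads)
  c2 <- assemble(sample(reads))
  expect_identical(lapply(c1, `[[`, "sequence"),
                   lapply(c2, `[[`, "sequence"))
})

test_that("junction reads are extracted on the correct side", {
  set.seed(54)
  reads <- make_reads(
    list(qname = "l", pos = 1321L, cigar = "150M"),          # ends 1470
    list(qname = "c5", pos = 1405L, cigar = "100M50S"),      # ends 1504
    list(qname = "c3", pos = 1501L, cigar = "60S90M"),       # starts 1501
    list(qname = "r", pos = 1530L, cigar = "150M"),
    list(qname = "far", pos = 1655L, cigar = "150M")         # 151 bp away
  )
  sets <- extract_junction_reads(reads, "chr1", 1501L, 1504L)
  expect_length(sets$reads_5p, 2)   # l and c5
  expect_length(sets$reads_3p, 2)   # c3 and r
  # the read ending 30 bp left of the TSD belongs to the 5' set
  reads30 <- make_reads(list(qname = "x", pos = 1322L, cigar = "150M"))
  expect_length(extract_junction_reads(reads30, "chr1", 1501L,
                                       1504L)$reads_5p, 1)
})

test_that("every junction-spanning truth read lands on its side", {
  s <- shared_sim()
  tr <- s$truth[1, ]
  tsd_start <- tr$pos; tsd_end <- tr$pos + tr$tsd_len - 1L
  sets <- extract_junction_reads(s$reads, tr$chrom, tsd_start, tsd_end)
  ch <- s$reads[s$reads$chrom == tr$chrom, ]
  right_clipped <- ch[!ch$unmapped & ch$clip_right >= 10 &
                      ch$end == tsd_end, ]
  left_clipped <- ch[!ch$unmapped & ch$clip_left >= 10 &
                     ch$pos == tsd_start, ]
  expect_true(all(right_clipped$seq %in% sets$reads_5p))
  expect_true(all(left_clipped$seq %in% sets$reads_3p))
})

test_that("junction analysis splits contigs into reference and element", {
  set.seed(55)
  s <- shared_sim()
  lib <- s$library$ltr_library
  refseq <- s$reference[[1]]
  bp <- 50000L
  contig <- paste0(substr(refseq, bp - 149L, bp),
                   substr(lib[["LTR_B3"]], 1, 300))
  call <- data.frame(chrom = "chr1", breakpoint_pos = bp,
                     tsd_start = NA_integer_, tsd_end = NA_integer_)
  jc <- analyze_junction(nrltr:::new_contig(contig,
                                            nrltr:::seq_counts(contig), 3L),
                         s$reference, call, lib)
  expect_identical(jc$junction_side, "5p")
  expect_identical(jc$nonref_hit$element, "LTR_B3")
  expect_equal(jc$nonref_hit$identity, 1.0)

  # a contig fully matching the reference has no non-reference part
  refonly <- substr(refseq, bp - 299L, bp)
  expect_null(analyze_junction(
    nrltr:::new_contig(refonly, nrltr:::seq_counts(refonly), 3L),
    s$reference, call, lib))
})

test_that("reconstruction spans TSD to TSD and flags one-sided loci", {
  s <- shared_sim()
  calls <- shared_calls()
  recs <- reconstruct_insertions(s$reads, calls, s$reference,
                                 s$library$ltr_library)
  expect_length(recs, nrow(s$truth))
  for (r in recs) {
    tr <- s$truth[s$truth$chrom == r$chrom &
                  abs(s$truth$pos - r$breakpoint_pos) <= 10, ]
    expect_identical(r$completeness, "both")
    expect_identical(r$sequence, tr$ltr_truth)
    expect_equal(r$overlap_mismatches, 0L)
    expect_identical(r$tsd5, r$tsd3)
  }

  # with only a 5' junction contig the locus is reported one-sided
  one <- reconstruct_ltr(j5 = list(nonref_seq = "ACGTACGT",
                                   nonref_counts = nrltr:::seq_counts("ACGTACGT"),
                                   nonref_hit = list(element = "LTR_B1"),
                                   contig = list(n_reads = 5L)),
                         j3 = NULL, tsd = NULL,
                         call = data.frame(chrom = "chr1",
                                           breakpoint_pos = 100L))
  expect_identical(one$completeness, "5p_only")
  expect_null(one$tsd3)
})

test_that("a mutation between provirus LTR copies surfaces as a mismatch", {
  lib <- element_library(101L)
  ltr <- lib$ltr_library[["LTR_B2"]]
  # plant one substitution mid-LTR in the 3' copy only
  mid <- 320L
  ltr_mut <- ltr
  substr(ltr_mut, mid, mid) <- setdiff(c("A", "C", "G", "T"),
                                       substr(ltr, mid, mid))[1]
  internal <- build_internal("B", 7000L, lib$panel, seed = 4L)
  lib$elements[["PV_MUT"]] <- build_provirus(ltr, internal, ltr_mut)
  lib$meta <- rbind(lib$meta, data.frame(
    element_id = "PV_MUT", kind = "provirus", subtype = "B2",
    perv_type = "B", ltr_length = nchar(ltr),
    element_length = nchar(lib$elements[["PV_MUT"]])))
  lib$ltr_units <- c(lib$ltr_units, PV_MUT = ltr)

  ref <- generate_reference(genome_spec(1, 40000L, 0.41, seed = 61L))
  ev <- data.frame(chrom = "chr1", position = 20000L,
                   element_kind = "provirus", element_id = "PV_MUT",
                   orientation = "+", tsd_length = 4L)
  ds <- insert_elements(ref, ev, lib)
  sim <- simulate_reads(ds, readsim_params(coverage = 50, seed = 62L))
  d <- withr::local_tempdir()
  reads <- read_sam(write_simulation(sim, d)["sam"])
  anc <- collect_anchors(reads, lib$ltr_library)
  calls <- call_insertions(anc, reads, ref)
  expect_equal(nrow(calls), 1)
  recs <- reconstruct_insertions(reads, calls, ref, lib$ltr_library)
  expect_length(recs, 1)
  expect_identical(recs[[1]]$completeness, "both")
  expect_gte(recs[[1]]$overlap_mismatches, 1L)
})
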