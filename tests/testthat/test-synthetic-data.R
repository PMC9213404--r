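test_that("reference generation is seed-deterministic and GC-calibrated", {
  spec <- genome_spec(1, 100000L, 0.42, seed = 1L)
  expect_identical(generate_reference(spec), generate_reference(spec))

  at_only <- generate_reference(genome_spec(1, 10000L, 0, seed = 2L))
  expect_true(grepl("^[AT]+$", at_only[[1]]))

  big <- generate_reference(genome_spec(1, 1000000L, 0.5, seed = 7L))
  gc <- nrltr:::gc_fraction(big[[1]])
  expect_gte(gc, 0.49); expect_lte(gc, 0.51)

  expect_error(genome_spec(chrom_length = 500), ">= 10,000")
  expect_error(genome_spec(gc_fraction = 1.2), "gc_fraction")
})

test_that("built LTRs carry the requested U3 repeat structure", {
  specs <- default_ltr_specs(11L)
  b1 <- build_ltr(specs$B1)
  expect_setequal(unique(b1$repeats$unit_length), c(18L, 21L))
  found <- detect_repeats(b1$sequence)
  expect_true(any(found$unit_length == 18) && any(found$unit_length == 21))

  a1 <- build_ltr(specs$A1)
  found_a <- detect_repeats(a1$sequence)
  expect_true(all(found_a$copies < 2) || nrow(found_a) == 0)

  # round trip through the classifier for the highest-copy subtype
  b3 <- build_ltr(specs$B3)
  expect_identical(classify_subtype(b3$sequence)$minor, "B3")

  # repeats that cannot fit inside U3 are rejected
  too_big <- ltr_spec(560L, data.frame(unit_length = c(18L, 21L),
                                       copies = c(10L, 10L)), "B3",
                      seed = 1L)
  expect_error(build_ltr(too_big), "longer than the U3")
})

test_that("provirus assembly is additive and typable", {
  lib <- element_library(33L)
  ltr <- lib$ltr_library[["LTR_B2"]]
  internal <- build_internal("B", 7000L, lib$panel, seed = 2L)
  pv <- build_provirus(ltr, internal, ltr)
  expect_equal(nchar(pv), 2 * nchar(ltr) + 7000L)
  expect_error(build_provirus(ltr, "", ltr), "non-empty")

  ty <- classify_perv_type(pv, lib$panel)
  expect_identical(ty$type, "B")
})

test_that("insertion planting duplicates the target site on both sides", {
  set.seed(8)
  refseq <- random_dna_str(30000)
  pos <- 12001L
  substr(refseq, pos, pos + 3L) <- "CTAT"
  ref <- c(chr1 = refseq)
  lib <- element_library(101L)
  ev <- data.frame(chrom = "chr1", position = pos,
                   element_kind = "solo_ltr", element_id = "LTR_A1",
                   orientation = "+", tsd_length = 4L)
  ds <- insert_elements(ref, ev, lib)
  elem <- lib$elements[["LTR_A1"]]
  expect_identical(ds$truth$tsd_seq, "CTAT")
  # donor: ...CTAT | element | CTAT...
  left_end <- pos + 3L
  expect_identical(substr(ds$donor[[1]], pos, left_end), "CTAT")
  expect_identical(substr(ds$donor[[1]], left_end + 1L,
                          left_end + nchar(elem)), elem)
  expect_identical(substr(ds$donor[[1]], left_end + nchar(elem) + 1L,
                          left_end + nchar(elem) + 4L), "CTAT")

  # empty event list leaves the reference untouched
  none <- insert_elements(ref, ev[0, ], lib)
  expect_identical(none$donor, ref)

  # donor length = reference + sum(element + tsd)
  ref2 <- generate_reference(genome_spec(1, 60000L, 0.41, seed = 4L))
  ev2 <- sample_insertion_events(ref2, lib, 4, margin = 3000L, seed = 6L)
  ds2 <- insert_elements(ref2, ev2, lib)
  expect_equal(nchar(ds2$donor[[1]]),
               nchar(ref2[[1]]) + sum(ds2$truth$element_length) +
                 sum(ds2$truth$tsd_len))

  # reverse-orientation events insert the reverse complement
  ev3 <- ev; ev3$orientation <- "-"
  ds3 <- insert_elements(ref, ev3, lib)
  expect_identical(substr(ds3$donor[[1]], left_end + 1L,
                          left_end + nchar(elem)), revcomp(elem))

  # coordinate and overlap validation
  ev_bad <- ev; ev_bad$position <- 30000L
  expect_error(insert_elements(ref, ev_bad, lib), "beyond chromosome end")
  ev_twice <- rbind(ev, ev); ev_twice$position <- c(12001L, 12002L)
  expect_error(insert_elements(ref, ev_twice, lib), "overlapping")
})

test_that("read simulation matches coverage and junction truth", {
  s <- shared_sim()
  # pair count ~ coverage * genome / (2 * read length)
  dlen <- nchar(s$donor_set$donor[[1]])
  expected_pairs <- 40 * dlen / 300
  n_pairs <- nrow(s$simres$reads) / 2
  expect_lt(abs(n_pairs - expected_pairs) / expected_pairs, 0.05)

  # every soft-clipped truth record's clip boundary is a junction
  reads <- s$simres$reads
  clipped <- reads[!is.na(reads$junction), ]
  junctions <- c(s$truth$pos + s$truth$tsd_len - 1L, s$truth$pos)
  expect_gt(nrow(clipped), 0)
  expect_true(all(clipped$junction %in% junctions))

  # no proper-flagged record overlaps a junction interior
  ci <- nrltr:::cigar_info(reads$cigar)
  fl <- sam_flags(reads$flag)
  prop <- reads[fl$proper & !fl$unmapped, ]
  expect_true(all(grepl("^[0-9]+M$", prop$cigar)))
})

test_that("a donor without insertions yields only proper pairs", {
  ref <- generate_reference(genome_spec(1, 30000L, 0.41, seed = 21L))
  ds <- insert_elements(ref, data.frame(), nrltr::element_library(101L))
  sim <- simulate_reads(ds, readsim_params(coverage = 20, seed = 2L,
                                           fragment_sd = 1e-9))
  expect_true(all(sim$reads$truth_class == "proper"))
})

test_that("simulation outputs are byte-identical across runs", {
  ref <- generate_reference(genome_spec(1, 20000L, 0.41, seed = 31L))
  lib <- element_library(101L)
  ev <- sample_insertion_events(ref, lib, 1, margin = 6000L, seed = 32L)
  ds <- insert_elements(ref, ev, lib)
  p <- readsim_params(coverage = 10, seed = 33L, per_base_error = 0.001)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_simulation(simulate_reads(ds, p), d1)
  f2 <- write_simulation(simulate_reads(ds, p), d2)
  for (k in seq_along(f1)) {
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  }
})
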