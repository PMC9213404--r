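test_that("FASTA writing and reading round-trips, normalizes case", {
  set.seed(1)
  seqs <- c(a = random_dna_str(150), b = random_dna_str(70),
            c = random_dna_str(200))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  expect_identical(read_fasta(path), seqs)

  writeLines(c(">x", "acgtn"), path)
  expect_identical(unname(read_fasta(path)), "ACGTN")
})

test_that("FASTA edge cases: empty file, duplicates, bad characters", {
  path <- withr::local_tempfile(fileext = ".fasta")
  file.create(path)
  expect_length(read_fasta(path), 0)

  writeLines(c(">x", "ACGT", ">x", "GGGG"), path)
  expect_error(read_fasta(path), "duplicate")

  writeLines(c(">x", "ACZT"), path)
  expect_error(read_fasta(path), "non-IUPAC")
})

test_that("FASTQ pairs round-trip with /1 and /2 suffixes", {
  prefix <- file.path(withr::local_tempdir(), "rp")
  paths <- write_fastq_pairs(c("p1", "p2"), c("ACGT", "GGCC"),
                             c("TTTT", "CAGT"), prefix)
  r1 <- read_fastq(paste0(prefix, "_1.fastq"))
  r2 <- read_fastq(paste0(prefix, "_2.fastq"))
  expect_identical(r1, c(`p1/1` = "ACGT", `p2/1` = "GGCC"))
  expect_identical(r2, c(`p1/2` = "TTTT", `p2/2` = "CAGT"))
})

test_that("SAM flag decoding follows the specification", {
  f <- sam_flags(c(99L, 147L, 4L, 73L))
  # 99/147: proper FR pair, first mate forward, second reverse
  expect_true(all(f$paired[1:2]))
  expect_true(all(f$proper[1:2]))
  expect_false(f$rev[1]); expect_true(f$rev[2])
  expect_true(f$first[1]); expect_true(f$second[2])
  expect_true(f$unmapped[3])
  expect_true(f$first[4] && !f$unmapped[4] && f$munmapped[4])
})

test_that("CIGAR arithmetic exposes clips and aligned span", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    paste("r1", 0, "chr1", 1000, 60, "30S120M", "*", 0, 0,
          strrep("A", 150), "*", sep = "\t")
  ), path)
  reads <- read_sam(path)
  expect_equal(reads$clip_left, 30L)
  expect_equal(reads$clip_right, 0L)
  expect_equal(reads$pos, 1000L)
  expect_equal(reads$end, 1119L)
  expect_equal(attr(reads, "sq")$name, "chr1")
})

test_that("malformed SAM records are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:chr1\tLN:10000",
    paste("ok", 0, "chr1", 100, 60, "10M", "*", 0, 0, strrep("A", 10),
          "*", sep = "\t"),
    paste("bad", 0, "chr1", 200, 60, "20M", "*", 0, 0, strrep("A", 10),
          "*", sep = "\t")
  ), path)
  expect_error(read_sam(path), "line 3.*20 query bases.*10")
})

test_that("simulator SAM output parses and mates reunite", {
  s <- shared_sim()
  reads <- s$reads
  expect_equal(nrow(reads), nrow(s$simres$reads))
  paired <- nrltr:::pair_reads(reads)
  expect_equal(nrow(paired), nrow(reads))
  expect_true(all(table(paired$qname) == 2))
})

test_that("call tables round-trip field-identically", {
  set.seed(42)
  n <- 10
  tsd_len <- sample(4:5, n, replace = TRUE)
  tsd_start <- sort(sample(1e6, n))
  calls <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    breakpoint_pos = tsd_start + 1L,
    support_5p = sample(10:60, n), support_3p = sample(10:60, n),
    filter_level = sample(5:8, n, replace = TRUE),
    tsd_start = tsd_start, tsd_end = tsd_start + tsd_len - 1L,
    tsd_seq = vapply(tsd_len, random_dna_str, character(1)),
    status = "LTR", stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, path)
  back <- read_calls(path)
  expect_equal(back, nrltr:::sort_by_locus(calls, "breakpoint_pos"),
               ignore_attr = TRUE)
})

test_that("call validation enforces TSD and filter-level invariants", {
  call <- data.frame(chrom = "chr1", breakpoint_pos = 100L,
                     support_5p = 5L, support_3p = 6L, filter_level = 9L,
                     tsd_start = NA_integer_, tsd_end = NA_integer_,
                     tsd_seq = NA_character_, status = "LTR")
  expect_error(nrltr:::validate_calls(call), "filter_level")
  call$filter_level <- 8L
  call$tsd_start <- 90L  # start without end/seq
  expect_error(nrltr:::validate_calls(call), "all present or all absent")
  call$tsd_end <- 95L; call$tsd_seq <- "ACGTAC"  # 6 bp
  expect_error(nrltr:::validate_calls(call), "4 or 5")
})

test_that("TSD BED output is 0-based half-open", {
  # a 4-bp TSD reported at 1-based position 38,667,241 becomes
  # [38667240, 38667244) in BED coordinates
  call <- data.frame(chrom = "SSC1", breakpoint_pos = 38667242L,
                     support_5p = 20L, support_3p = 20L, filter_level = 8L,
                     tsd_start = 38667241L, tsd_end = 38667244L,
                     tsd_seq = "CTAT", status = "LTR")
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(call, path)
  line <- strsplit(readLines(path), "\t")[[1]]
  expect_identical(line[1:3], c("SSC1", "38667240", "38667244"))

  write_calls(call[0, ], path)
  expect_match(readLines(path)[1], "^#")   # header-only file
  expect_equal(nrow(read_calls(path)), 0)
})

test_that("writers order records deterministically by locus", {
  calls <- data.frame(
    chrom = c("chr2", "chr1", "chr1"),
    breakpoint_pos = c(50L, 900L, 100L),
    support_5p = 10L, support_3p = 10L, filter_level = 8L,
    tsd_start = NA_integer_, tsd_end = NA_integer_,
    tsd_seq = NA_character_, status = "LTR")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, path)
  back <- read_calls(path)
  expect_identical(back$breakpoint_pos, c(100L, 900L, 50L))
})
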