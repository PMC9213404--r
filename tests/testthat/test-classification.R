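test_that("progressive alignment handles identity and single gaps", {
  two <- align_progressive(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_identical(two$rows, c("ACGTACGT", "ACGTACGT"))

  gap <- align_progressive(c(a = "ACGTACGT", b = "ACGACGT"))
  expect_equal(gap$width, 8)
  m <- do.call(rbind, strsplit(gap$rows, ""))
  matches <- sum(m[1, ] == m[2, ] & m[1, ] != "-")
  expect_equal(matches, 7)
  expect_equal(sum(m == "-"), 1)

  single <- align_progressive(c(x = "ACGT"))
  expect_identical(single$rows, "ACGT")
})

test_that("degapping alignment rows returns the input sequences", {
  set.seed(71)
  seqs <- stats::setNames(
    vapply(sample(60:90, 21, replace = TRUE), random_dna_str, character(1)),
    paste0("s", 1:21))
  aln <- align_progressive(seqs)
  expect_true(all(nchar(aln$rows) == aln$width))
  expect_identical(vapply(aln$rows, degap, character(1), USE.NAMES = FALSE),
                   unname(seqs))
})

test_that("K3P distance matches its closed form", {
  r <- strrep("A", 100)
  expect_equal(as.numeric(k3p_distance(r, r)), 0)

  # 100 columns: 10 transitions, 5 A<->T/G<->C, 5 A<->C/G<->T
  ch <- rep("A", 100)
  ch[1:10] <- "G"; ch[11:15] <- "T"; ch[16:20] <- "C"
  d <- k3p_distance(r, paste(ch, collapse = ""))
  expect_equal(as.numeric(d), -0.25 * log(0.7 * 0.7 * 0.8))

  # symmetry over random pairs; gaps and N excluded
  set.seed(72)
  for (k in 1:10) {
    a <- random_dna_str(80); b <- mutate_seq(a, sample(5:25, 1))
    expect_equal(as.numeric(k3p_distance(a, b)),
                 as.numeric(k3p_distance(b, a)))
  }
  expect_error(k3p_distance("---N", "AC-T"), "no comparable columns")
})

test_that("K3P reduces to the Jukes-Cantor form when classes are equal", {
  # P = Q = R = p/3 with p = 0.2: d = -(3/4) ln(1 - 4p/3)
  n <- 120
  ch <- rep("A", n)
  ch[1:8] <- "G"; ch[9:16] <- "T"; ch[17:24] <- "C"
  d <- as.numeric(k3p_distance(strrep("A", n), paste(ch, collapse = "")))
  p <- 24 / n
  expect_equal(d, -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
})

test_that("K3P agrees with an independent reference implementation", {
  set.seed(73)
  for (k in 1:5) {
    a <- random_dna_str(300)
    b <- mutate_seq(a, sample(20:80, 1))
    m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
    rownames(m) <- c("a", "b")
    want <- as.numeric(ape::dist.dna(ape::as.DNAbin(tolower(m)),
                                     model = "K81"))
    expect_equal(as.numeric(k3p_distance(a, b)), want, tolerance = 1e-12)
  }
})

test_that("saturated pairs are flagged and capped", {
  a <- strrep("A", 40); g <- strrep("G", 40)
  d <- k3p_distance(a, g)
  expect_true(attr(d, "saturated"))
  expect_equal(as.numeric(d), 5.0)
})

test_that("NJ recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:3):1);")
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  got <- nj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), got)), 0)
  back <- ape::cophenetic.phylo(got)[rownames(D), colnames(D)]
  expect_equal(back, D, tolerance = 1e-12)

  # three taxa: the unique topology with three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  tip_edge <- t3$edge[, 2] <= 3
  lens <- stats::setNames(t3$edge.length[tip_edge],
                          t3$tip.label[t3$edge[tip_edge, 2]])
  expect_equal(lens[["a"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["b"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["c"]], (4 + 5 - 3) / 2)

  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
  sat <- matrix(TRUE, 3, 3)
  expect_error(nj_tree(d3, sat), "saturated")
})

test_that("NJ separates two sequence families into two clusters", {
  set.seed(74)
  ancA <- random_dna_str(600)
  ancB <- random_dna_str(600)
  seqs <- c(
    stats::setNames(vapply(1:4, function(i) mutate_seq(ancA, 8),
                           character(1)), paste0("A", 1:4)),
    stats::setNames(vapply(1:4, function(i) mutate_seq(ancB, 8),
                           character(1)), paste0("B", 1:4))
  )
  aln <- align_progressive(seqs)
  dm <- k3p_matrix(aln)
  tree <- nj_tree(dm$dist, dm$saturated)
  splits <- ape::prop.part(tree)
  labels <- attr(splits, "labels")
  family_a <- sort(paste0("A", 1:4))
  found <- any(vapply(splits, function(s) {
    grp <- sort(labels[s])
    identical(grp, family_a) ||
      identical(grp, sort(setdiff(labels, family_a)))
  }, logical(1)))
  expect_true(found)
})

test_that("tandem repeat detection finds arrays and resists noise", {
  set.seed(75)
  unit <- random_dna_str(18)
  seq <- paste0(random_dna_str(60), strrep(unit, 3), random_dna_str(60))
  found <- detect_repeats(seq)
  expect_equal(nrow(found), 1)
  expect_equal(found$unit_length, 18L)
  expect_equal(found$copies, 3L)
  expect_equal(found$start, 61L)
  expect_identical(found$consensus, unit)

  # random sequence, exact matching: no arrays expected
  for (k in 1:10) {
    rnd <- random_dna_str(600)
    expect_equal(nrow(detect_repeats(rnd, max_unit_mismatch = 0L)), 0,
                 label = paste("seed rep", k))
  }

  # a copy carrying 2 mismatches still counts at tolerance 3
  copy2 <- mutate_seq(unit, 2)
  seq2 <- paste0(random_dna_str(50), unit, unit, copy2, random_dna_str(50))
  found2 <- detect_repeats(seq2)
  expect_equal(found2$copies, 3L)
  expect_lt(found2$mean_identity, 1)

  expect_error(detect_repeats("ACGT"), "shorter")
})

test_that("subtype calls follow U3 repeat structure", {
  specs <- default_ltr_specs(81L)
  for (nm in names(specs)) {
    el <- build_ltr(specs[[nm]])
    cls <- classify_subtype(el$sequence)
    expect_identical(cls$minor, nm)
    expect_identical(cls$major, substr(nm, 1, 1))
    # strand invariance
    expect_identical(classify_subtype(revcomp(el$sequence))$minor, nm)
  }
  # a plain sequence with no arrays at all is A1
  set.seed(82)
  plain <- classify_subtype(paste0(random_dna_str(380), "TATAAA",
                                   random_dna_str(214)),
                            config = subtype_config(sub_max_mismatch = 0L))
  expect_identical(plain$minor, "A1")
})

test_that("PERV typing hits the right panel member or abstains", {
  panel <- perv_typing_panel(91L)
  set.seed(92)
  elem <- paste0(random_dna_str(200), panel[["PERV-B"]], random_dna_str(200))
  ty <- classify_perv_type(elem, panel)
  expect_identical(ty$type, "B")
  expect_equal(ty$identity, 1.0)

  expect_identical(classify_perv_type(random_dna_str(500), panel)$type,
                   "unknown")
  expect_error(classify_perv_type("ACGT", character(0)), "empty")
})
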