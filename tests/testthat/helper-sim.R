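# Shared small simulation, built once per test run and cached. 250 kb,
# six planted insertions (mixed solo-LTR / provirus), error-free 40x reads:
# large enough that every stage has work to do, small enough to build in
# well under a minute.

.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (!is.null(.sim_cache$sim)) return(.sim_cache$sim)
  ref <- generate_reference(genome_spec(1, 250000L, 0.41, seed = 5L))
  lib <- element_library(101L)
  events <- sample_insertion_events(ref, lib, 6, seed = 3L)
  donor_set <- insert_elements(ref, events, lib)
  simres <- simulate_reads(donor_set, readsim_params(coverage = 40,
                                                     seed = 9L))
  dir <- file.path(tempdir(), "nrltr-shared-sim")
  paths <- write_simulation(simres, dir, "sim")
  reads <- read_sam(paths["sam"])
  .sim_cache$sim <- list(
    reference = ref, library = lib, events = events,
    donor_set = donor_set, truth = donor_set$truth, simres = simres,
    paths = paths, reads = reads
  )
  .sim_cache$sim
}

shared_anchors <- function() {
  if (!is.null(.sim_cache$anchors)) return(.sim_cache$anchors)
  s <- shared_sim()
  .sim_cache$anchors <- collect_anchors(s$reads, s$library$ltr_library)
  .sim_cache$anchors
}

shared_calls <- function() {
  if (!is.null(.sim_cache$calls)) return(.sim_cache$calls)
  s <- shared_sim()
  .sim_cache$calls <- call_insertions(shared_anchors(), s$reads,
                                      s$reference)
  .sim_cache$calls
}

# Build a minimal SAM read frame directly (for unit tests of pair
# classification and TSD detection without a full simulation).
make_reads <- function(...) {
  rows <- list(...)
  defaults <- list(qname = "r", flag = 0L, chrom = "chr1", pos = 1L,
                   mapq = 60L, cigar = "150M", mchrom = "=", mpos = 1L,
                   tlen = 0L, seq = strrep("A", 150))
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(utils::modifyList(defaults, r), stringsAsFactors = FALSE)
  }))
  df <- cbind(df, sam_flags(df$flag))
  ci <- nrltr:::cigar_info(df$cigar)
  df$clip_left <- ifelse(df$unmapped, 0L, ci$clip_left)
  df$clip_right <- ifelse(df$unmapped, 0L, ci$clip_right)
  df$end <- ifelse(df$unmapped, NA_integer_, df$pos + ci$rlen - 1L)
  df$pos[df$unmapped] <- NA_integer_
  df
}
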