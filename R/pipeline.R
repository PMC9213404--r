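# Pipeline stages over a working directory, mirroring the command-line
# interface: simulate -> discover -> call -> assemble -> classify ->
# evaluate. Every stage writes a machine-readable parameter manifest next
# to its outputs, sufficient to re-run the stage identically; no stage
# mutates its inputs.

write_manifest <- function(dir, stage, params) {
  manifest <- list(
    stage = stage,
    package = "nrltr",
    version = as.character(utils::packageVersion("nrltr")),
    params = params
  )
  path <- file.path(dir, paste0(stage, ".manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulation stage: genome, library, donor, reads and truth on disk
#'
#' @param out_dir output directory.
#' @param genome a [genome_spec()].
#' @param n_insertions number of planted insertions.
#' @param sim a [readsim_params()].
#' @param library_seed seed for [element_library()].
#' @param events_seed seed for [sample_insertion_events()].
#' @param solo_fraction fraction of solo-LTR insertions.
#' @return named character vector of output paths (invisibly the in-memory
#'   objects as attribute `objects`).
#' @export
stage_simulate <- function(out_dir, genome = genome_spec(),
                           n_insertions = 20L, sim = readsim_params(),
                           library_seed = 101L, events_seed = 1L,
                           solo_fraction = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- generate_reference(genome)
  lib <- element_library(library_seed)
  events <- if (n_insertions > 0)
    sample_insertion_events(reference, lib, n_insertions,
                            solo_fraction = solo_fraction,
                            seed = events_seed)
  else data.frame(chrom = character(0), position = integer(0),
                  element_kind = character(0), element_id = character(0),
                  orientation = character(0), tsd_length = integer(0))
  donor_set <- insert_elements(reference, events, lib)
  simres <- simulate_reads(donor_set, sim)
  paths <- c(
    reference = file.path(out_dir, "reference.fasta"),
    library = file.path(out_dir, "library.fasta"),
    panel = file.path(out_dir, "panel.fasta"),
    donor = file.path(out_dir, "donor.fasta"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_fasta(reference, paths["reference"])
  write_fasta(lib$ltr_library, paths["library"])
  write_fasta(lib$panel, paths["panel"])
  write_fasta(donor_set$donor, paths["donor"])
  write_truth(donor_set$truth, paths["truth"])
  sim_paths <- write_simulation(simres, out_dir, "reads")
  paths <- c(paths, sim_paths)
  write_manifest(out_dir, "simulate", list(
    genome = unclass(genome), n_insertions = n_insertions,
    sim = unclass(sim), library_seed = library_seed,
    events_seed = events_seed, solo_fraction = solo_fraction,
    outputs = as.list(paths)))
  structure(invisible(paths),
            objects = list(reference = reference, library = lib,
                           donor_set = donor_set, sim = simres))
}

#' Discovery stage: anchor evidence table from SAM + library
#'
#' @param sam_path SAM alignments.
#' @param library_path LTR library FASTA.
#' @param out_dir output directory.
#' @param params a [discovery_params()].
#' @return path of the anchor table.
#' @export
stage_discover <- function(sam_path, library_path, out_dir,
                           params = discovery_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  library <- read_fasta(library_path)
  if (length(library) == 0)
    stop("element library is empty: ", library_path, call. = FALSE)
  reads <- read_sam(sam_path)
  anchors <- collect_anchors(reads, library, params)
  out <- file.path(out_dir, "anchors.tsv")
  write_anchors(anchors, out)
  write_manifest(out_dir, "discover", list(
    sam = sam_path, library = library_path, params = unclass(params),
    n_anchors = nrow(anchors)))
  invisible(out)
}

#' Calling stage: breakpoint calls and TSD BED from anchors + SAM
#'
#' @param anchors_path anchor table.
#' @param sam_path SAM alignments.
#' @param reference_path reference FASTA.
#' @param out_dir output directory.
#' @param params a [calling_params()].
#' @return path of the call table.
#' @export
stage_call <- function(anchors_path, sam_path, reference_path, out_dir,
                       params = calling_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  anchors <- read_anchors(anchors_path)
  reads <- read_sam(sam_path)
  reference <- read_fasta(reference_path)
  calls <- call_insertions(anchors, reads, reference, params)
  out <- file.path(out_dir, "calls.tsv")
  write_calls(calls, out)
  write_bed(calls, file.path(out_dir, "tsd.bed"))
  write_manifest(out_dir, "call", list(
    anchors = anchors_path, sam = sam_path, reference = reference_path,
    params = unclass(params), n_calls = nrow(calls)))
  invisible(out)
}

#' Assembly stage: junction contigs and reconstructed LTR FASTA
#'
#' @param sam_path SAM alignments.
#' @param calls_path call table.
#' @param reference_path reference FASTA.
#' @param library_path LTR library FASTA.
#' @param out_dir output directory.
#' @param params an [assembly_params()].
#' @param disc_params a [discovery_params()].
#' @return path of the reconstructed-LTR FASTA.
#' @export
stage_assemble <- function(sam_path, calls_path, reference_path,
                           library_path, out_dir,
                           params = assembly_params(),
                           disc_params = discovery_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- read_sam(sam_path)
  calls <- read_calls(calls_path)
  reference <- read_fasta(reference_path)
  library <- read_fasta(library_path)
  recs <- reconstruct_insertions(reads, calls, reference, library, params,
                                 disc_params)
  out <- file.path(out_dir, "ltrs.fasta")
  write_ltr_fasta(recs, out)
  report <- if (length(recs)) data.frame(
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    breakpoint_pos = vapply(recs, `[[`, integer(1), "breakpoint_pos"),
    completeness = vapply(recs, `[[`, character(1), "completeness"),
    length_with_tsd = vapply(recs, `[[`, integer(1), "length_with_tsd"),
    overlap_mismatches = vapply(recs, `[[`, integer(1),
                                "overlap_mismatches"),
    element = vapply(recs, `[[`, character(1), "element"),
    stringsAsFactors = FALSE
  ) else data.frame(chrom = character(0), breakpoint_pos = integer(0),
                    completeness = character(0),
                    length_with_tsd = integer(0),
                    overlap_mismatches = integer(0),
                    element = character(0))
  write_tsv_commented(sort_by_locus(report, "breakpoint_pos"),
                      file.path(out_dir, "ltr_report.tsv"),
                      "reconstructed LTR loci; coordinates 1-based")
  write_manifest(out_dir, "assemble", list(
    sam = sam_path, calls = calls_path, reference = reference_path,
    library = library_path, params = unclass(params),
    n_reconstructed = length(recs)))
  invisible(out)
}

#' Classification stage: subtype table, alignment and NJ tree
#'
#' @param ltr_path reconstructed-LTR FASTA.
#' @param out_dir output directory.
#' @param config a [subtype_config()].
#' @param panel_path optional typed pol panel FASTA; when given, each LTR
#'   sequence is also typed against it.
#' @return path of the classification table.
#' @export
stage_classify <- function(ltr_path, out_dir, config = subtype_config(),
                           panel_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- read_fasta(ltr_path)
  out <- file.path(out_dir, "classification.tsv")
  if (length(seqs) == 0) {
    write_tsv_commented(data.frame(name = character(0)), out,
                        "LTR subtype classification")
    return(invisible(out))
  }
  res <- classify_ltrs(seqs, config)
  tab <- res$table
  if (!is.null(panel_path)) {
    panel <- read_fasta(panel_path)
    tab$perv_type <- vapply(seqs, function(s)
      classify_perv_type(s, panel)$type, character(1))
  }
  write_tsv_commented(tab, out, "LTR subtype classification")
  if (!is.null(res$alignment))
    write_fasta(stats::setNames(res$alignment$rows, res$alignment$names),
                file.path(out_dir, "alignment.fasta"))
  if (!is.null(res$tree))
    ape::write.tree(res$tree, file.path(out_dir, "tree.nwk"))
  write_manifest(out_dir, "classify", list(
    ltrs = ltr_path, config = config, n_sequences = length(seqs)))
  invisible(out)
}

#' Evaluation stage: score calls/reconstructions against truth
#'
#' @param calls_path call table.
#' @param ltr_path reconstructed-LTR FASTA (for completeness counts).
#' @param truth_path truth table.
#' @param out_dir output directory.
#' @param tolerance_bp breakpoint matching tolerance.
#' @return the `eval_report`, invisibly; written as `evaluation.tsv`.
#' @export
stage_evaluate <- function(calls_path, ltr_path, truth_path, out_dir,
                           tolerance_bp = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- read_calls(calls_path)
  truth <- read_truth(truth_path)
  report <- evaluate(calls, list(), truth, tolerance_bp)
  df <- data.frame(metric = c("n_truth", "n_called", "tp", "fp", "fn",
                              "precision", "recall", "f1",
                              "tsd_exact_rate"),
                   value = c(report$n_truth, report$n_called, report$tp,
                             report$fp, report$fn, report$precision,
                             report$recall, report$f1,
                             report$tsd_exact_rate))
  write_tsv_commented(df, file.path(out_dir, "evaluation.tsv"),
                      "evaluation against planted truth")
  write_manifest(out_dir, "evaluate", list(
    calls = calls_path, truth = truth_path, tolerance_bp = tolerance_bp))
  invisible(report)
}

#' Run the full pipeline over a working directory
#'
#' Simulates a study (reference, library, donor, reads), then runs
#' discovery, calling, assembly, classification and evaluation. All
#' outputs and per-stage manifests land under `work_dir`; the run is
#' byte-reproducible given the same seeds.
#'
#' @param work_dir working directory.
#' @param genome a [genome_spec()].
#' @param n_insertions planted insertion count.
#' @param sim a [readsim_params()].
#' @param disc a [discovery_params()].
#' @param calling a [calling_params()].
#' @param asm an [assembly_params()].
#' @param library_seed,events_seed generator seeds.
#' @param solo_fraction fraction of solo-LTR insertions.
#' @return list with `calls`, `reconstructions`, `classification`,
#'   `evaluation`, `paths`.
#' @export
run_pipeline <- function(work_dir, genome = genome_spec(),
                         n_insertions = 20L, sim = readsim_params(),
                         disc = discovery_params(),
                         calling = calling_params(),
                         asm = assembly_params(),
                         library_seed = 101L, events_seed = 1L,
                         solo_fraction = 0.5) {
  paths <- stage_simulate(work_dir, genome, n_insertions, sim,
                          library_seed, events_seed, solo_fraction)
  obj <- attr(paths, "objects")
  anchors_path <- stage_discover(paths[["sam"]], paths[["library"]],
                                 work_dir, disc)
  calls_path <- stage_call(anchors_path, paths[["sam"]],
                           paths[["reference"]], work_dir, calling)
  ltr_path <- stage_assemble(paths[["sam"]], calls_path,
                             paths[["reference"]], paths[["library"]],
                             work_dir, asm, disc)
  cls_path <- stage_classify(ltr_path, work_dir,
                             panel_path = paths[["panel"]])
  calls <- read_calls(calls_path)
  recs_fasta <- read_fasta(ltr_path)
  report <- evaluate(calls,
                     reconstructions = reconstructions_from_report(
                       file.path(work_dir, "ltr_report.tsv"), recs_fasta),
                     truth = obj$donor_set$truth)
  df <- data.frame(metric = c("precision", "recall", "tsd_exact_rate",
                              "ltr_identity_mean"),
                   value = c(report$precision, report$recall,
                             report$tsd_exact_rate,
                             report$ltr_identity_mean))
  write_tsv_commented(df, file.path(work_dir, "evaluation.tsv"),
                      "evaluation against planted truth")
  list(calls = calls,
       reconstructions = recs_fasta,
       classification = read_tsv_commented(cls_path),
       evaluation = report,
       paths = c(paths, anchors = anchors_path, calls = calls_path,
                 ltrs = ltr_path, classification = cls_path))
}

# Rebuild minimal reconstructed_ltr objects from the on-disk report +
# FASTA, for evaluation runs that start from files.
reconstructions_from_report <- function(report_path, seqs) {
  rep <- read_tsv_commented(report_path)
  if (nrow(rep) == 0) return(list())
  lapply(seq_len(nrow(rep)), function(k) {
    nm <- sprintf("%s_%d|%s|%d", rep$chrom[k], rep$breakpoint_pos[k],
                  rep$completeness[k], rep$length_with_tsd[k])
    structure(list(
      sequence = unname(seqs[nm]), length_with_tsd = rep$length_with_tsd[k],
      completeness = rep$completeness[k],
      overlap_mismatches = rep$overlap_mismatches[k],
      chrom = rep$chrom[k], breakpoint_pos = rep$breakpoint_pos[k],
      element = rep$element[k]
    ), class = "reconstructed_ltr")
  })
}
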