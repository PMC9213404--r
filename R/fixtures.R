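# Published per-locus fixture: the detected-TSD table for the three
# sequenced pigs, shipped as a plain-text transcription under extdata and
# convertible into per-sample inputs for [summarize_loci()].

#' Path of the published per-locus TSD table
#' @return file path of the bundled tab-separated table.
#' @export
published_locus_table <- function() {
  system.file("extdata", "table1_loci.tsv", package = "nrltr",
              mustWork = TRUE)
}

#' Convert the per-locus table into per-sample call summaries
#'
#' Each sample column becomes one data.frame of (chrom, pos, status,
#' completeness), the input shape of [summarize_loci()]. Loci in the
#' single-TSD section are carried with `5p_only` completeness (the table
#' does not state which end).
#'
#' @param path path of a per-locus table (defaults to the bundled one).
#' @return named list of per-sample data.frames.
#' @export
locus_table_samples <- function(path = published_locus_table()) {
  tab <- read_tsv_commented(path)
  sample_cols <- setdiff(names(tab),
                         c("chrom", "pos", "tsd_seq", "tsd_section"))
  completeness <- ifelse(tab$tsd_section == "both", "both", "5p_only")
  stats::setNames(lapply(sample_cols, function(s) {
    data.frame(chrom = tab$chrom, pos = tab$pos, status = tab[[s]],
               completeness = completeness, stringsAsFactors = FALSE)
  }), sample_cols)
}
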