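# Tab-separated tables (calls, anchors, truth) and BED output.
#
# Conventions, also stated in each file's header comment:
#   * call/anchor/truth tables are 1-based inclusive;
#   * BED intervals are 0-based half-open;
#   * writers sort by (chrom, position) so output is deterministic.

CALL_COLUMNS <- c("chrom", "breakpoint_pos", "support_5p", "support_3p",
                  "filter_level", "tsd_start", "tsd_end", "tsd_seq", "status")

sort_by_locus <- function(df, pos_col) {
  df[order(df$chrom, df[[pos_col]]), , drop = FALSE]
}

write_tsv_commented <- function(df, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write breakpoint calls to a tab-separated table
#'
#' Columns: chrom, breakpoint_pos, support_5p, support_3p, filter_level,
#' tsd_start, tsd_end, tsd_seq, status. Coordinates are 1-based inclusive.
#' TSD fields are all present or all `NA`.
#'
#' @param calls data.frame of call records.
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  calls <- validate_calls(calls)
  write_tsv_commented(sort_by_locus(calls[CALL_COLUMNS], "breakpoint_pos"),
                      path, "breakpoint calls; coordinates 1-based inclusive")
}

#' Read a breakpoint call table written by [write_calls()]
#' @param path path to the table.
#' @return data.frame of call records.
#' @export
read_calls <- function(path) {
  df <- read_tsv_commented(path)
  missing <- setdiff(CALL_COLUMNS, names(df))
  if (length(missing))
    stop("call table ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$tsd_seq <- as.character(df$tsd_seq)
  df$chrom <- as.character(df$chrom)
  df$status <- as.character(df$status)
  validate_calls(df)
}

validate_calls <- function(calls) {
  stopifnot(all(CALL_COLUMNS %in% names(calls)))
  if (nrow(calls) == 0) return(calls)
  if (any(calls$filter_level < 1 | calls$filter_level > 8))
    stop("filter_level must be in [1, 8]", call. = FALSE)
  tsd_na <- is.na(calls$tsd_start) + is.na(calls$tsd_end) + is.na(calls$tsd_seq)
  if (any(tsd_na %in% c(1L, 2L)))
    stop("tsd_start/tsd_end/tsd_seq must be all present or all absent",
         call. = FALSE)
  has <- !is.na(calls$tsd_start)
  len <- calls$tsd_end[has] - calls$tsd_start[has] + 1L
  if (any(len != nchar(calls$tsd_seq[has])) || any(!len %in% c(4L, 5L)))
    stop("TSD length must be 4 or 5 and match tsd_seq", call. = FALSE)
  calls
}

#' Write TSD intervals as BED (0-based half-open)
#'
#' A call at 1-based TSD interval `[s, e]` becomes the BED line
#' `chrom  s-1  e`. Calls without a TSD are omitted.
#'
#' @param calls data.frame of call records.
#' @param path output path.
#' @export
write_bed <- function(calls, path) {
  if (nrow(calls) == 0) {
    file.create(path)
    return(invisible(path))
  }
  has <- !is.na(calls$tsd_start)
  bed <- data.frame(chrom = calls$chrom[has],
                    start = calls$tsd_start[has] - 1L,
                    end = calls$tsd_end[has],
                    name = paste0(calls$chrom[has], "_", calls$breakpoint_pos[has]))
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write reconstructed LTRs to FASTA
#'
#' Headers are `<chrom>_<pos>|<completeness>|<length>`.
#'
#' @param recs list of reconstructed-LTR objects (see [reconstruct_ltr()]).
#' @param path output path.
#' @export
write_ltr_fasta <- function(recs, path) {
  if (length(recs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  nm <- vapply(recs, function(r)
    sprintf("%s_%d|%s|%d", r$chrom, r$breakpoint_pos, r$completeness,
            r$length_with_tsd), character(1))
  seqs <- stats::setNames(vapply(recs, `[[`, character(1), "sequence"), nm)
  ord <- order(vapply(recs, `[[`, character(1), "chrom"),
               vapply(recs, `[[`, integer(1), "breakpoint_pos"))
  write_fasta(seqs[ord], path)
}

#' Write / read the planted-insertion truth table
#'
#' Columns: chrom, pos, kind, element_id, orientation, tsd_len, tsd_seq,
#' subtype (1-based target-site start).
#'
#' @param truth truth data.frame from [insert_elements()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  keep <- c("chrom", "pos", "kind", "element_id", "orientation",
            "tsd_len", "tsd_seq", "subtype")
  write_tsv_commented(sort_by_locus(truth[keep], "pos"), path,
                      "planted insertion truth; pos = 1-based target-site start")
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read_tsv_commented(path)

#' Write / read the anchor evidence table
#' @param anchors anchor data.frame from [collect_anchors()].
#' @param path output path.
#' @export
write_anchors <- function(anchors, path) {
  keep <- c("chrom", "pos", "strand", "kind", "element", "identity",
            "length", "side")
  write_tsv_commented(sort_by_locus(anchors[keep], "pos"), path,
                      "anchor evidence; pos = 1-based innermost anchor end")
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) read_tsv_commented(path)
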