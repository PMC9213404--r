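# Evaluation against the planted-insertion truth table, and the
# locus-by-sample summary in the published table's style (both-TSD versus
# single-TSD sections).

#' Score calls and reconstructions against the truth table
#'
#' Calls are greedily matched one-to-one to truth loci by breakpoint
#' distance (within `tolerance_bp`, same chromosome). Precision is
#' undefined (NA) when no calls were made, never 0/0 = 0.
#'
#' @param calls call data.frame from [call_insertions()].
#' @param reconstructions list of `reconstructed_ltr` objects (may be
#'   empty).
#' @param truth truth data.frame from [insert_elements()].
#' @param tolerance_bp breakpoint matching tolerance.
#' @return list of class `eval_report`: n_truth, n_called, tp, fp, fn,
#'   precision, recall, f1, tsd_exact_rate, ltr_identity_mean,
#'   completeness_counts, matches (data.frame).
#' @export
evaluate <- function(calls, reconstructions = list(), truth,
                     tolerance_bp = 10L) {
  n_truth <- nrow(truth); n_called <- nrow(calls)
  matched_truth <- rep(NA_integer_, n_called)
  used <- logical(n_truth)
  if (n_called > 0) {
    ord <- order(calls$chrom, calls$breakpoint_pos)
    for (k in ord) {
      cand <- which(!used & truth$chrom == calls$chrom[k] &
                    abs(truth$pos - calls$breakpoint_pos[k]) <= tolerance_bp)
      if (length(cand)) {
        best <- cand[which.min(abs(truth$pos[cand] -
                                   calls$breakpoint_pos[k]))]
        matched_truth[k] <- best
        used[best] <- TRUE
      }
    }
  }
  tp <- sum(!is.na(matched_truth))
  fp <- n_called - tp
  fn <- n_truth - tp
  precision <- if (n_called == 0) NA_real_ else tp / n_called
  recall <- if (n_truth == 0) NA_real_ else tp / n_truth
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  # TSD exactness among true positives
  tsd_exact <- NA_real_
  if (tp > 0) {
    hit <- which(!is.na(matched_truth))
    exact <- vapply(hit, function(k) {
      t <- truth[matched_truth[k], ]
      !is.na(calls$tsd_seq[k]) && calls$tsd_seq[k] == t$tsd_seq &&
        calls$tsd_start[k] == t$pos
    }, logical(1))
    tsd_exact <- mean(exact)
  }
  # Reconstruction identity measures base-level accuracy: each sequence is
  # compared against the truth region it claims to cover (the whole
  # TSD-to-TSD element for two-sided reconstructions, the matching prefix
  # or suffix for one-sided ones). Completeness is reported separately in
  # completeness_counts, so truncation is visible there, not hidden here.
  ids <- numeric(0)
  completeness <- c(both = 0L, `5p_only` = 0L, `3p_only` = 0L)
  for (r in reconstructions) {
    completeness[r$completeness] <- completeness[r$completeness] + 1L
    t <- truth[truth$chrom == r$chrom &
               abs(truth$pos - r$breakpoint_pos) <= tolerance_bp, ,
               drop = FALSE]
    if (nrow(t) == 0) next
    target <- t$ltr_truth[1]
    n <- nchar(r$sequence)
    if (r$completeness == "5p_only" && n < nchar(target)) {
      target <- substr(target, 1, n)
    } else if (r$completeness == "3p_only" && n < nchar(target)) {
      target <- substr(target, nchar(target) - n + 1L, nchar(target))
    }
    ids <- c(ids, seq_identity(r$sequence, target))
  }
  structure(list(
    n_truth = n_truth, n_called = n_called, tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    tsd_exact_rate = tsd_exact,
    ltr_identity_mean = if (length(ids)) mean(ids) else NA_real_,
    completeness_counts = completeness,
    matches = data.frame(call = seq_len(n_called),
                         truth = matched_truth)
  ), class = "eval_report")
}

# Global alignment identity between two sequences: matches over the longer
# input length, so truncated reconstructions are penalized rather than
# scored on their aligned prefix alone.
seq_identity <- function(a, b) {
  if (identical(a, b)) return(1)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix =
                                        sub_matrix(default_scoring()),
                                      gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(pa) / max(nchar(a), nchar(b))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Insertion-calling evaluation\n")
  cat(sprintf("  truth loci: %d  called: %d  TP: %d  FP: %d  FN: %d\n",
              x$n_truth, x$n_called, x$tp, x$fp, x$fn))
  cat(sprintf("  precision: %s  recall: %s  F1: %s\n",
              format(x$precision, digits = 4),
              format(x$recall, digits = 4), format(x$f1, digits = 4)))
  cat(sprintf("  TSD exact: %s  LTR identity: %s\n",
              format(x$tsd_exact_rate, digits = 4),
              format(x$ltr_identity_mean, digits = 4)))
  cat("  completeness:", paste(names(x$completeness_counts),
                               x$completeness_counts, collapse = "  "), "\n")
  invisible(x)
}

#' Merge per-sample locus calls into a locus-by-sample table
#'
#' Loci from all samples are merged within `merge_window` bp into rows;
#' each cell holds the sample's status at that locus (`non-LTR` when the
#' sample has no call there). Rows are partitioned into a both-TSD section
#' and a single-TSD section, mirroring the published per-locus accounting.
#'
#' @param samples named list of per-sample data.frames with columns chrom,
#'   pos, status, completeness (`both`, `5p_only` or `3p_only`).
#' @param merge_window cross-sample locus merge window in bp.
#' @return list of class `locus_summary`: `table` (chrom, pos,
#'   completeness, one status column per sample, section) and
#'   `section_counts` (both_tsd, single_tsd).
#' @export
summarize_loci <- function(samples, merge_window = 500L) {
  stopifnot(length(samples) >= 1)
  if (is.null(names(samples)))
    names(samples) <- paste0("sample", seq_along(samples))
  all_loci <- do.call(rbind, lapply(names(samples), function(s) {
    df <- samples[[s]]
    if (nrow(df) == 0) return(NULL)
    data.frame(sample = s, chrom = as.character(df$chrom), pos = df$pos,
               status = as.character(df$status),
               completeness = as.character(df$completeness),
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_loci) || nrow(all_loci) == 0)
    stop("no loci in any sample", call. = FALSE)
  all_loci <- all_loci[order(all_loci$chrom, all_loci$pos), , drop = FALSE]
  # chain loci within merge_window into shared rows
  row_id <- integer(nrow(all_loci))
  cur <- 0L
  for (k in seq_len(nrow(all_loci))) {
    if (k == 1 || all_loci$chrom[k] != all_loci$chrom[k - 1] ||
        all_loci$pos[k] - all_loci$pos[k - 1] > merge_window) {
      cur <- cur + 1L
    }
    row_id[k] <- cur
  }
  rows <- lapply(split(seq_len(nrow(all_loci)), row_id), function(ix) {
    grp <- all_loci[ix, , drop = FALSE]
    comp <- grp$completeness[grp$status != "non-LTR"]
    if (!length(comp)) comp <- grp$completeness
    status <- vapply(names(samples), function(s) {
      st <- grp$status[grp$sample == s]
      if (length(st)) st[1] else "non-LTR"
    }, character(1))
    c(list(chrom = grp$chrom[1], pos = min(grp$pos),
           completeness = if (any(comp == "both")) "both" else comp[1]),
      as.list(status))
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  names(tab) <- c("chrom", "pos", "completeness", names(samples))
  tab$section <- ifelse(tab$completeness == "both", "both_tsd", "single_tsd")
  tab <- tab[order(tab$section, tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    section_counts = c(both_tsd = sum(tab$section == "both_tsd"),
                       single_tsd = sum(tab$section == "single_tsd"))
  ), class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  cat("Locus-by-sample summary:",
      x$section_counts["both_tsd"], "both-TSD loci,",
      x$section_counts["single_tsd"], "single-TSD loci\n")
  print(x$table, ...)
  invisible(x)
}
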