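# Synthetic-data generators: reference genomes, LTR/provirus element
# libraries with controlled U3 repeat structure, donor genomes carrying
# TSD-flanked insertions, and the planted-insertion truth table.
#
# All generators are deterministic given their seed and restore the caller's
# RNG state. Coordinates in truth tables and file outputs are 1-based
# inclusive; internal arithmetic is 0-based half-open where convenient.

#' Genome simulation specification
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp (>= 10,000).
#' @param gc_fraction GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 1L, chrom_length = 100000L,
                        gc_fraction = 0.41, seed = 1L) {
  if (n_chromosomes < 1) stop("n_chromosomes must be positive", call. = FALSE)
  if (chrom_length < 10000)
    stop("chrom_length must be >= 10,000 bp", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]", call. = FALSE)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 gc_fraction = gc_fraction, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a random reference genome
#'
#' @param spec a [genome_spec()].
#' @return named character vector of chromosome sequences (`chr1`, `chr2`,
#'   ...), alphabet `{A,C,G,T}`.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    seqs <- vapply(seq_len(spec$n_chromosomes), function(i)
      random_dna(spec$chrom_length, spec$gc_fraction), character(1))
    stats::setNames(seqs, paste0("chr", seq_len(spec$n_chromosomes)))
  })
}

#' LTR element specification
#'
#' Describes a synthetic retroviral LTR: total length, the tandem-repeat
#' blocks to place in U3 (units of 18 or 21 bp, as observed for LTR-B
#' promoter repeats), and the target subtype label. B-type specs must carry
#' at least one 18-bp and one 21-bp unit; A-type specs must carry none.
#'
#' @param total_length LTR length in bp (550-760, bracketing the 598-710 bp
#'   range observed for reconstructed LTRs including TSDs).
#' @param u3_repeat_units data.frame with columns `unit_length` (18 or 21)
#'   and `copies`, or NULL.
#' @param subtype_label one of `A1`, `A2`, `B1`, `B2`, `B3`.
#' @param seed integer seed.
#' @param sub_repeat for A2 specs, `c(unit_length, copies)` of the planted
#'   sub-repeat (unit 8-15 bp); ignored otherwise.
#' @return object of class `ltr_spec`.
#' @export
ltr_spec <- function(total_length, u3_repeat_units = NULL,
                     subtype_label, seed = 1L, sub_repeat = c(12L, 3L)) {
  subtype_label <- match.arg(subtype_label, c("A1", "A2", "B1", "B2", "B3"))
  if (total_length < 550 || total_length > 760)
    stop("total_length must be in [550, 760] bp", call. = FALSE)
  if (is.null(u3_repeat_units))
    u3_repeat_units <- data.frame(unit_length = integer(0), copies = integer(0))
  if (!all(u3_repeat_units$unit_length %in% c(18L, 21L)))
    stop("repeat units must be 18 or 21 bp", call. = FALSE)
  is_b <- startsWith(subtype_label, "B")
  full <- u3_repeat_units[u3_repeat_units$copies >= 1, , drop = FALSE]
  if (is_b && !(18L %in% full$unit_length && 21L %in% full$unit_length))
    stop("B-type specs need >= 1 copy each of an 18-bp and a 21-bp unit",
         call. = FALSE)
  if (!is_b && nrow(full) > 0)
    stop("A-type specs must have no full 18/21-bp repeat copies", call. = FALSE)
  structure(list(total_length = as.integer(total_length),
                 u3_repeat_units = u3_repeat_units,
                 subtype_label = subtype_label, seed = as.integer(seed),
                 sub_repeat = as.integer(sub_repeat)),
            class = "ltr_spec")
}

#' Default LTR specifications for the five subtypes
#'
#' Copy numbers place the B specs in the three copy-number tiers used by the
#' subtype classifier (totals 4, 6 and 8 against tier boundaries 4/6).
#' Lengths sit in the lower-middle of the observed 598-710 bp range so that
#' 350-bp fragments can bridge both junction contigs during reconstruction.
#'
#' @param seed integer seed (per-subtype seeds are derived from it).
#' @return named list of [ltr_spec()] objects.
#' @export
default_ltr_specs <- function(seed = 101L) {
  units <- function(n18, n21) data.frame(unit_length = c(18L, 21L),
                                         copies = c(n18, n21))
  list(
    A1 = ltr_spec(598L, NULL, "A1", seed = seed + 1L),
    A2 = ltr_spec(610L, NULL, "A2", seed = seed + 2L),
    B1 = ltr_spec(620L, units(2L, 2L), "B1", seed = seed + 3L),
    B2 = ltr_spec(634L, units(3L, 3L), "B2", seed = seed + 4L),
    B3 = ltr_spec(650L, units(4L, 4L), "B3", seed = seed + 5L)
  )
}

#' Build a synthetic LTR sequence from a specification
#'
#' The LTR is laid out as U3, a TATA box (`TATAAA`), R and U5. Requested
#' repeat blocks are placed as tandem arrays inside U3. Construction is
#' verified against the subtype classifier (the round-trip property): drawn
#' sequences that by chance carry confounding motifs (spurious repeat
#' arrays, an early TATA box) are redrawn deterministically.
#'
#' @param spec an [ltr_spec()].
#' @param config classifier configuration, see [subtype_config()].
#' @return object of class `ltr_element`: list with `sequence`, `u3`, `r`,
#'   `u5` coordinate pairs, `repeats` (unit_length, copies, start), and
#'   `subtype`.
#' @export
build_ltr <- function(spec, config = subtype_config()) {
  stopifnot(inherits(spec, "ltr_spec"))
  total <- spec$total_length
  u3_len <- as.integer(round(0.62 * total))
  tata <- "TATAAA"
  r_len <- as.integer(round(0.13 * total))
  u5_len <- total - u3_len - nchar(tata) - r_len
  units <- spec$u3_repeat_units
  block_len <- sum(units$unit_length * units$copies)
  n_blocks <- nrow(units)
  lead <- 30L
  spacer_each <- 8L
  if (startsWith(spec$subtype_label, "A2"))
    block_len <- block_len + prod(spec$sub_repeat)
  if (lead + block_len + spacer_each * (n_blocks + 2L) > u3_len)
    stop("requested repeats are longer than the U3 region", call. = FALSE)

  for (attempt in 0:59) {
    el <- with_seed(spec$seed + 1000L * attempt, {
      parts <- character(0)
      starts <- integer(0)
      pos <- lead + 1L
      lead_seq <- random_dna(lead)
      parts <- lead_seq
      rep_rows <- list()
      add_array <- function(unit_len, copies) {
        unit <- random_dna(unit_len)
        arr <- strrep(unit, copies)
        sp <- random_dna(spacer_each)
        rep_rows[[length(rep_rows) + 1L]] <<-
          data.frame(unit_length = unit_len, copies = copies, start = pos)
        parts <<- c(parts, arr, sp)
        pos <<- pos + nchar(arr) + nchar(sp)
      }
      if (nrow(units) > 0)
        for (k in seq_len(nrow(units)))
          add_array(units$unit_length[k], units$copies[k])
      if (spec$subtype_label == "A2")
        add_array(spec$sub_repeat[1], spec$sub_repeat[2])
      fill <- u3_len - (pos - 1L)
      u3 <- paste0(paste(parts, collapse = ""), random_dna(fill))
      seqn <- paste0(u3, tata, random_dna(r_len), random_dna(u5_len))
      reps <- if (length(rep_rows)) do.call(rbind, rep_rows) else
        data.frame(unit_length = integer(0), copies = integer(0),
                   start = integer(0))
      structure(list(
        sequence = seqn, subtype = spec$subtype_label,
        u3 = c(1L, u3_len),
        r = c(u3_len + nchar(tata) + 1L, u3_len + nchar(tata) + r_len),
        u5 = c(total - u5_len + 1L, total),
        repeats = reps, spec = spec
      ), class = "ltr_element")
    })
    cls <- classify_subtype(el$sequence, config = config)
    u3_found <- u3_region(el$sequence, config = config)
    if (cls$minor == spec$subtype_label && u3_found[2] == u3_len) return(el)
  }
  stop("could not realize an LTR consistent with subtype ",
       spec$subtype_label, call. = FALSE)
}

#' Concatenate a full provirus from its components
#'
#' @param ltr5,ltr3 LTR sequences (character) or `ltr_element` objects.
#' @param internal internal (gag/pol/env) sequence carrying the typing
#'   markers; must be non-empty (a solo LTR is not a provirus).
#' @return character provirus sequence with attribute `component_lengths`.
#' @export
build_provirus <- function(ltr5, internal, ltr3) {
  s5 <- if (inherits(ltr5, "ltr_element")) ltr5$sequence else ltr5
  s3 <- if (inherits(ltr3, "ltr_element")) ltr3$sequence else ltr3
  if (!nzchar(s5) || !nzchar(internal) || !nzchar(s3))
    stop("provirus components must be non-empty", call. = FALSE)
  out <- paste0(s5, internal, s3)
  attr(out, "component_lengths") <- c(ltr5 = nchar(s5),
                                      internal = nchar(internal),
                                      ltr3 = nchar(s3))
  out
}

#' Generate the typed pol-region reference panel
#'
#' Three synthetic pol-region marker sequences labelled PERV-A/B/C, used both
#' to tag provirus internals and as the typing panel for
#' [classify_perv_type()].
#'
#' @param seed integer seed.
#' @param marker_length marker length in bp.
#' @return named character vector (`PERV-A`, `PERV-B`, `PERV-C`).
#' @export
perv_typing_panel <- function(seed = 7L, marker_length = 450L) {
  with_seed(seed, {
    stats::setNames(vapply(1:3, function(i) random_dna(marker_length),
                           character(1)),
                    c("PERV-A", "PERV-B", "PERV-C"))
  })
}

#' Build a provirus internal region carrying a typed pol marker
#'
#' @param type `"A"`, `"B"` or `"C"`.
#' @param length internal length in bp (default 7 kb; real internal lengths
#'   for these loci are not resolvable from short reads, so this is a
#'   simulation convention).
#' @param panel typing panel from [perv_typing_panel()].
#' @param seed integer seed.
#' @return character sequence.
#' @export
build_internal <- function(type = c("A", "B", "C"), length = 7000L,
                           panel = perv_typing_panel(), seed = 11L) {
  type <- match.arg(type)
  marker <- panel[[paste0("PERV-", type)]]
  if (length < nchar(marker) + 200L)
    stop("internal length too short for the pol marker", call. = FALSE)
  with_seed(seed + match(type, c("A", "B", "C")), {
    pre <- random_dna(as.integer(round(0.4 * (length - nchar(marker)))))
    post <- random_dna(length - nchar(marker) - nchar(pre))
    paste0(pre, marker, post)
  })
}

#' Build the synthetic element library
#'
#' Produces the five subtype LTR elements, three typed proviruses, the pol
#' typing panel, and the LTR library used by the discovery stage.
#'
#' @param seed integer seed.
#' @param internal_length provirus internal length in bp.
#' @return list with `elements` (named character: every insertable element),
#'   `meta` (data.frame: element_id, kind, subtype, perv_type, ltr_length,
#'   element_length), `ltr_units` (named character: the LTR unit of every
#'   element), `ltr_library` (named character: subtype LTRs, the discovery
#'   library), `ltr_elements` (list of `ltr_element`), and `panel`.
#' @export
element_library <- function(seed = 101L, internal_length = 7000L) {
  specs <- default_ltr_specs(seed)
  ltr_elements <- lapply(specs, build_ltr)
  ltr_seqs <- vapply(ltr_elements, `[[`, character(1), "sequence")
  names(ltr_seqs) <- paste0("LTR_", names(specs))
  panel <- perv_typing_panel(seed + 50L)
  pv_plan <- data.frame(subtype = c("A1", "B2", "B3"),
                        perv_type = c("A", "B", "C"))
  elements <- as.list(ltr_seqs)
  meta <- data.frame(
    element_id = names(ltr_seqs), kind = "solo_ltr",
    subtype = names(specs), perv_type = NA_character_,
    ltr_length = nchar(ltr_seqs), element_length = nchar(ltr_seqs),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(pv_plan))) {
    st <- pv_plan$subtype[k]; ty <- pv_plan$perv_type[k]
    internal <- build_internal(ty, internal_length, panel, seed + 60L)
    pv <- build_provirus(ltr_seqs[[paste0("LTR_", st)]], internal,
                         ltr_seqs[[paste0("LTR_", st)]])
    id <- paste0("PV_", st, "_", ty)
    elements[[id]] <- as.character(pv)
    meta <- rbind(meta, data.frame(
      element_id = id, kind = "provirus", subtype = st, perv_type = ty,
      ltr_length = nchar(ltr_seqs[[paste0("LTR_", st)]]),
      element_length = nchar(pv), stringsAsFactors = FALSE
    ))
  }
  rownames(meta) <- NULL
  list(elements = stats::setNames(unlist(elements), names(elements)),
       meta = meta,
       ltr_units = stats::setNames(
         ltr_seqs[paste0("LTR_", meta$subtype)], meta$element_id),
       ltr_library = ltr_seqs, ltr_elements = ltr_elements, panel = panel)
}

#' Sample random insertion events over a reference
#'
#' Events are at least `min_spacing` apart (default 2 kb, so that anchor
#' clusters from neighbouring insertions cannot interfere within the 500-bp
#' call-merge window) and away from chromosome ends.
#'
#' @param reference named character vector of chromosomes.
#' @param library an [element_library()].
#' @param n number of events.
#' @param solo_fraction fraction of events drawing solo-LTR elements.
#' @param tsd_lengths candidate TSD lengths (4-5 bp).
#' @param min_spacing minimum spacing between events on a chromosome.
#' @param margin keep-out distance from chromosome ends.
#' @param seed integer seed.
#' @return data.frame of events (chrom, position, element_kind, element_id,
#'   orientation, tsd_length), sorted by (chrom, position).
#' @export
sample_insertion_events <- function(reference, library, n,
                                    solo_fraction = 0.5,
                                    tsd_lengths = c(4L, 5L),
                                    min_spacing = 2000L, margin = 5000L,
                                    seed = 1L) {
  with_seed(seed, {
    lens <- nchar(reference)
    chroms <- sample(names(reference), n, replace = TRUE,
                     prob = lens / sum(lens))
    pos <- integer(n)
    for (i in seq_len(n)) {
      lo <- margin; hi <- lens[[chroms[i]]] - margin
      repeat {
        p <- lo + floor(runif(1) * (hi - lo + 1))
        same <- pos[seq_len(i - 1)][chroms[seq_len(i - 1)] == chroms[i]]
        if (!length(same) || min(abs(same - p)) >= min_spacing) break
      }
      pos[i] <- p
    }
    solo_ids <- library$meta$element_id[library$meta$kind == "solo_ltr"]
    pv_ids <- library$meta$element_id[library$meta$kind == "provirus"]
    n_solo <- round(solo_fraction * n)
    kind <- sample(c(rep("solo_ltr", n_solo), rep("provirus", n - n_solo)))
    ids <- ifelse(kind == "solo_ltr",
                  sample(solo_ids, n, replace = TRUE),
                  sample(pv_ids, n, replace = TRUE))
    ev <- data.frame(
      chrom = chroms, position = pos, element_kind = kind, element_id = ids,
      orientation = sample(c("+", "-"), n, replace = TRUE),
      tsd_length = sample(tsd_lengths, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    ev[order(ev$chrom, ev$position), , drop = FALSE]
  })
}

#' Plant insertion events into a reference genome
#'
#' At each event the donor carries
#' `reference[..pos+tsd-1] + element + reference[pos..]`, i.e. the 4-5 bp
#' target site appears once on each side of the element (the TSD). Elements
#' with orientation `-` are reverse-complemented; the TSD, being
#' host-derived, never is.
#'
#' @param reference named character vector of chromosomes.
#' @param events event data.frame from [sample_insertion_events()] (sorted,
#'   non-overlapping).
#' @param library an [element_library()].
#' @return list with `donor` (named character), `truth` (data.frame: chrom,
#'   pos, kind, element_id, orientation, tsd_len, tsd_seq, subtype,
#'   element_length, donor_elem_start, donor_elem_end, ltr_truth) and
#'   `ref_lengths`.
#' @export
insert_elements <- function(reference, events, library) {
  if (nrow(events) == 0) {
    return(list(donor = reference,
                truth = empty_truth(),
                ref_lengths = nchar(reference)))
  }
  if (is.unsorted(order(events$chrom, events$position)) ||
      any(diff(events$position) < 0 &
          events$chrom[-1] == events$chrom[-nrow(events)]))
    stop("events must be sorted by (chrom, position)", call. = FALSE)
  truth <- NULL
  donor <- reference
  for (ch in unique(events$chrom)) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    refseq <- reference[[ch]]
    L <- nchar(refseq)
    if (any(ev$position + ev$tsd_length - 1L > L))
      stop("event beyond chromosome end on ", ch, call. = FALSE)
    if (any(diff(ev$position) < ev$tsd_length[-nrow(ev)]))
      stop("overlapping events on ", ch, call. = FALSE)
    pieces <- character(0)
    cur <- 1L
    offset <- 0L
    for (k in seq_len(nrow(ev))) {
      p <- ev$position[k]; tl <- ev$tsd_length[k]
      elem <- library$elements[[ev$element_id[k]]]
      if (is.null(elem)) stop("unknown element: ", ev$element_id[k],
                              call. = FALSE)
      if (ev$orientation[k] == "-") elem <- revcomp(elem)
      tsd <- substr(refseq, p, p + tl - 1L)
      left <- substr(refseq, cur, p + tl - 1L)
      pieces <- c(pieces, left, elem)
      elem_start <- offset + (p + tl - 1L) - cur + 1L + 1L
      meta <- library$meta[library$meta$element_id == ev$element_id[k], ]
      ltr_unit <- library$ltr_units[[ev$element_id[k]]]
      if (ev$orientation[k] == "-") ltr_unit <- revcomp(ltr_unit)
      truth <- rbind(truth, data.frame(
        chrom = ch, pos = p, kind = ev$element_kind[k],
        element_id = ev$element_id[k], orientation = ev$orientation[k],
        tsd_len = tl, tsd_seq = tsd, subtype = meta$subtype,
        element_length = nchar(elem),
        donor_elem_start = elem_start,
        donor_elem_end = elem_start + nchar(elem) - 1L,
        ltr_truth = paste0(tsd, ltr_unit, tsd),
        stringsAsFactors = FALSE
      ))
      offset <- offset + (p + tl - 1L) - cur + 1L + nchar(elem)
      cur <- p
    }
    pieces <- c(pieces, substr(refseq, cur, L))
    donor[[ch]] <- paste(pieces, collapse = "")
  }
  rownames(truth) <- NULL
  list(donor = donor, truth = truth, ref_lengths = nchar(reference))
}

empty_truth <- function() {
  data.frame(chrom = character(0), pos = integer(0), kind = character(0),
             element_id = character(0), orientation = character(0),
             tsd_len = integer(0), tsd_seq = character(0),
             subtype = character(0), element_length = integer(0),
             donor_elem_start = integer(0), donor_elem_end = integer(0),
             ltr_truth = character(0), stringsAsFactors = FALSE)
}
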