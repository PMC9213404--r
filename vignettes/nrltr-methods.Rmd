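---
title: "Detecting non-reference endogenous retrovirus LTR insertions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-reference endogenous retrovirus LTR insertions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Endogenous retroviruses (ERVs) are proviral elements — `gag`/`pol`/`env`
flanked by two long terminal repeats (LTRs) — fixed in their host's
germline. In pigs these are PERVs, a central safety concern for
xenotransplantation. Reference genome assemblies systematically
under-represent such repeats, so an individual animal typically carries
insertions absent from the assembly: *non-reference* PERVs. They are
invisible to reference annotation and detectable only through read-mapping
anomalies in whole-genome sequencing data.

`nrltr` implements a complete, tested pipeline for this detection problem:

1. **discover** — classify read pairs and collect *anchor* evidence:
   mapped reads whose mate (or clipped tail) matches an LTR element
   library;
2. **call** — cluster anchors into candidate insertion breakpoints,
   filter by support and evidence tier, merge nearby calls, and detect the
   4–5 bp target site duplication (TSD) from soft-clip stacks;
3. **assemble** — extract reads near the TSD, build 5′ and 3′ junction
   contigs by greedy overlap-layout-consensus, and reconstruct the
   inserted LTR as the TSD-to-TSD region;
4. **classify** — group reconstructed LTRs into the LTR-A / LTR-B families
   (progressive alignment, Kimura three-parameter distances, neighbor
   joining), assign U3 repeat subtypes (A1/A2/B1/B2/B3), and type elements
   against a pol-region panel;
5. **evaluate** — score calls and reconstructions against a ground truth.

A first-class synthetic-data module generates reference genomes, element
libraries with controlled U3 repeat structure, donor genomes carrying
TSD-flanked insertions, and paired-end reads with *truth alignments*, so
that every stage is verifiable end to end with no external data and no
aligner.

## The insertion signature

An integrated element duplicates a short host target site: the donor
chromosome reads `...ref[..p+L-1] | element | ref[p..]...`, with the same
`L`-long target site (here `L` of 4 or 5) on both sides of the element.
In reads mapped against the *reference*, this produces a characteristic
pile-up at the insertion point:

* pairs fully inside flanking sequence map as **proper** pairs;
* pairs straddling a junction leave one mate unmapped (**singletons**)
  whose sequence matches the element;
* reads crossing a junction are **soft-clipped** there: reads approaching
  from the 5′ side have alignments ending at the *last* base of the
  duplicated target site, reads from the 3′ side start at its *first*
  base. The two clip stacks therefore overlap by exactly the TSD length —
  this overlap *is* the TSD call, and its sequence is always taken from
  the reference, never from read bases.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `min_support` | 10 | reads | minimum anchors for a breakpoint call |
| `merge_window` | 500 | bp | calls within this distance are one insertion |
| `min_filter_level` | 7 | tier (1–8) | evidence tier kept for reporting |
| `max_depth` | 10,000 | reads | repeat-region guard on cluster depth |
| `cluster_window` | insert mean + 2 sd | bp | anchor single-linkage window |
| `window` (assembly) | 150 | bp | read extraction window around the TSD |
| `min_identity` | 0.80 | proportion | library-hit identity floor |
| `min_hit_length` | 36 | bp | library-hit length floor (mate hits) |
| `min_clip` | 10 | bp | informative soft-clip length |
| `min_overlap` / identity | 40 / 0.90 | bp / proportion | assembler merge rule |
| `read_length` / `fragment_mean` | 150 / 350 | bp | sequencing geometry |

The support, merge, filter-level, depth and window defaults are the
operating point of the RetroSeq-based detection protocol this package
re-implements; the
identity/length floors mirror the defaults of the RetroSeq family of
callers, and the assembler thresholds are CAP3-like. All are configurable
through the `*_params()` constructors and the command-line flags.

### Filter levels

RetroSeq-style callers grade calls into tiers 1–8 but the tier semantics
are not formally documented. This package uses a declared
re-interpretation preserving the operational rule "keep tiers ≥ 7": a base
level of 5, plus one bonus each for (a) anchors on both sides, (b) ≥ 2
soft-clip reads abutting the breakpoint within 10 bp, and (c) an anchor
interval no wider than twice the read length. A clean two-sided insertion
scores 7–8; one-sided or diffuse clusters score 5–6 and are *flagged*
(`low_level`), not deleted — mirroring the handling of loci supported by a
single TSD.

### TSD detection

The 5′ stack's modal right-clip end `L` and the 3′ stack's modal
left-clip start `R` (each needing ≥ 2 reads; the mode guards against
single chimeric reads) yield a TSD call when `L − R + 1 ∈ {4, 5}`. When a
4-bp and a 5-bp solution are mode-tied, the one with more supporting reads
wins, then the shorter. Requiring ≥ 2 reads per stack is this package's
decision; manual genome-browser inspection, which this step replaces,
implies no such rule.

### Call merging

"Calls within 500 bp are considered identical" is implemented as
keep-best-drop-rest under the lexicographic key (filter level, total
support, leftmost position) — dropping *all* members of a chain would
delete every true call observed twice.

## Junction assembly and reconstruction

Reads whose alignments end within 150 bp upstream of the TSD (plus
unmapped mates of in-window anchors) form the 5′ set; the mirror rule
forms the 3′ set. Each set is assembled by a greedy
overlap-layout-consensus assembler: the longest gapless overlap of at
least 40 bp at ≥ 0.90 identity is merged first, consensus is per-column
coverage-weighted majority with ties broken alphabetically, and reads are
used in both orientations. Because unique reads are canonically ordered
and every tie-break is deterministic, the contig set is invariant to input
order. The assembler is gapless by design: the error model is
substitutions-only, so true overlaps contain no indels.

A contig is split into its reference and element parts by local alignment
against ±1 kb of reference around the call. The maximal local alignment
can absorb element bases that match the reference by chance just past the
junction, so the boundary is then re-anchored *exactly*: the 20 reference
bases ending at (starting at) the TSD boundary must occur literally in the
contig consensus. The remainder must hit the element library at ≥ 0.80
identity to qualify as a junction contig.

The 5′ and 3′ element segments are merged over their best overlap;
columns where the two contigs' consensus bases disagree are counted into
`overlap_mismatches` and reported, never silently resolved — for a
provirus, the two junction contigs sample the two LTR *copies*, so a
mutation between the 5′ and 3′ LTR surfaces here. The reported sequence
spans TSD to TSD inclusive, matching the convention that published LTR
lengths include their TSDs. Sides that cannot be joined are reported as
`5p_only`/`3p_only` rather than guessed.

Provirus internals are *not* assembled: at 150-bp reads the internal
`gag`/`pol`/`env` region is unresolvable repetitive sequence, and the
standard practice is to confirm internals by long-range PCR (wet-lab work,
out of scope). The pipeline reports LTR junctions and types elements from
sequence, which is the part short reads can support.

## Classification

* **Alignment.** Progressive alignment with a 6-mer-distance UPGMA guide
  tree and affine-gap profile merging (+1/−1, open −4, extend −1). This is
  a deliberate simplification of log-expectation multiple aligners; for
  ~600-bp LTR sets it produces alignments on which distance-based
  clustering is stable.
* **Distances.** Kimura three-parameter:
  `d = −¼ ln[(1−2P−2Q)(1−2P−2R)(1−2Q−2R)]` with `P` transitions and
  `Q`, `R` the two transversion classes; columns with a gap or ambiguity
  code in either row are excluded (pairwise deletion). Non-positive
  factors mark the pair *saturated*, reported as a configurable ceiling
  (default 5.0 substitutions/site) rather than an infinity.
* **Tree.** Canonical neighbor joining. NJ on plain K3P distances replaces
  a maximum-likelihood search with gamma rate heterogeneity: the quantity
  that matters downstream is the two-cluster LTR-A/LTR-B split, which NJ
  reproduces on separable data (and is exact on additive matrices, which
  the tests verify). ML-specific statistics (log-likelihood, gamma shape)
  are explicitly not reproduced. Negative NJ branches are clamped to zero
  with the deficit moved to the sister branch.
* **U3 boundary.** Published LTR annotations give no U3/R/U5 coordinates,
  so the package locates the TATA box (first `TATAWA` in the 3′ half) and
  takes U3 as everything before it, falling back to the first 65% of the
  LTR. This is a convention, exposed in `subtype_config()`.
* **Subtypes.** B-type requires both an 18-bp and a 21-bp tandem array
  (≥ 2 full copies each) in U3; B1/B2/B3 follow the total 18+21 copy
  number with tier boundaries 4/6 — a declared convention, since the
  source material states only that copy numbers "varied". A-type LTRs are
  A2 when a shorter sub-repeat array (8–15 bp unit) is present, else A1.
  Sub-repeat scanning is exact-match by default: with units as short as
  8 bp, a mismatch tolerance would fire on random sequence at an
  unacceptable rate. Repeat arrays are detected de novo by period (seed
  window extended while the next block matches the running consensus with
  ≤ 3 mismatches), not by fixed motif, because exact repeat consensus
  sequences are only available graphically.
* **Orientation.** Classification considers both strands and scores them
  by (TATA box found, 18/21 copies in U3, sub-repeats in U3), with a
  lexicographic final tie-break, making `classify_subtype()` invariant to
  reverse complementation.
* **PERV typing** follows the published procedure — best local-alignment
  hit against a typed pol-region panel — with two guards: hits shorter
  than 50 bp are ignored (maximal-scoring local alignments between random
  sequences are short and high-identity) and a top-two identity gap under
  0.5% is reported `unknown`. Whether pol alone can separate types on real
  data is debatable (pol is conserved; env differs); the panel is an
  argument, so an env panel can be swapped in.

## The synthetic-data module

The generator emulates a short-read WGS design typical of PERV surveys:
150-bp paired-end reads from
~350-bp fragments (sd 50, a typical PCR-free library width) at
configurable coverage, mapped to a reference of known composition, with
solo-LTR and full-provirus insertions each flanked by a 4–5 bp duplicated
target site and spaced ≥ 2 kb apart (so neighbouring anchor clusters
cannot interact within the 500-bp merge window). Truth alignments are
computed by mapping each read's donor interval back through the insertion
events — reads inside elements become (mate-anchored) unmapped records,
junction-spanning reads are soft-clipped at the junction when at least
20 bp align (a seed-aligner approximation). Per-base errors are
substitutions only, and the error-free mode is what the verification suite
uses; quality scores are not modelled.

Default LTR lengths (598–650 bp across the five subtype specs) sit in the
lower-middle of the observed 598–710 bp range. This is deliberate: with
350 ± 50 bp fragments, junction contigs reach ~330–430 bp into the element
from each side, so both-side reconstruction of the longest observed LTRs
(> ~700 bp) needs larger fragments or deeper coverage than the default
conditions provide — a real limitation of short-fragment data that the
package reports honestly as one-sided reconstructions rather than hiding.
Provirus internals default to 7 kb; published loci report only a long-PCR
product band of 8–10 kb, so this is a convention, not a measured value.

What passing synthetic tests does **not** show: robustness to indel
sequencing errors, to reference mis-assembly, to segmental duplications
that mimic discordant signatures, or to insertions into pre-existing
repeats — real WGS data contain all of these, and in practice they are
resolved by manual browser inspection and PCR validation.

## Numerical and degenerate-input choices

* All file coordinates are 1-based inclusive (SAM convention); BED output
  is 0-based half-open; internal arithmetic is 0-based half-open where
  convenient.
* Alignment scoring is match +1, mismatch −1, gap of length `k` costs
  `2 + k`; `N` never matches. Local alignments with no positive-scoring
  cell are reported empty (score 0), not as a 1-column alignment.
* `evaluate()` reports precision as undefined (`NA`) when no calls were
  made — never 0/0 = 0. Greedy breakpoint matching is one-to-one within
  ±10 bp (≈ twice the TSD length), stable under input order.
* Reconstruction identity measures base-level *accuracy*: a one-sided
  reconstruction is compared against the truth prefix or suffix it claims
  to cover, while its incompleteness is counted in `completeness_counts`
  (mirroring the published accounting, which lists single-TSD loci as a
  category of their own rather than as failures). Identity is matches over
  the longer sequence length, so over- and under-calls both cost.
* Cluster depth guards use the anchor count over the cluster interval;
  a full pileup depth is not recomputed.
* Empty FASTA files parse as empty sets; every parser rejects, with a
  located error (line number), files its writer would not produce.

## Verification problem sizes

The test suite builds a shared 250-kb/6-insertion/40× simulation for the
stage-level checks, and the acceptance checks run the full pipeline on a
2-Mb genome with 20 planted insertions at error-free 50× — the scale at
which every planted locus is recovered with exact breakpoints, exact TSDs
and 100% reconstruction identity, and a zero-insertion run yields zero
calls. Oracle checks (brute-force Smith–Waterman, exhaustive
single-linkage and interval-graph merging, additive-matrix NJ, K3P closed
form, an independent K3P implementation) pin the core computations
independently of the pipeline.

## Known limitations

* Genotyping (het/hom) and multi-sample joint calling are out of scope;
  per-sample results are compared downstream by `summarize_loci()`.
* The assembler is gapless; indel sequencing errors would fragment
  contigs rather than corrupt them.
* LTRs much longer than ~2×(fragment − read) resist both-side
  reconstruction at default geometry (reported one-sided).
* The NJ tree carries no bootstrap support; it is a clustering device for
  the A/B split, not a dated phylogeny. Insertion dating from 5′/3′ LTR
  divergence is not modelled — the per-locus `overlap_mismatches` count
  surfaces the raw observation.
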