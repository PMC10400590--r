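#' Build a three-letter bisulfite alignment index
#'
#' Stores each contig twice in C-to-T converted space (forward strand and
#' reverse complement) for seed-and-extend alignment of bisulfite reads in
#' all four orientations (OT, OB, CTOT, CTOB).
#'
#' @param genome A [sim_genome()] object (or named character vector of
#'   contig sequences).
#' @param k Seed length (>= 12; default 24).
#' @return A `bs_index` object.
#' @export
bs_index <- function(genome, k = 24) {
  k <- .check_count(k, "k", lower = 12)
  seqs <- if (inherits(genome, "sim_genome")) genome$seq else genome
  contigs <- if (inherits(genome, "sim_genome")) genome$contigs else
    tibble::tibble(contig = names(seqs), length = nchar(seqs),
                   species = "A", is_spike = FALSE)
  short <- contigs$length < k
  if (any(short)) {
    warn(sprintf("%d contig(s) shorter than the seed length are unseedable",
                 sum(short)))
  }
  structure(
    list(seq = seqs,
         conv_fwd = gsub("C", "T", seqs, fixed = TRUE),
         conv_rev = stats::setNames(gsub("C", "T", .revcomp(seqs),
                                         fixed = TRUE), names(seqs)),
         contigs = contigs, k = k),
    class = "bs_index")
}

#' @export
print.bs_index <- function(x, ...) {
  cat(sprintf("<bs_index> %d contigs, k = %d\n", nrow(x$contigs), x$k))
  invisible(x)
}

.bs_modes <- c("OT", "OB", "CTOT", "CTOB")

#' Align bisulfite reads against a three-letter index
#'
#' Reads are C-to-T converted and seeded (read start and mid-read) against
#' the converted references in the requested orientations; candidates are
#' extended by substitution-only edit distance. Only a unique best hit
#' (strictly better than the runner-up) with at most `max_edit` mismatches is
#' reported; ties are ambiguous, everything else unmapped.
#'
#' @param reads Tibble with a read sequence column `seq` (plus any id
#'   columns, carried through), or a character vector of sequences.
#' @param index A [bs_index()] object.
#' @param max_edit Maximum mismatches (default 3).
#' @param mode_set Orientations to consider, a subset of
#'   `c("OT","OB","CTOT","CTOB")`. Original-strand reads use OT/OB; PBAT-like
#'   (complementary-strand) reads use CTOT/CTOB.
#' @return The input tibble with columns `contig`, `start`, `end` (0-based
#'   half-open), `mode`, `nm` and `status` (`"unique"`, `"ambiguous"`,
#'   `"unmapped"`) appended.
#' @export
bs_align <- function(reads, index, max_edit = 3, mode_set = .bs_modes) {
  stopifnot(inherits(index, "bs_index"))
  mode_set <- match.arg(mode_set, .bs_modes, several.ok = TRUE)
  if (is.character(reads)) reads <- tibble::tibble(seq = reads)
  reads <- tibble::as_tibble(reads)
  if (!"seq" %in% names(reads)) {
    abort("`reads` must have a `seq` column.",
          class = "dropmeth_invalid_parameter")
  }
  res <- cpp_bs_align(reads$seq, unname(index$conv_fwd),
                      unname(index$conv_rev), index$k,
                      as.integer(max_edit))
  out <- reads
  out$contig <- index$contigs$contig[res$contig_idx]
  out$start <- res$start
  out$end <- res$end
  out$mode <- .bs_modes[res$mode_idx + 1L]
  out$nm <- res$nm
  out$status <- c("unmapped", "unique", "ambiguous")[res$status + 1L]
  # restrict to the requested orientation set
  drop <- out$status == "unique" & !(out$mode %in% mode_set)
  if (any(drop)) {
    out$status[drop] <- "unmapped"
    out$contig[drop] <- NA_character_
    out$start[drop] <- NA_integer_
    out$end[drop] <- NA_integer_
    out$mode[drop] <- NA_character_
    out$nm[drop] <- NA_integer_
  }
  out
}

#' Align both mates of demultiplexed read pairs
#'
#' R1 and R2 are aligned separately: R2 in the original-strand orientations
#' (OT/OB) and R1, which reads the random-primed complementary strand, in the
#' PBAT orientations (CTOT/CTOB).
#'
#' @param demux A [demultiplex()] result (or its `$reads` tibble).
#' @param index A [bs_index()] object.
#' @param max_edit Maximum mismatches.
#' @return Tibble with one row per mate: `read_id`, `mate` (`"R1"`/`"R2"`),
#'   `barcode`, `seq`, and the [bs_align()] columns.
#' @export
align_mates <- function(demux, index, max_edit = 3) {
  reads <- if (inherits(demux, "demux_result")) demux$reads else
    tibble::as_tibble(demux)
  r1 <- tibble::tibble(read_id = reads$read_id, mate = "R1",
                       barcode = reads$barcode, seq = reads$r1)
  r2 <- tibble::tibble(read_id = reads$read_id, mate = "R2",
                       barcode = reads$barcode, seq = reads$r2)
  dplyr::bind_rows(
    bs_align(r1, index, max_edit, mode_set = c("CTOT", "CTOB")),
    bs_align(r2, index, max_edit, mode_set = c("OT", "OB"))) |>
    dplyr::arrange(.data$barcode, .data$read_id, .data$mate)
}

#' Per-barcode mapping efficiency
#'
#' Fraction of submitted trimmed mates that aligned uniquely; R1 and R2 count
#' separately. This is the discriminating statistic between cell-associated
#' and noise barcodes.
#'
#' @param alignments An [align_mates()] tibble (must contain `barcode` and
#'   `status`).
#' @return Tibble (`barcode`, `n_reads`, `n_unique`, `efficiency`).
#' @export
mapping_efficiency <- function(alignments) {
  if (nrow(alignments) == 0) {
    abort("no alignments supplied.", class = "dropmeth_invalid_parameter")
  }
  alignments |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(n_reads = dplyr::n(),
                     n_unique = sum(.data$status == "unique"),
                     efficiency = .data$n_unique / .data$n_reads,
                     .groups = "drop")
}

#' Write alignments as a SAM-like TSV
#'
#' Plain-text tab-separated alignment table (read, mate, barcode, contig,
#' start, end, mode, NM, status); intervals 0-based half-open.
#'
#' @param alignments An [align_mates()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alignments, path) {
  cols <- intersect(c("read_id", "mate", "barcode", "contig", "start", "end",
                      "mode", "nm", "status"), names(alignments))
  readr::write_tsv(alignments[, cols], path)
  invisible(path)
}
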