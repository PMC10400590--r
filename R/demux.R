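#' Extract the cell barcode from R2 sequences
#'
#' The barcode occupies bases 25-39 of R2 (1-based, inclusive). Reads shorter
#' than 39 bases cannot carry a barcode and return `NA`.
#'
#' @param r2 Character vector of raw R2 sequences.
#' @param layout A [read_layout()].
#' @return Character vector of 15-mers (`NA` for short reads).
#' @export
extract_barcode <- function(r2, layout = read_layout()) {
  from <- layout$r2_prefix_len + 1L
  to <- layout$r2_prefix_len + layout$barcode_len
  out <- substr(r2, from, to)
  out[nchar(r2) < to] <- NA_character_
  out
}

#' Build a barcode whitelist from raw read counts
#'
#' Keeps the `ceiling(multiplier * expected_cells)` barcodes with the most
#' raw reads (ties at the cutoff broken lexicographically) and builds a
#' Hamming-distance-1 correction map over A/C/G/T substitutions; observed
#' barcodes within distance 1 of exactly one accepted barcode are corrected
#' to it, neighbours of two or more accepted barcodes are left unassigned.
#'
#' @param counts Data frame with columns `barcode` and `n` (raw read count),
#'   or a raw barcode character vector to be tabulated.
#' @param expected_cells Expected number of cells (X).
#' @param multiplier Selection multiplier (default 2.5, i.e. top 2.5X).
#' @return A `barcode_whitelist` object: `$accepted` tibble (`barcode`, `n`),
#'   `$map` named character vector from observed 15-mer to accepted barcode.
#' @export
build_whitelist <- function(counts, expected_cells, multiplier = 2.5) {
  counts <- .as_barcode_counts(counts)
  expected_cells <- .check_count(expected_cells, "expected_cells", lower = 1)
  m <- as.integer(ceiling(multiplier * expected_cells))
  accepted <- .top_barcodes(counts, m)
  if (nrow(accepted) < m) {
    warn(sprintf("only %d distinct barcodes available; requested %d",
                 nrow(accepted), m))
  }
  structure(list(accepted = accepted,
                 map = .hamming1_map(accepted$barcode),
                 requested = m),
            class = "barcode_whitelist")
}

.as_barcode_counts <- function(counts) {
  if (is.character(counts)) {
    counts <- tibble::as_tibble(table(barcode = counts[!is.na(counts)]),
                                .name_repair = "minimal")
    names(counts) <- c("barcode", "n")
    counts$n <- as.integer(counts$n)
  }
  counts <- tibble::as_tibble(counts)
  if (!all(c("barcode", "n") %in% names(counts)) || nrow(counts) == 0) {
    abort("`counts` must have columns barcode and n (non-empty).",
          class = "dropmeth_invalid_parameter")
  }
  counts
}

.top_barcodes <- function(counts, m) {
  counts |>
    dplyr::arrange(desc(.data$n), .data$barcode) |>
    dplyr::slice(seq_len(min(m, dplyr::n())))
}

# Hamming-1 correction map over the sequencing alphabet; ambiguous neighbours
# (reachable from >= 2 accepted barcodes) map to nothing
.hamming1_map <- function(accepted) {
  len <- nchar(accepted[1])
  alphabet <- c("A", "C", "G", "T")
  neigh <- lapply(accepted, function(b) {
    out <- character(len * 3L)
    k <- 0L
    for (i in seq_len(len)) {
      orig <- substr(b, i, i)
      for (a in alphabet[alphabet != orig]) {
        v <- b
        substr(v, i, i) <- a
        k <- k + 1L
        out[k] <- v
      }
    }
    out
  })
  nb <- unlist(neigh, use.names = FALSE)
  owner <- rep(accepted, lengths(neigh))
  dup <- nb[duplicated(nb)]
  keep <- !(nb %in% dup) & !(nb %in% accepted)
  map <- c(stats::setNames(accepted, accepted),
           stats::setNames(owner[keep], nb[keep]))
  map
}

#' Demultiplex a read-pair table by cell barcode
#'
#' Extracts and error-corrects the R2 barcode of each pair against a
#' whitelist, clips the artificial bases (15 off R1, 40 off R2), and returns
#' the trimmed pairs with their assigned barcode. Reads whose barcode does
#' not correct to an accepted barcode are reported unassigned; reads too
#' short to carry a barcode are tallied separately. Conservation holds:
#' assigned + unassigned + short equals the input count.
#'
#' @param reads Tibble with `read_id`, `r1`, `r2` (raw sequences), e.g. from
#'   [sim_reads()] or [read_fastq_pair()].
#' @param whitelist A [build_whitelist()] object.
#' @param layout A [read_layout()].
#' @return A `demux_result`: `$reads` tibble (`read_id`, `barcode`, `r1`,
#'   `r2` — trimmed; unassigned reads excluded), `$qc` tibble with assigned /
#'   unassigned / short counts.
#' @export
demultiplex <- function(reads, whitelist, layout = read_layout()) {
  stopifnot(inherits(whitelist, "barcode_whitelist"))
  reads <- tibble::as_tibble(reads)
  if (!all(c("read_id", "r1", "r2") %in% names(reads))) {
    abort("`reads` must have columns read_id, r1, r2.",
          class = "dropmeth_invalid_parameter")
  }
  raw_bc <- extract_barcode(reads$r2, layout)
  short <- is.na(raw_bc)
  corrected <- unname(whitelist$map[raw_bc])
  assigned <- !short & !is.na(corrected)

  out <- reads[assigned, ]
  out$barcode <- corrected[assigned]
  out$r1 <- substr(out$r1, layout$r1_clip + 1L, nchar(out$r1))
  out$r2 <- substr(out$r2, layout$r2_clip + 1L, nchar(out$r2))
  out <- out[order(out$barcode, out$read_id),
             c("read_id", "barcode", "r1", "r2")]

  n_assigned <- sum(assigned)
  n_short <- sum(short)
  structure(
    list(reads = out,
         qc = tibble::tibble(
           total = nrow(reads),
           assigned = n_assigned,
           unassigned = nrow(reads) - n_assigned - n_short,
           short = n_short)),
    class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("<demux_result>\n")
  print(x$qc)
  invisible(x)
}

#' Per-barcode raw read counts from raw R2 sequences
#'
#' Tallies extracted (uncorrected) barcodes, the input to whitelist building
#' and candidate selection.
#'
#' @param reads Tibble with an `r2` column of raw sequences.
#' @param layout A [read_layout()].
#' @return Tibble (`barcode`, `n`), most reads first.
#' @export
barcode_counts <- function(reads, layout = read_layout()) {
  bc <- extract_barcode(reads$r2, layout)
  .as_barcode_counts(bc[!is.na(bc)]) |>
    dplyr::arrange(desc(.data$n), .data$barcode)
}
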