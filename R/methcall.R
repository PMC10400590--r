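#' Remove PCR duplicates per barcode
#'
#' Keeps one representative per (barcode, contig, start, end, mode); among
#' duplicates the alignment with the lowest edit distance, then the lowest
#' read id, wins. Non-unique alignments are dropped first.
#'
#' @param alignments An [align_mates()] tibble.
#' @return The deduplicated alignment tibble (status `"unique"` only).
#' @export
dedup_alignments <- function(alignments) {
  alignments |>
    dplyr::filter(.data$status == "unique") |>
    dplyr::arrange(.data$barcode, .data$contig, .data$start, .data$end,
                   .data$mode, .data$nm, .data$read_id) |>
    dplyr::distinct(.data$barcode, .data$contig, .data$start, .data$end,
                    .data$mode, .keep_all = TRUE)
}

# trinucleotide decoding for the C++ context code
.ctx_table <- local({
  b <- c("A", "C", "G", "T")
  codes <- 0:127
  n1 <- (codes %% 64) %/% 4
  n2 <- codes %% 4
  paste0("C", b[n1 + 1], b[n2 + 1])
})

#' Call per-cytosine methylation into an allc table
#'
#' For every reference cytosine covered on its informative strand, a retained
#' C in the read adds a methylated count and a T an unmethylated count; other
#' read bases (sequencing errors) are ignored. Context is the reference
#' trinucleotide on the cytosine's strand, classed CG when the next base is
#' G and CH otherwise. CpG sites are not strand-collapsed (see
#' [collapse_cpg()]).
#'
#' @param alignments Deduplicated alignments from [dedup_alignments()] (must
#'   retain the `seq` column).
#' @param genome The reference [sim_genome()].
#' @return An allc tibble: `barcode`, `chrom`, `pos` (1-based), `strand`,
#'   `context`, `class`, `mc`, `cov`, sorted by barcode and position.
#' @export
call_methylation <- function(alignments, genome) {
  stopifnot(inherits(genome, "sim_genome"))
  if (nrow(alignments) == 0) {
    abort("no alignments to call.", class = "dropmeth_invalid_parameter")
  }
  if (!all(c("seq", "barcode", "contig", "start", "mode") %in%
             names(alignments))) {
    abort("alignments must carry seq, barcode, contig, start, mode.")
  }
  contig_idx <- match(alignments$contig, genome$contigs$contig)
  mode_idx <- match(alignments$mode, .bs_modes) - 1L
  chunks <- split(seq_len(nrow(alignments)), alignments$barcode)
  res <- lapply(chunks, function(idx) {
    obs <- cpp_call_meth(alignments$seq[idx], contig_idx[idx],
                         alignments$start[idx], mode_idx[idx],
                         unname(genome$seq))
    dt <- data.table::as.data.table(obs)
    agg <- dt[, list(mc = sum(meth), cov = .N),
              by = list(contig_idx, pos0, strand_idx, ctx_code)]
    agg
  })
  out <- data.table::rbindlist(res, idcol = "barcode")
  data.table::setorder(out, barcode, contig_idx, pos0, strand_idx)
  tibble::tibble(
    barcode = out$barcode,
    chrom = genome$contigs$contig[out$contig_idx],
    pos = out$pos0 + 1L,
    strand = c("+", "-")[out$strand_idx + 1L],
    context = .ctx_table[out$ctx_code + 1L],
    class = ifelse(out$ctx_code >= 64L, "CG", "CH"),
    mc = as.integer(out$mc),
    cov = as.integer(out$cov))
}

#' Bisulfite conversion rate from the spike-in contig
#'
#' One minus the pooled methylation rate over the fully unmethylated
#' spike-in contig.
#'
#' @param allc An allc tibble.
#' @param spike_contig Spike-in contig name (default `"spike"`).
#' @param min_calls Minimum total coverage required (default 1000); below it
#'   the value is withheld (`NA`) with a warning.
#' @return A single conversion-rate estimate in `[0, 1]`.
#' @export
conversion_rate <- function(allc, spike_contig = "spike", min_calls = 1000) {
  sp <- allc[allc$chrom == spike_contig, ]
  tot <- sum(sp$cov)
  if (tot < min_calls) {
    warn(sprintf("only %d spike-in calls (< %d); conversion rate withheld",
                 tot, min_calls))
    return(NA_real_)
  }
  1 - sum(sp$mc) / tot
}

#' Global methylation levels per barcode
#'
#' Pooled sum(mc)/sum(cov) per context class, spike-in contig excluded.
#'
#' @param allc An allc tibble.
#' @param class `"CG"` or `"CH"`.
#' @param spike_contig Spike-in contig name to exclude (`NULL` for none).
#' @return Tibble (`barcode`, `class`, `level`, `n_sites`, `coverage`).
#'   Barcodes with zero coverage in the class are absent (flagged by a
#'   warning if the filtered table is empty).
#' @export
global_levels <- function(allc, class = c("CG", "CH"),
                          spike_contig = "spike") {
  class <- match.arg(class)
  cls <- class
  x <- allc[allc$class == cls, ]
  if (!is.null(spike_contig)) x <- x[x$chrom != spike_contig, ]
  if (nrow(x) == 0) {
    warn(sprintf("no %s coverage; global level undefined", cls))
    return(tibble::tibble(barcode = character(), class = character(),
                          level = numeric(), n_sites = integer(),
                          coverage = integer()))
  }
  dt <- data.table::data.table(barcode = x$barcode, mc = x$mc, cov = x$cov)
  agg <- dt[, list(level = sum(mc) / sum(cov), n_sites = .N,
                   coverage = sum(cov)), by = barcode]
  data.table::setorder(agg, barcode)
  tibble::tibble(barcode = agg$barcode, class = cls, level = agg$level,
                 n_sites = agg$n_sites, coverage = agg$coverage)
}

#' Collapse CpG strands
#'
#' Merges the plus- and minus-strand cytosines of each CpG dinucleotide into
#' one record keyed by the plus-strand C position, for CpG-count reporting.
#'
#' @param allc An allc tibble.
#' @return Tibble (`barcode`, `chrom`, `pos`, `mc`, `cov`) of collapsed CpGs.
#' @export
collapse_cpg <- function(allc) {
  x <- allc[allc$class == "CG", ]
  dt <- data.table::data.table(
    barcode = x$barcode, chrom = x$chrom,
    pos = ifelse(x$strand == "-", x$pos - 1L, x$pos),
    mc = x$mc, cov = x$cov)
  agg <- dt[, list(mc = sum(mc), cov = sum(cov)),
            by = list(barcode, chrom, pos)]
  data.table::setorder(agg, barcode, chrom, pos)
  tibble::as_tibble(agg)
}

#' Expected unique reads at assigned sequencing depths
#'
#' Exact subsampling-without-replacement expectation: for a barcode with `N`
#' aligned reads of which fragment `f` occurs `m_f` times, the expected
#' number of unique fragments among `d` sampled reads is
#' \eqn{\sum_f 1 - \binom{N - m_f}{d} / \binom{N}{d}}. Monotone
#' non-decreasing and concave in `d`; plateaus at the library complexity.
#'
#' @param alignments Pre-deduplication unique-status alignments (tibble with
#'   `barcode`, `contig`, `start`, `end`, `mode`).
#' @param depths Increasing integer vector of assigned depths.
#' @return Tibble (`barcode`, `depth`, `expected_unique`). Depths above a
#'   barcode's read count are truncated with a warning.
#' @export
saturation_curve <- function(alignments, depths) {
  if (is.unsorted(depths)) {
    abort("`depths` must be sorted ascending.",
          class = "dropmeth_invalid_parameter")
  }
  aln <- alignments |> dplyr::filter(.data$status == "unique")
  mult <- aln |>
    dplyr::count(.data$barcode, .data$contig, .data$start, .data$end,
                 .data$mode, name = "m")
  res <- mult |>
    dplyr::group_by(.data$barcode) |>
    dplyr::group_map(function(g, key) {
      N <- sum(g$m)
      d_use <- pmin(depths, N)
      if (any(depths > N)) {
        warn(sprintf("depths above %d reads truncated for barcode %s",
                     N, key$barcode))
      }
      eu <- vapply(d_use, function(d) {
        if (d == 0) return(0)
        sum(1 - exp(lchoose(N - g$m, d) - lchoose(N, d)))
      }, numeric(1))
      tibble::tibble(barcode = key$barcode, depth = depths,
                     expected_unique = eu)
    }) |>
    purrr::list_rbind()
  res
}

#' Per-barcode quality-control summary
#'
#' Combines mapping efficiency, unique-read counts, per-species aligned-read
#' fractions, global methylation levels, covered CpG counts and the
#' conversion rate into the per-cell QC table used for cell calling and
#' species classification.
#'
#' @param alignments All aligned mates from [align_mates()].
#' @param allc The allc tibble from [call_methylation()] on deduplicated
#'   alignments.
#' @param genome The reference [sim_genome()] (for species tags and the
#'   spike-in).
#' @param spike_contig Spike-in contig name.
#' @param min_spike_calls Minimum per-barcode spike calls for a conversion
#'   estimate.
#' @return Tibble with one row per barcode: `barcode`, `n_reads`,
#'   `efficiency`, `unique_reads`, per-species fractions (`frac_<tag>`),
#'   `mCG`, `mCH`, `covered_cpg`, `conversion`.
#' @export
cell_summary <- function(alignments, allc, genome, spike_contig = "spike",
                         min_spike_calls = 100) {
  eff <- mapping_efficiency(alignments)
  uniq <- dedup_alignments(alignments)
  ucount <- uniq |> dplyr::count(.data$barcode, name = "unique_reads")

  species_map <- stats::setNames(genome$contigs$species,
                                 genome$contigs$contig)
  spfrac <- uniq |>
    dplyr::mutate(species = unname(species_map[.data$contig])) |>
    dplyr::filter(.data$species != "spike") |>
    dplyr::count(.data$barcode, .data$species) |>
    dplyr::group_by(.data$barcode) |>
    dplyr::mutate(frac = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "species", values_from = "frac",
                       names_prefix = "frac_", values_fill = 0)

  gcg <- global_levels(allc, "CG", spike_contig) |>
    dplyr::select("barcode", mCG = "level")
  gch <- global_levels(allc, "CH", spike_contig) |>
    dplyr::select("barcode", mCH = "level")
  cpg <- collapse_cpg(allc[allc$chrom != spike_contig, ]) |>
    dplyr::count(.data$barcode, name = "covered_cpg")
  conv <- allc[allc$chrom == spike_contig, ] |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(conversion = ifelse(sum(.data$cov) >= min_spike_calls,
                                         1 - sum(.data$mc) / sum(.data$cov),
                                         NA_real_),
                     .groups = "drop")

  eff |>
    dplyr::left_join(ucount, by = "barcode") |>
    dplyr::left_join(spfrac, by = "barcode") |>
    dplyr::left_join(gcg, by = "barcode") |>
    dplyr::left_join(gch, by = "barcode") |>
    dplyr::left_join(cpg, by = "barcode") |>
    dplyr::left_join(conv, by = "barcode") |>
    dplyr::mutate(unique_reads = dplyr::coalesce(.data$unique_reads, 0L),
                  covered_cpg = dplyr::coalesce(.data$covered_cpg, 0L))
}

#' Write per-barcode allc files
#'
#' One tab-separated file `allc_<barcode>.tsv` per barcode, no header,
#' columns chrom, 1-based position, strand, trinucleotide context,
#' methylated count, coverage and a methylated flag (1 if `mc > 0`).
#'
#' @param allc An allc tibble.
#' @param dir Output directory (created if needed).
#' @return Character vector of paths, invisibly.
#' @export
write_allc <- function(allc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(split(allc, allc$barcode), function(x) {
    p <- file.path(dir, sprintf("allc_%s.tsv", x$barcode[1]))
    out <- x[, c("chrom", "pos", "strand", "context", "mc", "cov")]
    out$methylated <- as.integer(x$mc > 0)
    readr::write_tsv(out, p, col_names = FALSE)
    p
  }, character(1))
  invisible(unname(paths))
}

#' Read allc files into one tibble
#'
#' @param paths Paths to `allc_<barcode>.tsv` files; barcodes are recovered
#'   from the filenames.
#' @return An allc tibble.
#' @export
read_allc <- function(paths) {
  purrr::map(paths, function(p) {
    bc <- sub("^allc_(.*)\\.tsv$", "\\1", basename(p))
    x <- readr::read_tsv(p, col_names = c("chrom", "pos", "strand",
                                          "context", "mc", "cov",
                                          "methylated"),
                         col_types = "ciccii-", progress = FALSE)
    x$barcode <- bc
    x$class <- ifelse(substr(x$context, 2, 2) == "G", "CG", "CH")
    x[, c("barcode", "chrom", "pos", "strand", "context", "class", "mc",
          "cov")]
  }) |> purrr::list_rbind()
}
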