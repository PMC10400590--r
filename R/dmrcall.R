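#' Merge single-cell allc tables into a pseudobulk profile
#'
#' Per unique site, methylated counts and coverage are summed over the
#' member cells; the site set is the union. Conflicting strand or context
#' annotations at the same site indicate corrupt input and raise an error.
#'
#' @param allc An allc tibble covering the member cells (one or more
#'   barcodes).
#' @param name Name of the pseudobulk group (stored in `barcode`).
#' @return An allc tibble with a single `barcode` equal to `name`.
#' @export
merge_pseudobulk <- function(allc, name = "pseudobulk") {
  if (nrow(allc) == 0) {
    abort("empty allc input.", class = "dropmeth_invalid_parameter")
  }
  conflicts <- allc |>
    dplyr::distinct(.data$chrom, .data$pos, .data$strand, .data$context,
                    .data$class) |>
    dplyr::count(.data$chrom, .data$pos, .data$strand) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(sprintf("conflicting context annotations at %d site(s).",
                  nrow(conflicts)), class = "dropmeth_corrupt_input")
  }
  allc |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand, .data$context,
                    .data$class) |>
    dplyr::summarise(mc = sum(.data$mc), cov = sum(.data$cov),
                     .groups = "drop") |>
    dplyr::mutate(barcode = name) |>
    dplyr::select("barcode", "chrom", "pos", "strand", "context", "class",
                  "mc", "cov") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
}

#' Call CG-DMRs between two pseudobulk groups
#'
#' A self-contained two-group caller: CpG strands are collapsed, sites with
#' at least `min_cov` coverage in both groups are tested with a two-sided
#' two-proportion z-test on the pooled counts (zero-variance sites — rate 0
#' or 1 in both groups — are skipped), and p-values are Benjamini-Hochberg
#' adjusted. CpGs passing the FDR threshold anchor candidate regions;
#' same-sign CpGs at nominal `p <= support_p` extend and bridge them
#' (hotspot extension, which recovers region edges and interior CpGs whose
#' individual coverage leaves them just under the FDR threshold). Supporting
#' CpGs within `merge_dist` of each other merge into one region; a region is
#' reported when it contains at least `min_cpgs` FDR-significant anchors and
#' its pooled-rate difference is at least `min_delta` in absolute value.
#' Region q-values combine the member CpGs' z-scores (Stouffer) with BH
#' adjustment across regions.
#'
#' @param group_a,group_b Pseudobulk allc tibbles from [merge_pseudobulk()].
#' @param min_cov Minimum per-group coverage per CpG (default 5).
#' @param fdr FDR threshold on CpG q-values (default 0.05).
#' @param min_delta Minimum absolute methylation difference (default 0.1).
#' @param merge_dist Maximum gap between supporting CpGs in a region
#'   (default 500 bp).
#' @param min_cpgs Minimum FDR-significant CpGs per region (default 3).
#' @param support_p Nominal p-value for region-extending CpGs (default
#'   0.05).
#' @return Tibble of regions sorted by coordinate: `chrom`, `start`, `end`
#'   (0-based half-open), `n_cpgs` (member CpGs), `n_sig` (FDR-significant
#'   anchors), `mean_a`, `mean_b`, `diff` (a minus b, pooled within the
#'   region), `q`, `gene` (NA until [annotate_genes()]).
#' @export
call_dmrs <- function(group_a, group_b, min_cov = 5, fdr = 0.05,
                      min_delta = 0.1, merge_dist = 500, min_cpgs = 3,
                      support_p = 0.05) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_cpgs = integer(),
                          n_sig = integer(),
                          mean_a = numeric(), mean_b = numeric(),
                          diff = numeric(), q = numeric(),
                          gene = character())
  a <- collapse_cpg(group_a)
  b <- collapse_cpg(group_b)
  j <- dplyr::inner_join(a, b, by = c("chrom", "pos"),
                         suffix = c("_a", "_b")) |>
    dplyr::filter(.data$cov_a >= min_cov, .data$cov_b >= min_cov)
  if (nrow(j) == 0) {
    warn("no CpG passes the coverage filter in both groups.")
    return(empty)
  }
  r1 <- j$mc_a / j$cov_a
  r2 <- j$mc_b / j$cov_b
  p_pool <- (j$mc_a + j$mc_b) / (j$cov_a + j$cov_b)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / j$cov_a + 1 / j$cov_b))
  testable <- se > 0
  z <- ifelse(testable, (r1 - r2) / se, 0)
  p <- ifelse(testable, 2 * pnorm(-abs(z)), NA_real_)
  q <- rep(NA_real_, length(p))
  q[testable] <- p.adjust(p[testable], method = "BH")
  anchor <- !is.na(q) & q <= fdr
  if (!any(anchor)) return(empty)
  support <- !is.na(p) & p <= support_p
  if (!any(support)) return(empty)

  s <- j[support, ]
  s$z <- z[support]
  s$anchor <- anchor[support]
  s <- dplyr::arrange(s, .data$chrom, .data$pos)
  # supporting CpGs merge when close and concordant in sign
  new_region <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                    diff(s$pos) > merge_dist |
                    sign(s$z[-1]) != sign(s$z[-nrow(s)]))
  s$region <- cumsum(new_region)

  regions <- s |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos) - 1L,
      end = max(.data$pos) - 1L + 2L,  # through the CpG dinucleotide
      n_cpgs = dplyr::n(),
      n_sig = sum(.data$anchor),
      mean_a = sum(.data$mc_a) / sum(.data$cov_a),
      mean_b = sum(.data$mc_b) / sum(.data$cov_b),
      diff = .data$mean_a - .data$mean_b,
      z_comb = sum(.data$z) / sqrt(dplyr::n()),
      .groups = "drop") |>
    dplyr::filter(.data$n_sig >= min_cpgs, abs(.data$diff) >= min_delta)
  if (nrow(regions) == 0) return(empty)
  regions$q <- p.adjust(2 * pnorm(-abs(regions$z_comb)), method = "BH")
  regions |>
    dplyr::mutate(gene = NA_character_) |>
    dplyr::select("chrom", "start", "end", "n_cpgs", "n_sig", "mean_a",
                  "mean_b", "diff", "q", "gene") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Annotate DMRs to genes
#'
#' Priority rule: a region overlapping a promoter window (TSS +/- 2 kb) is
#' assigned to that gene; otherwise a gene-body overlap; otherwise the
#' nearest TSS. Ties break by smallest TSS distance, then gene name.
#'
#' @param regions A [call_dmrs()] tibble.
#' @param genes Gene annotation tibble, BED6-like: `chrom`, `start`, `end`
#'   (0-based half-open), `name`, `strand` (`"+"`/`"-"`; TSS is `start` on
#'   plus, `end - 1` on minus).
#' @param promoter_width Half-width of the promoter window (default 2000).
#' @return `regions` with the `gene` column filled.
#' @export
annotate_genes <- function(regions, genes, promoter_width = 2000) {
  genes <- tibble::as_tibble(genes)
  if (nrow(genes) == 0) {
    abort("empty gene annotation.", class = "dropmeth_invalid_parameter")
  }
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  if (nrow(regions) == 0) return(regions)
  regions$gene <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    g <- genes[genes$chrom == r$chrom, ]
    if (nrow(g) == 0) return(NA_character_)
    dist_tss <- pmax(g$tss - (r$end - 1L), r$start - g$tss, 0L)
    pick <- function(idx) {
      if (!length(idx)) return(NA_character_)
      o <- order(dist_tss[idx], g$name[idx])
      g$name[idx[o[1]]]
    }
    prom <- which(r$start < g$tss + promoter_width + 1L &
                    r$end > g$tss - promoter_width)
    if (length(prom)) return(pick(prom))
    body <- which(r$start < g$end & r$end > g$start)
    if (length(body)) return(pick(body))
    pick(seq_len(nrow(g)))
  }, character(1))
  regions
}

#' Write DMRs as a BED-compatible table
#'
#' @param regions A [call_dmrs()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(regions, path) {
  out <- regions |>
    dplyr::mutate(name = sprintf("dmr_%d", dplyr::row_number())) |>
    dplyr::select("chrom", "start", "end", "name", "diff", "q", "gene")
  readr::write_tsv(out, path)
  invisible(path)
}
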