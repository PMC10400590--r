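#' Read architecture of the droplet bisulfite library
#'
#' R2 starts with a 24-base ligation/adapter stub, carries the 15-nt cell
#' barcode at bases 25-39 (1-based, inclusive) and one junction base, then
#' genomic sequence; R1 starts with a 15-base random-primer stub. The
#' artificial stubs are regenerated per read, which makes the conventional
#' clipping parameters (15 bases off R1, 40 off R2) exactly correct.
#'
#' @param read_length Total raw read length (default 150).
#' @param r2_prefix_len Adapter stub before the barcode on R2.
#' @param barcode_len Barcode length (15).
#' @param r2_junction_len Artificial bases after the barcode on R2.
#' @param r1_artificial_len Random-primer stub on R1.
#' @return A `read_layout` list.
#' @export
read_layout <- function(read_length = 150, r2_prefix_len = 24,
                        barcode_len = 15, r2_junction_len = 1,
                        r1_artificial_len = 15) {
  stopifnot(barcode_len == 15)
  out <- list(read_length = as.integer(read_length),
              r2_prefix_len = as.integer(r2_prefix_len),
              barcode_len = as.integer(barcode_len),
              r2_junction_len = as.integer(r2_junction_len),
              r1_artificial_len = as.integer(r1_artificial_len))
  out$r2_clip <- out$r2_prefix_len + out$barcode_len + out$r2_junction_len
  out$r1_clip <- out$r1_artificial_len
  out$r1_genomic <- out$read_length - out$r1_clip
  out$r2_genomic <- out$read_length - out$r2_clip
  structure(out, class = "read_layout")
}

#' Simulate paired-end bisulfite reads with a truth sidecar
#'
#' Turns an experiment realization into raw R1/R2 read pairs. Per cell, read
#' pairs are drawn at a lognormally varying depth around `reads_per_cell`;
#' each pair is a fresh fragment with probability `1 - duplication_rate`,
#' otherwise a PCR re-emission of a previously drawn fragment of the same
#' cell (identical coordinates and conversion pattern, independent sequencing
#' errors). Fragments have truncated-normal lengths (minimum `min_frag`,
#' mirroring bead-based removal of short fragments), come from the owning
#' cell's species contigs — or from the unmethylated spike-in contig with
#' probability `spike_fraction` — and draw per-cytosine methylation from the
#' cell type's methylome. Unmethylated cytosines are read as T with
#' probability `conversion_rate`. Noise barcodes receive a small number of
#' unalignable read pairs (half adapter-dimer-like, half scrambled genomic).
#'
#' @param experiment A [sim_experiment()] object.
#' @param methylomes A [sim_methylomes()] object.
#' @param genome The [sim_genome()] used to build the methylomes.
#' @param layout A [read_layout()].
#' @param reads_per_cell Mean sequenced read pairs per cell.
#' @param depth_cv Lognormal coefficient of variation of per-cell depth.
#' @param frag_mean,frag_sd,min_frag Fragment-length model (bp).
#' @param conversion_rate Bisulfite conversion rate of unmethylated C.
#' @param seq_error Per-base uniform substitution error rate.
#' @param duplication_rate PCR duplication rate (fraction of pairs that are
#'   re-emissions).
#' @param spike_fraction Fraction of fragments from the spike-in contig.
#' @param contam_rate Fraction of a barcode's fragments originating from a
#'   random other cell (ambient contamination).
#' @param noise_reads_mean Mean read pairs per noise barcode.
#' @param store_states Keep per-fragment methylation state strings in the
#'   truth table (memory-heavy; for small runs).
#' @param seed Integer seed.
#' @return A `sim_reads` object: `$reads` tibble (`read_id`, `r1`, `r2`),
#'   `$truth` tibble (per pair: barcode, cell, type, species, fragment
#'   coordinates, strand, duplicate/noise/contaminant flags, true
#'   methylated/total CpG and CH counts on the fragment), `$layout`,
#'   `$params`.
#' @export
sim_reads <- function(experiment, methylomes, genome,
                      layout = read_layout(),
                      reads_per_cell = 2000, depth_cv = 0.2,
                      frag_mean = 300, frag_sd = 80, min_frag = 150,
                      conversion_rate = 0.99, seq_error = 0.001,
                      duplication_rate = 0.1, spike_fraction = 0.02,
                      contam_rate = 0, noise_reads_mean = 40,
                      store_states = FALSE, seed = NULL) {
  stopifnot(inherits(experiment, "sim_experiment"),
            inherits(methylomes, "sim_methylomes"),
            inherits(genome, "sim_genome"))
  .check_fraction(conversion_rate, "conversion_rate")
  .check_fraction(seq_error, "seq_error")
  .check_fraction(duplication_rate, "duplication_rate")
  .check_fraction(spike_fraction, "spike_fraction")
  .check_fraction(contam_rate, "contam_rate")
  .check_number(min_frag, "min_frag", lower = 1)
  if (min_frag < max(layout$r1_genomic, layout$r2_genomic)) {
    abort("`min_frag` must cover the genomic part of both mates.",
          class = "dropmeth_invalid_parameter")
  }
  cells <- experiment$cells
  if (nrow(cells) == 0) {
    abort("experiment contains no cells.", class = "dropmeth_invalid_parameter")
  }
  if (!all(cells$type %in% methylomes$types$type)) {
    abort("cell types in the experiment lack methylomes.")
  }
  contigs <- genome$contigs

  .with_seed(seed, {
    ## ---- per-cell depth and fragment table -------------------------------
    n_cell <- nrow(cells)
    sdlog <- sqrt(log(1 + depth_cv^2))
    depth <- pmax(1L, round(reads_per_cell *
                              stats::rlnorm(n_cell, -sdlog^2 / 2, sdlog)))
    n_pairs_tot <- sum(depth)
    pair_cell <- rep(seq_len(n_cell), depth)

    # duplication model: each pair is new w.p. (1 - d); duplicates re-emit a
    # uniformly chosen unique fragment of the same cell
    is_new <- runif(n_pairs_tot) < (1 - duplication_rate)
    # ensure every cell has at least one unique fragment
    first_of_cell <- !duplicated(pair_cell)
    is_new[first_of_cell] <- TRUE
    frag_of_pair <- integer(n_pairs_tot)
    frag_of_pair[is_new] <- seq_len(sum(is_new))
    # duplicates pick among the cell's unique fragments
    for (ci in seq_len(n_cell)) {
      idx <- which(pair_cell == ci & !is_new)
      if (!length(idx)) next
      pool <- frag_of_pair[pair_cell == ci & is_new]
      frag_of_pair[idx] <- pool[sample.int(length(pool), length(idx),
                                           replace = TRUE)]
    }

    n_frag <- sum(is_new)
    frag_cell <- pair_cell[is_new]

    # ambient contamination: fragment sourced from a random other cell
    is_contam <- runif(n_frag) < contam_rate & n_cell > 1
    src_cell <- frag_cell
    if (any(is_contam)) {
      for (i in which(is_contam)) {
        src_cell[i] <- sample(seq_len(n_cell)[-frag_cell[i]], 1)
      }
    }

    ## ---- fragment coordinates -------------------------------------------
    frag_len <- .rtrunc_norm(n_frag, frag_mean, frag_sd, min_frag)
    src_species <- cells$species[src_cell]
    frag_contig <- integer(n_frag)
    for (sp in unique(src_species)) {
      rows <- which(src_species == sp)
      ok <- which((contigs$species == sp | contigs$is_spike) &
                    contigs$length > max(frag_len[rows]) + 1)
      w <- ifelse(contigs$is_spike[ok], NA_real_,
                  as.double(contigs$length[ok]))
      w[is.na(w)] <- sum(w, na.rm = TRUE) * spike_fraction /
        max(1e-12, 1 - spike_fraction)
      frag_contig[rows] <- ok[sample.int(length(ok), length(rows),
                                         replace = TRUE, prob = w)]
    }
    frag_start <- as.integer(floor(runif(n_frag) *
                                     (contigs$length[frag_contig] - frag_len)))
    frag_strand <- as.integer(runif(n_frag) < 0.5)
    type_idx <- match(cells$type[src_cell], methylomes$types$type)

    ## ---- bisulfite conversion and mate extraction (C++) ------------------
    simres <- cpp_simulate_fragments(
      unname(genome$seq), frag_contig - 1L, frag_start, frag_len,
      frag_strand, type_idx - 1L, unname(methylomes$probs),
      conversion_rate, layout$r1_genomic, layout$r2_genomic, store_states)

    ## ---- expand PCR duplicates, build raw reads --------------------------
    f <- frag_of_pair
    n_noise_bc <- sum(experiment$barcodes$class == "noise")
    noise_bc <- experiment$barcodes$barcode[experiment$barcodes$class ==
                                              "noise"]
    n_noise_pairs <- if (n_noise_bc) rpois(n_noise_bc, noise_reads_mean) else
      integer(0)
    n_noise <- sum(n_noise_pairs)

    noise <- .noise_genomic(n_noise, layout, genome$gc_fraction %||% 0.42)

    r1_gen <- c(simres$r1[f], noise$r1)
    r2_gen <- c(simres$r2[f], noise$r2)
    bc <- c(cells$barcode[pair_cell], rep(noise_bc, n_noise_pairs))
    n_reads <- length(r1_gen)

    r1_raw <- paste0(
      cpp_random_strings(n_reads, layout$r1_artificial_len,
                         c("A", "C", "G", "T"), rep(1, 4)),
      r1_gen)
    r2_raw <- paste0(
      cpp_random_strings(n_reads, layout$r2_prefix_len,
                         c("A", "C", "G", "T"), rep(1, 4)),
      bc,
      cpp_random_strings(n_reads, layout$r2_junction_len,
                         c("A", "C", "G", "T"), rep(1, 4)),
      r2_gen)
    if (seq_error > 0) {
      r1_raw <- cpp_apply_seq_error(r1_raw, seq_error)
      r2_raw <- cpp_apply_seq_error(r2_raw, seq_error)
    }
    read_id <- sprintf("read%07d", seq_len(n_reads))

    truth <- tibble::tibble(
      read_id = read_id,
      barcode = bc,
      cell_id = c(cells$cell_id[pair_cell], rep(NA_character_, n_noise)),
      type = c(cells$type[src_cell][f], rep(NA_character_, n_noise)),
      species = c(cells$species[src_cell][f], rep(NA_character_, n_noise)),
      contig = c(contigs$contig[frag_contig][f], rep(NA_character_, n_noise)),
      start = c(frag_start[f], rep(NA_integer_, n_noise)),
      end = c(frag_start[f] + frag_len[f], rep(NA_integer_, n_noise)),
      strand = c(c("+", "-")[frag_strand + 1L][f],
                 rep(NA_character_, n_noise)),
      frag_id = c(f, rep(NA_integer_, n_noise)),
      is_dup = c(!is_new, rep(FALSE, n_noise)),
      is_noise = c(rep(FALSE, n_pairs_tot), rep(TRUE, n_noise)),
      is_contam = c(is_contam[f], rep(FALSE, n_noise)),
      cg_meth = c(simres$cg_meth[f], rep(NA_integer_, n_noise)),
      cg_total = c(simres$cg_total[f], rep(NA_integer_, n_noise)),
      ch_meth = c(simres$ch_meth[f], rep(NA_integer_, n_noise)),
      ch_total = c(simres$ch_total[f], rep(NA_integer_, n_noise)))
    if (store_states) {
      truth$states <- c(simres$states[f], rep(NA_character_, n_noise))
    }

    structure(
      list(reads = tibble::tibble(read_id = read_id, r1 = r1_raw,
                                  r2 = r2_raw),
           truth = truth, layout = layout,
           params = list(reads_per_cell = reads_per_cell,
                         depth_cv = depth_cv, frag_mean = frag_mean,
                         frag_sd = frag_sd, min_frag = min_frag,
                         conversion_rate = conversion_rate,
                         seq_error = seq_error,
                         duplication_rate = duplication_rate,
                         spike_fraction = spike_fraction,
                         contam_rate = contam_rate,
                         noise_reads_mean = noise_reads_mean,
                         seed = seed)),
      class = "sim_reads")
  })
}

# truncated normal fragment lengths by rejection
.rtrunc_norm <- function(n, mean, sd, lower) {
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[out[bad] < lower]
  }
  as.integer(out)
}

# unalignable background for noise barcodes: half adapter-dimer repeats,
# half scrambled genome-composition sequence
.noise_genomic <- function(n, layout, gc) {
  if (n == 0) return(list(r1 = character(0), r2 = character(0)))
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
  dimer <- strrep(adapter, ceiling(layout$read_length / nchar(adapter)))
  is_dimer <- seq_len(n) %% 2L == 0L
  w <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  scr1 <- cpp_random_strings(n, layout$r1_genomic, c("A", "C", "G", "T"), w)
  scr2 <- cpp_random_strings(n, layout$r2_genomic, c("A", "C", "G", "T"), w)
  list(
    r1 = ifelse(is_dimer, substr(dimer, 1, layout$r1_genomic), scr1),
    r2 = ifelse(is_dimer, substr(dimer, 1, layout$r2_genomic), scr2))
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(
    "<sim_reads> %d read pairs (%d noise), %d barcodes, layout %d bp\n",
    nrow(x$reads), sum(x$truth$is_noise),
    length(unique(x$truth$barcode)), x$layout$read_length))
  invisible(x)
}

#' Write simulated read pairs to FASTQ
#'
#' Standard 4-line records with constant quality; use a `.gz` suffix for
#' gzipped output. The barcode is inside R2, not in the header.
#'
#' @param sim A [sim_reads()] object (or a tibble with `read_id`, `r1`,
#'   `r2`).
#' @param r1_path,r2_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(sim, r1_path, r2_path) {
  reads <- if (inherits(sim, "sim_reads")) sim$reads else sim
  .write_fastq(reads$read_id, reads$r1, r1_path)
  .write_fastq(reads$read_id, reads$r2, r2_path)
  invisible(c(r1_path, r2_path))
}

.write_fastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  out <- character(4 * length(ids))
  out[seq(1, length(out), by = 4)] <- paste0("@", ids)
  out[seq(2, length(out), by = 4)] <- seqs
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- qual
  readr::write_lines(out, path)
  invisible(path)
}

#' Read a FASTQ pair into a reads tibble
#'
#' @param r1_path,r2_path FASTQ paths (optionally gzipped).
#' @return Tibble with `read_id`, `r1`, `r2`.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  p1 <- .read_fastq(r1_path)
  p2 <- .read_fastq(r2_path)
  if (nrow(p1) != nrow(p2) || !all(p1$read_id == p2$read_id)) {
    abort("R1/R2 FASTQ records do not match.", class = "dropmeth_io_error")
  }
  tibble::tibble(read_id = p1$read_id, r1 = p1$seq, r2 = p2$seq)
}

.read_fastq <- function(path) {
  x <- readr::read_lines(path)
  if (length(x) %% 4 != 0) {
    abort("malformed FASTQ (record count not a multiple of 4).",
          class = "dropmeth_io_error")
  }
  ids <- sub("^@", "", x[seq(1, length(x), by = 4)])
  ids <- sub("\\s.*$", "", ids)
  tibble::tibble(read_id = ids, seq = x[seq(2, length(x), by = 4)])
}

#' Simulate per-type pseudobulk allc tables directly from methylomes
#'
#' Count-level shortcut past read simulation and alignment: for every
#' cytosine of the genome, coverage is drawn Poisson(`mean_cov`) and
#' methylated counts binomially from the type's site probability (adjusted
#' for incomplete bisulfite conversion, which makes a fraction
#' `1 - conversion_rate` of unmethylated cytosines read as methylated).
#' Useful for exercising count-level operations (pseudobulk merging, DMR
#' z-score annotation) across many seeds at low cost.
#'
#' @param methylomes A [sim_methylomes()] object.
#' @param genome The matching [sim_genome()].
#' @param mean_cov Mean per-site coverage per type.
#' @param conversion_rate Bisulfite conversion rate (default 0.99).
#' @param types Types to simulate (default all).
#' @param seed Integer seed.
#' @return An allc tibble with one `barcode` per type.
#' @export
sim_type_allc <- function(methylomes, genome, mean_cov = 5,
                          conversion_rate = 0.99, types = NULL,
                          seed = NULL) {
  stopifnot(inherits(methylomes, "sim_methylomes"),
            inherits(genome, "sim_genome"))
  if (is.null(types)) types <- methylomes$types$type
  contigs <- genome$contigs
  .with_seed(seed, {
    purrr::map(types, function(ty) {
      purrr::map(seq_len(nrow(contigs)), function(ci) {
        si <- methylomes$sites[[ci]]
        p <- methylomes$probs[[ty]][[ci]]
        tabs <- purrr::map2(
          list(si$pos_top, si$pos_bot), list("+", "-"),
          function(pos, strand) {
            cg <- if (strand == "+") si$cg_top else si$cg_bot
            cov <- rpois(length(pos), mean_cov)
            keep <- cov > 0
            pp <- p[pos[keep] + 1L]
            p_app <- pp + (1 - pp) * (1 - conversion_rate)
            tibble::tibble(
              barcode = ty, chrom = contigs$contig[ci],
              pos = pos[keep] + 1L, strand = strand,
              context = ifelse(cg[keep], "CGN", "CHN"),
              class = ifelse(cg[keep], "CG", "CH"),
              mc = rbinom(sum(keep), cov[keep], p_app),
              cov = cov[keep])
          })
        purrr::list_rbind(tabs)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind() |>
      dplyr::arrange(.data$barcode, .data$chrom, .data$pos, .data$strand)
  })
}

#' Simulate a pseudobulk allc pair with planted DMRs
#'
#' Generates two pseudobulk CpG count tables over one synthetic contig:
#' shared per-site baseline rates with binomial sampling at `coverage`, and a
#' set of planted DMR intervals where group B's rate is shifted by `-delta`.
#' Used to exercise the DMR caller against known truth (including the null,
#' `n_dmrs = 0`).
#'
#' @param n_cpgs Number of CpG sites.
#' @param spacing Mean spacing between CpGs in bp (truncated-geometric,
#'   capped at four times the mean, reflecting CpG clustering).
#' @param coverage Per-site coverage in both groups.
#' @param base_rate Mean baseline methylation rate.
#' @param n_dmrs Number of planted DMRs.
#' @param dmr_cpgs CpGs per planted DMR.
#' @param delta Methylation drop in group B inside DMRs.
#' @param seed Integer seed.
#' @return List with `a` and `b` (allc-like tibbles, CpG class only) and
#'   `dmrs` (truth intervals, 0-based half-open).
#' @export
sim_pseudobulk_pair <- function(n_cpgs = 5000, spacing = 100, coverage = 30,
                                base_rate = 0.7, n_dmrs = 0, dmr_cpgs = 20,
                                delta = 0.4, seed = NULL) {
  .with_seed(seed, {
    pos0 <- cumsum(pmin(1L + stats::rgeom(n_cpgs, 1 / spacing),
                        4L * as.integer(spacing)))
    p <- rbeta(n_cpgs, base_rate * 10, (1 - base_rate) * 10)
    pb <- p
    dmrs <- tibble::tibble(chrom = character(), start = integer(),
                           end = integer())
    if (n_dmrs > 0) {
      starts <- sort(sample.int(n_cpgs - dmr_cpgs,
                                n_dmrs * 3))  # candidate left edges
      keep <- starts[c(TRUE, diff(starts) > 2 * dmr_cpgs)][seq_len(n_dmrs)]
      for (s in keep) {
        idx <- s:(s + dmr_cpgs - 1)
        pb[idx] <- pmax(p[idx] - delta, 0)
        dmrs <- dplyr::bind_rows(dmrs, tibble::tibble(
          chrom = "chrS1", start = pos0[idx[1]],
          end = pos0[idx[dmr_cpgs]] + 2L))
      }
    }
    mk <- function(rates) tibble::tibble(
      barcode = "pseudobulk", chrom = "chrS1", pos = pos0 + 1L,
      strand = "+", context = "CGA", class = "CG",
      mc = rbinom(n_cpgs, coverage, rates),
      cov = as.integer(coverage))
    list(a = mk(p), b = mk(pb), dmrs = dmrs)
  })
}
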