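#' Simulate cell-type methylomes with planted DMRs
#'
#' Builds one methylome per cell type over a simulated genome. CpG-context
#' cytosines get per-site methylation probabilities with (i) a type-specific
#' global target, (ii) smooth regional variation on `region_block`-sized
#' blocks (methylation-domain structure, the between-type signal that binned
#' clustering picks up), and (iii) beta-distributed site-level noise. CH
#' cytosines get low beta-distributed probabilities around the CH target.
#' Each type additionally receives a private set of hypomethylated regions
#' (planted DMRs, probability reduced by `dmr_depth` and floored at 0 in that
#' type only); DMR intervals are disjoint across types. The spike-in contig
#' is fully unmethylated in every type. After planting, CG and CH
#' probabilities are rescaled so the realized genome-wide mean matches the
#' target to within 0.01.
#'
#' Default targets are three epithelial/lymphoblast-like types with global
#' mCG/CG of 50.5%, 68.2% and 63.0% and ~1% mCH/CH.
#'
#' @param genome A [sim_genome()] object.
#' @param type_specs Tibble with columns `type`, `target_mCG`, `target_mCH`
#'   and optionally `species` (defaults to `"A"`).
#' @param n_dmrs Planted DMRs per type.
#' @param dmr_length DMR length in bp.
#' @param dmr_depth Methylation-probability drop inside a type's own DMRs.
#' @param region_sd SD of the per-block regional effect on the logit scale.
#' @param region_block Regional block size in bp.
#' @param site_concentration Beta concentration of site-level CG noise.
#' @param seed Integer seed.
#' @return A `sim_methylomes` object with `$types`, `$probs` (per type, per
#'   contig, a full-length probability vector indexed by forward position),
#'   `$dmrs` (tibble `type`, `chrom`, `start`, `end`, `depth`; 0-based
#'   half-open) and `$sites` (cytosine index per contig).
#' @examples
#' g <- sim_genome(n_contigs = 2, contig_length = 2e4, seed = 1)
#' m <- sim_methylomes(g, n_dmrs = 2, dmr_length = 1000, seed = 1)
#' methylome_mean(m)
#' @export
sim_methylomes <- function(genome,
                           type_specs = default_type_specs(),
                           n_dmrs = 8, dmr_length = 5000, dmr_depth = 0.4,
                           region_sd = 0.7, region_block = 20000,
                           site_concentration = 5, seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  type_specs <- tibble::as_tibble(type_specs)
  if (!all(c("type", "target_mCG", "target_mCH") %in% names(type_specs))) {
    abort("`type_specs` needs columns type, target_mCG, target_mCH.")
  }
  if (!"species" %in% names(type_specs)) type_specs$species <- "A"
  for (v in c(type_specs$target_mCG, type_specs$target_mCH)) {
    .check_fraction(v, "target", strict = TRUE)
  }
  n_dmrs <- .check_count(n_dmrs, "n_dmrs")
  .check_number(dmr_length, "dmr_length", lower = 0)
  .check_fraction(dmr_depth, "dmr_depth")
  .check_number(region_sd, "region_sd", lower = 0)

  contigs <- genome$contigs
  sites <- lapply(genome$seq, .site_index)

  .with_seed(seed, {
    dmrs <- .plant_dmr_intervals(contigs, type_specs$type, n_dmrs, dmr_length)
    if (nrow(dmrs) > 0) dmrs$depth <- dmr_depth
    probs <- lapply(seq_len(nrow(type_specs)), function(ti) {
      tg_cg <- type_specs$target_mCG[ti]
      tg_ch <- type_specs$target_mCH[ti]
      per_contig <- lapply(seq_len(nrow(contigs)), function(ci) {
        L <- contigs$length[ci]
        p <- numeric(L)
        if (contigs$is_spike[ci]) return(p)
        si <- sites[[ci]]
        # regional logit effect shared by both strands within a block
        n_blocks <- L %/% as.integer(region_block) + 1L
        eff <- rnorm(n_blocks, 0, region_sd)
        for (strand in c("top", "bot")) {
          pos <- si[[paste0("pos_", strand)]]
          cg <- si[[paste0("cg_", strand)]]
          n_cg <- sum(cg); n_ch <- sum(!cg)
          blocks <- pos %/% as.integer(region_block)
          m_cg <- stats::plogis(stats::qlogis(tg_cg) + eff[blocks[cg] + 1L])
          k <- site_concentration
          p[pos[cg] + 1L] <- rbeta(n_cg, m_cg * k, (1 - m_cg) * k)
          kch <- 20
          p[pos[!cg] + 1L] <- rbeta(n_ch, tg_ch * kch, (1 - tg_ch) * kch)
        }
        p
      })
      names(per_contig) <- contigs$contig
      per_contig
    })
    names(probs) <- type_specs$type

    # hypomethylate each type's own planted DMRs (CpG sites only)
    for (r in seq_len(nrow(dmrs))) {
      ti <- dmrs$type[r]; ci <- dmrs$chrom[r]
      si <- sites[[ci]]
      for (strand in c("top", "bot")) {
        pos <- si[[paste0("pos_", strand)]]
        cg <- si[[paste0("cg_", strand)]]
        hit <- pos[cg]
        hit <- hit[hit >= dmrs$start[r] & hit < dmrs$end[r]]
        probs[[ti]][[ci]][hit + 1L] <-
          pmax(probs[[ti]][[ci]][hit + 1L] - dmrs$depth[r], 0)
      }
    }

    obj <- structure(
      list(types = type_specs, probs = probs, dmrs = dmrs, sites = sites,
           contigs = contigs,
           params = list(n_dmrs = n_dmrs, dmr_length = dmr_length,
                         dmr_depth = dmr_depth, region_sd = region_sd,
                         region_block = region_block,
                         site_concentration = site_concentration),
           seed = seed),
      class = "sim_methylomes")
    .renormalize_methylomes(obj)
  })
}

#' Default cell-type specification for three-type simulations
#'
#' @return Tibble of three types with global mCG targets 50.5%, 68.2% and
#'   63.0% and cell-line-like (~1%) mCH.
#' @export
default_type_specs <- function() {
  tibble::tibble(type = c("typeA", "typeB", "typeC"),
                 target_mCG = c(0.505, 0.682, 0.630),
                 target_mCH = c(0.010, 0.011, 0.009),
                 species = "A")
}

# non-overlapping DMR intervals, disjoint across types, on non-spike contigs
.plant_dmr_intervals <- function(contigs, types, n_dmrs, dmr_length) {
  n_total <- n_dmrs * length(types)
  if (n_total == 0) {
    return(tibble::tibble(type = character(), chrom = character(),
                          start = integer(), end = integer(),
                          depth = numeric()))
  }
  gap <- max(1000, dmr_length)
  stride <- dmr_length + gap
  slots <- dplyr::bind_rows(lapply(which(!contigs$is_spike), function(ci) {
    L <- contigs$length[ci]
    starts <- seq(gap, L - dmr_length - gap, by = stride)
    tibble::tibble(chrom = contigs$contig[ci], start = as.integer(starts))
  }))
  if (nrow(slots) < n_total) {
    abort(sprintf("genome too small for %d DMRs of %d bp", n_total,
                  dmr_length), class = "dropmeth_invalid_parameter")
  }
  pick <- slots[sample.int(nrow(slots), n_total), ]
  pick$type <- rep(types, each = n_dmrs)
  pick$end <- pick$start + as.integer(dmr_length)
  pick$depth <- NA_real_
  dplyr::arrange(pick[, c("type", "chrom", "start", "end", "depth")],
                 .data$chrom, .data$start)
}

# scale per-class probabilities so realized means hit the targets
.renormalize_methylomes <- function(obj) {
  for (ti in seq_len(nrow(obj$types))) {
    for (cls in c("CG", "CH")) {
      target <- if (cls == "CG") obj$types$target_mCG[ti] else
        obj$types$target_mCH[ti]
      for (iter in 1:4) {
        tot <- 0; n <- 0
        for (ci in seq_len(nrow(obj$contigs))) {
          if (obj$contigs$is_spike[ci]) next
          idx <- .class_site_positions(obj$sites[[ci]], cls)
          tot <- tot + sum(obj$probs[[ti]][[ci]][idx + 1L])
          n <- n + length(idx)
        }
        m <- tot / n
        if (abs(m - target) < 1e-4) break
        for (ci in seq_len(nrow(obj$contigs))) {
          if (obj$contigs$is_spike[ci]) next
          idx <- .class_site_positions(obj$sites[[ci]], cls)
          obj$probs[[ti]][[ci]][idx + 1L] <-
            pmin(obj$probs[[ti]][[ci]][idx + 1L] * (target / m), 1)
        }
      }
    }
  }
  obj
}

.class_site_positions <- function(si, cls) {
  keep <- if (cls == "CG") {
    c(si$pos_top[si$cg_top], si$pos_bot[si$cg_bot])
  } else {
    c(si$pos_top[!si$cg_top], si$pos_bot[!si$cg_bot])
  }
  keep
}

#' Realized mean methylation probability of simulated methylomes
#'
#' @param methylomes A [sim_methylomes()] object.
#' @param class `"CG"` or `"CH"`.
#' @param exclude_spike Drop the spike-in contig (default `TRUE`).
#' @return Tibble with one row per type (`type`, `class`, `mean_prob`,
#'   `n_sites`).
#' @export
methylome_mean <- function(methylomes, class = c("CG", "CH"),
                           exclude_spike = TRUE) {
  class <- match.arg(class)
  contigs <- methylomes$contigs
  purrr::imap(methylomes$probs, function(per_contig, tname) {
    tot <- 0; n <- 0
    for (ci in seq_len(nrow(contigs))) {
      if (exclude_spike && contigs$is_spike[ci]) next
      idx <- .class_site_positions(methylomes$sites[[ci]], class)
      tot <- tot + sum(per_contig[[ci]][idx + 1L])
      n <- n + length(idx)
    }
    tibble::tibble(type = tname, class = class, mean_prob = tot / n,
                   n_sites = n)
  }) |> purrr::list_rbind()
}

#' @export
print.sim_methylomes <- function(x, ...) {
  cat(sprintf("<sim_methylomes> %d types, %d planted DMRs\n",
              nrow(x$types), nrow(x$dmrs)))
  print(x$types)
  invisible(x)
}

#' Write planted DMR sets to BED
#'
#' BED4 with the owning type in the name column; 0-based half-open.
#'
#' @param methylomes A [sim_methylomes()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(methylomes, path) {
  d <- methylomes$dmrs
  readr::write_tsv(d[, c("chrom", "start", "end", "type")], path,
                   col_names = FALSE)
  invisible(path)
}
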