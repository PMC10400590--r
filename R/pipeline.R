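#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end run with their defaults: the
#' droplet design, the simulation scale, the standard clip/barcode layout,
#' the 2.5X candidate multiplier, 100 kb bins, top-50 PCs and the 0.90
#' species-purity threshold. Unknown arguments are rejected.
#'
#' @param ... Overrides for any default (see the returned list for names).
#' @return A named list of parameters, class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    design = droplet_design(),
    type_specs = default_type_specs(),
    n_cells_by_type = c(typeA = 15, typeB = 15, typeC = 15),
    forced_doublets = 0,
    n_contigs = 4, contig_length = 5e5, gc_fraction = 0.42, n_species = 1,
    spike_length = 48000,
    n_dmrs = 8, dmr_length = 5000, dmr_depth = 0.4,
    region_sd = 0.7, region_block = 20000,
    layout = read_layout(),
    reads_per_cell = 2000, depth_cv = 0.2,
    frag_mean = 300, frag_sd = 80, min_frag = 150,
    conversion_rate = 0.99, seq_error = 0.001, duplication_rate = 0.1,
    spike_fraction = 0.02, contam_rate = 0, noise_reads_mean = 40,
    whitelist_multiplier = 2.5,
    k = 24, max_edit = 3,
    bin_width = 1e5, class = "CG",
    min_sites_per_bin = 20, min_cell_fraction = 0.5,
    n_pcs = 50, knn_k = 15, resolution = 1,
    mix_k_range = 2:4,
    purity_threshold = 0.90,
    z_max = -1,
    dmr_min_cov = 5, dmr_fdr = 0.05, dmr_min_delta = 0.1,
    dmr_merge_dist = 500, dmr_min_cpgs = 3,
    call_dmrs = TRUE,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
          class = "dropmeth_invalid_parameter")
  }
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a JSON file
#'
#' Scalar keys of [pipeline_config()] can be overridden from a structured
#' key-value file.
#'
#' @param path JSON file of overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  over <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, over)
}

.stage <- function(run_env, name, verbose, fn) {
  out_dir <- run_env$out_dir
  cache <- if (!is.null(out_dir)) {
    file.path(out_dir, sprintf("stage_%s.rds", name))
  }
  if (!is.null(cache) && run_env$resume && file.exists(cache)) {
    if (verbose) message(sprintf("[%s] resumed from %s", name, cache))
    return(readRDS(cache))
  }
  if (verbose) message(sprintf("[%s] running ...", name))
  t0 <- proc.time()[["elapsed"]]
  val <- tryCatch(fn(), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "dropmeth_stage_error", parent = e)
  })
  if (verbose) {
    message(sprintf("[%s] done (%.1f s)", name,
                    proc.time()[["elapsed"]] - t0))
  }
  if (!is.null(cache)) saveRDS(val, cache)
  val
}

#' Run the full simulate-to-DMR pipeline
#'
#' Executes, in order: genome and methylome simulation, droplet experiment
#' realization, read simulation, demultiplexing, bisulfite alignment,
#' deduplication and methylation calling, mixture-model cell calling, binned
#' clustering with DMR-set annotation, and (optionally) pseudobulk DMR
#' calling between the two largest clusters. Fixed seed gives identical
#' results. With `out_dir`, stages cache their result on disk and a rerun
#' with `resume = TRUE` skips completed stages; plain-text artifacts
#' (whitelist, QC tables, allc files, labels, z-scores, DMR table, report
#' JSON) are also written there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param resume Reuse cached stage results from `out_dir` (default `TRUE`).
#' @param verbose Log stage progress (default `TRUE`).
#' @return A `dropmeth_run` object: all stage results plus `$report`, a
#'   per-stage QC summary (read conservation, mapping-efficiency
#'   distribution, conversion rate, cells called, cluster sizes, labels,
#'   DMR count) echoing every parameter.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         resume = TRUE, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  env <- new.env()
  env$out_dir <- out_dir
  env$resume <- resume
  seed <- config$seed

  genome <- .stage(env, "genome", verbose, function() {
    sim_genome(config$n_contigs, config$contig_length, config$gc_fraction,
               config$n_species, config$spike_length,
               seed = .child_seed(seed, 1))
  })
  methylomes <- .stage(env, "methylomes", verbose, function() {
    sim_methylomes(genome, config$type_specs, config$n_dmrs,
                   config$dmr_length, config$dmr_depth, config$region_sd,
                   config$region_block, seed = .child_seed(seed, 2))
  })
  experiment <- .stage(env, "experiment", verbose, function() {
    ts <- stats::setNames(config$type_specs$species, config$type_specs$type)
    sim_experiment(config$design, config$n_cells_by_type,
                   type_species = ts,
                   forced_doublets = config$forced_doublets,
                   seed = .child_seed(seed, 3))
  })
  reads <- .stage(env, "reads", verbose, function() {
    sim_reads(experiment, methylomes, genome, config$layout,
              config$reads_per_cell, config$depth_cv, config$frag_mean,
              config$frag_sd, config$min_frag, config$conversion_rate,
              config$seq_error, config$duplication_rate,
              config$spike_fraction, config$contam_rate,
              config$noise_reads_mean, seed = .child_seed(seed, 4))
  })
  demux <- .stage(env, "demux", verbose, function() {
    counts <- barcode_counts(reads$reads, config$layout)
    expected <- max(1L, round(sum(config$n_cells_by_type)))
    wl <- build_whitelist(counts, expected, config$whitelist_multiplier)
    demultiplex(reads$reads, wl, config$layout)
  })
  alignments <- .stage(env, "align", verbose, function() {
    idx <- bs_index(genome, config$k)
    align_mates(demux, idx, config$max_edit)
  })
  meth <- .stage(env, "call", verbose, function() {
    uniq <- dedup_alignments(alignments)
    allc <- call_methylation(uniq, genome)
    summary <- cell_summary(alignments, allc, genome)
    list(allc = allc, summary = summary)
  })
  cellcall <- .stage(env, "cellcall", verbose, function() {
    counts <- barcode_counts(reads$reads, config$layout)
    expected <- max(1L, round(sum(config$n_cells_by_type)))
    cand <- select_candidates(counts, expected, config$whitelist_multiplier)
    cand <- dplyr::inner_join(cand, meth$summary, by = "barcode")
    fit <- fit_efficiency_mixture(cand$efficiency, config$mix_k_range)
    calls <- call_cells(cand, fit)
    list(fit = fit, calls = calls)
  })
  clust <- .stage(env, "cluster", verbose, function() {
    cells <- cellcall$calls$barcode[cellcall$calls$call == "cell"]
    allc_cells <- meth$allc[meth$allc$barcode %in% cells, ]
    mat <- build_meth_matrix(allc_cells, genome, config$bin_width,
                             config$class, config$min_sites_per_bin,
                             config$min_cell_fraction) |>
      normalize_meth_matrix()
    cl <- cluster_cells(mat, config$n_pcs, config$knn_k, config$resolution,
                        seed = .child_seed(seed, 5))
    ann <- tryCatch(
      annotate_clusters(cl, allc_cells, methylomes$dmrs,
                        z_max = config$z_max),
      error = function(e) NULL)
    list(matrix = mat, clusters = cl, annotation = ann)
  })
  dmr <- NULL
  if (isTRUE(config$call_dmrs)) {
    dmr <- .stage(env, "dmr", verbose, function() {
      sizes <- sort(table(clust$clusters$membership$cluster),
                    decreasing = TRUE)
      if (length(sizes) < 2) return(NULL)
      top2 <- as.integer(names(sizes)[1:2])
      memb <- clust$clusters$membership
      bc_a <- memb$barcode[memb$cluster == top2[1]]
      bc_b <- memb$barcode[memb$cluster == top2[2]]
      pa <- merge_pseudobulk(meth$allc[meth$allc$barcode %in% bc_a, ],
                             sprintf("cluster%d", top2[1]))
      pb <- merge_pseudobulk(meth$allc[meth$allc$barcode %in% bc_b, ],
                             sprintf("cluster%d", top2[2]))
      call_dmrs(pa, pb, config$dmr_min_cov, config$dmr_fdr,
                config$dmr_min_delta, config$dmr_merge_dist,
                config$dmr_min_cpgs)
    })
  }

  report <- .run_report(config, reads, demux, alignments, meth, cellcall,
                        clust, dmr)
  run <- structure(
    list(config = config, genome = genome, methylomes = methylomes,
         experiment = experiment, reads = reads, demux = demux,
         alignments = alignments, allc = meth$allc,
         summary = meth$summary, cellcall = cellcall,
         matrix = clust$matrix, clusters = clust$clusters,
         annotation = clust$annotation, dmrs = dmr, report = report),
    class = "dropmeth_run")
  if (!is.null(out_dir)) .write_run_artifacts(run, out_dir)
  run
}

.run_report <- function(config, reads, demux, alignments, meth, cellcall,
                        clust, dmr) {
  eff <- meth$summary$efficiency
  conv <- conversion_rate(meth$allc, min_calls = 1000)
  memb <- clust$clusters$membership
  list(
    parameters = lapply(unclass(config), function(x) {
      if (is.data.frame(x)) as.list(x) else if (is.list(x)) unclass(x) else x
    }),
    reads = list(simulated_pairs = nrow(reads$reads),
                 assigned = demux$qc$assigned,
                 unassigned = demux$qc$unassigned,
                 short = demux$qc$short,
                 conserved = demux$qc$assigned + demux$qc$unassigned +
                   demux$qc$short == demux$qc$total),
    alignment = list(mates_aligned = sum(alignments$status == "unique"),
                     mates_total = nrow(alignments),
                     efficiency_quartiles = unname(quantile(eff,
                                                            c(.25, .5, .75)))),
    methylation = list(conversion_rate = conv,
                       barcodes_with_calls = length(unique(meth$allc$barcode))),
    cells = list(candidates = nrow(cellcall$calls),
                 called_cells = sum(cellcall$calls$call == "cell"),
                 cutoff = cellcall$fit$cutoff),
    clustering = list(n_clusters = length(unique(memb$cluster)),
                      sizes = as.list(table(memb$cluster)),
                      labels = if (!is.null(clust$annotation)) {
                        as.list(stats::setNames(
                          clust$annotation$labels$label,
                          clust$annotation$labels$cluster))
                      }),
    dmr = list(n_regions = if (is.null(dmr)) NA_integer_ else nrow(dmr)))
}

.write_run_artifacts <- function(run, out_dir) {
  readr::write_tsv(run$summary, file.path(out_dir, "cell_summary.tsv"))
  readr::write_tsv(run$cellcall$calls, file.path(out_dir, "cell_calls.tsv"))
  readr::write_tsv(run$clusters$membership,
                   file.path(out_dir, "cluster_labels.tsv"))
  if (!is.null(run$annotation)) {
    readr::write_tsv(tidy(run$annotation),
                     file.path(out_dir, "cluster_zscores.tsv"))
  }
  if (!is.null(run$dmrs)) {
    write_dmr_table(run$dmrs, file.path(out_dir, "dmrs.tsv"))
  }
  write_allc(run$allc, file.path(out_dir, "allc"))
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.dropmeth_run <- function(x, ...) {
  r <- x$report
  cat("<dropmeth_run>\n")
  cat(sprintf("  read pairs: %d (assigned %d, unassigned %d, short %d)\n",
              r$reads$simulated_pairs, r$reads$assigned, r$reads$unassigned,
              r$reads$short))
  cat(sprintf("  cells called: %d of %d candidates (cutoff %.3f)\n",
              r$cells$called_cells, r$cells$candidates, r$cells$cutoff))
  cat(sprintf("  conversion rate: %.4f\n", r$methylation$conversion_rate))
  cat(sprintf("  clusters: %d; DMRs: %s\n", r$clustering$n_clusters,
              r$dmr$n_regions))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `dropmeth_run` object.
#' @param ... Unused.
#' @export
glance.dropmeth_run <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    read_pairs = r$reads$simulated_pairs,
    assigned = r$reads$assigned,
    called_cells = r$cells$called_cells,
    conversion_rate = r$methylation$conversion_rate,
    n_clusters = r$clustering$n_clusters,
    n_dmrs = r$dmr$n_regions)
}
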