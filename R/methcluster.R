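#' Genome-tiling bins
#'
#' Fixed-width bins over the non-spike contigs, 0-based half-open.
#'
#' @param contigs A [sim_genome()] object or its `$contigs` tibble.
#' @param bin_width Bin width in bp (100 kb for deep data, 1 Mb for shallow).
#' @return Tibble (`bin_id`, `chrom`, `start`, `end`).
#' @export
make_bins <- function(contigs, bin_width = 1e5) {
  if (inherits(contigs, "sim_genome")) contigs <- contigs$contigs
  contigs <- contigs[!contigs$is_spike, ]
  bins <- purrr::pmap(contigs[, c("contig", "length")],
                      function(contig, length) {
    starts <- seq(0L, length - 1L, by = bin_width)
    tibble::tibble(chrom = contig, start = as.integer(starts),
                   end = as.integer(pmin(starts + bin_width, length)))
  }) |> purrr::list_rbind()
  bins$bin_id <- sprintf("%s:%d-%d", bins$chrom, bins$start, bins$end)
  bins[, c("bin_id", "chrom", "start", "end")]
}

#' Build the cells-by-bins methylation feature matrix
#'
#' Per cell and genomic bin, the pooled methylation rate sum(mc)/sum(cov)
#' over the bin's sites of the chosen context class. A cell's bin is missing
#' (NA, never silently zero) when fewer than `min_sites_per_bin` of its
#' covered sites fall in the bin; bins observed in fewer than
#' `min_cell_fraction` of cells are dropped. The spike-in contig is always
#' excluded. Each cell's global level of the same class is attached for
#' normalization.
#'
#' @param allc An allc tibble (multiple barcodes).
#' @param contigs A [sim_genome()] or contigs tibble (for bin construction).
#' @param bin_width Bin width in bp.
#' @param class `"CG"` or `"CH"`.
#' @param min_sites_per_bin Minimum covered sites for a non-missing entry.
#' @param min_cell_fraction Minimum fraction of cells with data to retain a
#'   bin.
#' @param spike_contig Spike-in contig name.
#' @return A `meth_matrix` object: `$values` (cells x bins, NA = missing),
#'   `$bins`, `$cells`, `$global` tibble, `$class`, `$normalized`.
#' @export
build_meth_matrix <- function(allc, contigs, bin_width = 1e5,
                              class = c("CG", "CH"), min_sites_per_bin = 20,
                              min_cell_fraction = 0.5,
                              spike_contig = "spike") {
  class <- match.arg(class)
  cls <- class
  bins <- make_bins(contigs, bin_width)
  x <- allc[allc$class == cls & allc$chrom != spike_contig, ]
  if (length(unique(x$barcode)) < 2) {
    abort("need at least two cells to build a feature matrix.",
          class = "dropmeth_invalid_parameter")
  }
  dt <- data.table::data.table(
    barcode = x$barcode, chrom = x$chrom,
    bin = (x$pos - 1L) %/% as.integer(bin_width),
    mc = x$mc, cov = x$cov)
  agg <- dt[, list(mc = sum(mc), cov = sum(cov), n_sites = .N),
            by = list(barcode, chrom, bin)]
  agg[, rate := mc / cov]
  agg[n_sites < min_sites_per_bin, rate := NA_real_]
  # bin ids resolved against the authoritative bin table (contig tails)
  key <- paste0(agg$chrom, ":", agg$bin * as.integer(bin_width))
  bin_key <- paste0(bins$chrom, ":", bins$start)
  agg$bin_id <- bins$bin_id[match(key, bin_key)]

  cells <- sort(unique(agg$barcode))
  mat <- matrix(NA_real_, nrow = length(cells), ncol = nrow(bins),
                dimnames = list(cells, bins$bin_id))
  mat[cbind(match(agg$barcode, cells), match(agg$bin_id, bins$bin_id))] <-
    agg$rate

  keep <- colMeans(!is.na(mat)) >= min_cell_fraction
  if (!any(keep)) {
    abort(sprintf(
      "no bin is observed in >= %.0f%% of cells (min_sites_per_bin = %d)",
      100 * min_cell_fraction, min_sites_per_bin),
      class = "dropmeth_degenerate")
  }
  mat <- mat[, keep, drop = FALSE]

  glob <- global_levels(allc, cls, spike_contig)
  structure(
    list(values = mat, bins = bins[keep, ], cells = cells,
         global = glob, class = cls, bin_width = bin_width,
         normalized = FALSE),
    class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix> %d cells x %d bins (%s%s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$class,
              if (x$normalized) ", normalized" else "",
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Normalize a methylation feature matrix by per-cell global level
#'
#' Divides each cell's row by that cell's global mCG/CG (or mCH/CH), which
#' removes global-level differences so clustering reflects the distribution
#' of methylation across the genome; missing entries are then imputed with
#' the neutral normalized value 1. Cells with a zero global level are
#' dropped with a warning.
#'
#' @param m A [build_meth_matrix()] object.
#' @return The normalized `meth_matrix`.
#' @export
normalize_meth_matrix <- function(m) {
  stopifnot(inherits(m, "meth_matrix"))
  if (m$normalized) return(m)
  g <- stats::setNames(m$global$level, m$global$barcode)[rownames(m$values)]
  bad <- is.na(g) | g == 0
  if (any(bad)) {
    warn(sprintf("%d cell(s) dropped: zero/undefined global %s level",
                 sum(bad), m$class))
    m$values <- m$values[!bad, , drop = FALSE]
    m$cells <- rownames(m$values)
    g <- g[!bad]
  }
  m$values <- m$values / g
  m$values[is.na(m$values)] <- 1
  m$normalized <- TRUE
  m
}

#' Cluster cells by reduced binned methylation
#'
#' Column-centered PCA of the normalized matrix to the top `n_pcs`
#' components, a symmetric k-nearest-neighbour graph in PC space, and
#' Louvain community detection. Deterministic for a fixed seed. The 2-D PC
#' coordinates are kept for plotting.
#'
#' @param m A normalized [build_meth_matrix()] object.
#' @param n_pcs Number of principal components (lowered with a warning when
#'   cells or bins are fewer; default 50).
#' @param knn_k Neighbours per cell (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param min_modularity Partitions whose Louvain modularity falls below
#'   this value are treated as structureless and collapsed to a single
#'   cluster (default 0.3, the conventional benchmark for meaningful
#'   community structure; kNN graphs of homogeneous data typically score
#'   0.1-0.15).
#' @param seed Integer seed.
#' @return A `meth_clusters` object: `$membership` tibble (`barcode`,
#'   `cluster`), `$pcs` score matrix, `$n_pcs`, plus the parameters.
#' @export
cluster_cells <- function(m, n_pcs = 50, knn_k = 15, resolution = 1,
                          min_modularity = 0.3, seed = NULL) {
  stopifnot(inherits(m, "meth_matrix"))
  if (!m$normalized) {
    warn("matrix is not normalized; clustering raw rates")
  }
  X <- m$values
  n <- nrow(X)
  if (n < 3) abort("need at least 3 cells to cluster.")
  max_pcs <- min(n - 1L, ncol(X))
  if (n_pcs > max_pcs) {
    warn(sprintf("n_pcs lowered from %d to %d (matrix is %d x %d)",
                 n_pcs, max_pcs, n, ncol(X)))
    n_pcs <- max_pcs
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  S <- pc$x
  if (all(abs(S) < 1e-12)) {
    abort("degenerate feature matrix (rank 0).",
          class = "dropmeth_degenerate")
  }
  k <- min(knn_k, n - 1L)
  D <- as.matrix(dist(S))
  diag(D) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    cbind(i, nb)
  }))
  edges <- unique(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- .with_seed(seed %||% 0L, {
    igraph::cluster_louvain(g, resolution = resolution)
  })
  memb <- igraph::membership(comm)
  if (igraph::modularity(comm) < min_modularity) {
    memb[] <- 1L  # no meaningful community structure: one cluster
  }
  structure(
    list(membership = tibble::tibble(barcode = rownames(X),
                                     cluster = as.integer(memb)),
         pcs = S, n_pcs = n_pcs, knn_k = k, resolution = resolution,
         seed = seed),
    class = "meth_clusters")
}

#' @export
print.meth_clusters <- function(x, ...) {
  cat(sprintf("<meth_clusters> %d cells in %d clusters\n",
              nrow(x$membership), length(unique(x$membership$cluster))))
  print(dplyr::count(x$membership, .data$cluster))
  invisible(x)
}

#' @rdname cluster_cells
#' @param x,object A `meth_clusters` object.
#' @param ... Unused.
#' @export
tidy.meth_clusters <- function(x, ...) x$membership

#' @rdname cluster_cells
#' @export
autoplot.meth_clusters <- function(object, ...) {
  df <- tibble::tibble(PC1 = object$pcs[, 1],
                       PC2 = object$pcs[, min(2, ncol(object$pcs))],
                       cluster = factor(object$membership$cluster))
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = "cells in PC space, Louvain clusters")
}

#' Annotate clusters by DMR-set methylation z-scores
#'
#' Pools the CpG methylation of each cluster's cells over every reference
#' DMR set, z-scales the rates across clusters within each set (sample SD),
#' and labels each cluster with the set of minimum z-score — type-specific
#' DMRs are hypomethylated in their own type — provided that minimum is
#' below `z_max`; otherwise the cluster is left unlabelled.
#'
#' With `normalize = TRUE` (the default) each cluster's DMR-set rates are
#' first divided by that cluster's pooled global mCG/CG, the same
#' global-level normalization applied to the clustering matrix. This removes
#' the global-methylation differences between clusters so the z-scores
#' reflect targeted hypomethylation rather than global shifts.
#'
#' @param clusters A [cluster_cells()] object (or a membership tibble with
#'   `barcode`, `cluster`).
#' @param allc The allc tibble of the clustered cells.
#' @param dmr_sets Tibble (`chrom`, `start`, `end`, `set`) of reference DMR
#'   intervals, 0-based half-open (e.g. the planted sets from
#'   [write_dmr_bed()], or [sim_methylomes()]`$dmrs` with `type` renamed to
#'   `set`).
#' @param z_max Labelling threshold on the minimum z (default -1).
#' @param normalize Divide each cluster's DMR-set rates by its global
#'   mCG/CG before z-scoring (default `TRUE`).
#' @param spike_contig Spike-in contig excluded from the global level.
#' @return A `cluster_annotation` object: `$rates` (raw pooled rates) and
#'   `$z` (clusters x sets), `$labels` tibble (`cluster`, `label`,
#'   `min_z`), `$sets`.
#' @export
annotate_clusters <- function(clusters, allc, dmr_sets, z_max = -1,
                              normalize = TRUE, spike_contig = "spike") {
  memb <- if (inherits(clusters, "meth_clusters")) clusters$membership else
    tibble::as_tibble(clusters)
  dmr_sets <- tibble::as_tibble(dmr_sets)
  if ("type" %in% names(dmr_sets) && !"set" %in% names(dmr_sets)) {
    dmr_sets <- dplyr::rename(dmr_sets, set = "type")
  }
  if (nrow(dmr_sets) == 0) abort("empty DMR set table.")
  kl <- sort(unique(memb$cluster))
  if (length(kl) < 2) {
    abort("need >= 2 clusters for z-scoring.",
          class = "dropmeth_invalid_parameter")
  }
  sets <- sort(unique(dmr_sets$set))
  x <- allc[allc$class == "CG", ]
  x <- dplyr::inner_join(x, memb, by = "barcode")

  rates <- matrix(NA_real_, length(kl), length(sets),
                  dimnames = list(as.character(kl), sets))
  for (s in sets) {
    iv <- dmr_sets[dmr_sets$set == s, ]
    hit <- rep(FALSE, nrow(x))
    for (r in seq_len(nrow(iv))) {
      hit <- hit | (x$chrom == iv$chrom[r] & x$pos - 1L >= iv$start[r] &
                      x$pos - 1L < iv$end[r])
    }
    xs <- x[hit, ]
    if (nrow(xs) == 0) next
    agg <- xs |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(rate = sum(.data$mc) / sum(.data$cov),
                       .groups = "drop")
    rates[as.character(agg$cluster), s] <- agg$rate
  }
  scored <- rates
  if (normalize) {
    glob <- x[x$chrom != spike_contig, ] |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(g = sum(.data$mc) / sum(.data$cov), .groups = "drop")
    gv <- stats::setNames(glob$g, as.character(glob$cluster))[rownames(rates)]
    scored <- rates / gv
  }
  z <- scale(scored)  # per-set mean 0, sample-sd 1 across clusters
  labels <- tibble::tibble(
    cluster = kl,
    label = vapply(seq_along(kl), function(i) {
      zi <- z[i, ]
      if (all(is.na(zi))) return(NA_character_)
      j <- which.min(zi)
      if (zi[j] < z_max) sets[j] else NA_character_
    }, character(1)),
    min_z = vapply(seq_along(kl), function(i) {
      zi <- z[i, ]
      if (all(is.na(zi))) NA_real_ else min(zi, na.rm = TRUE)
    }, numeric(1)))
  structure(list(rates = rates, z = z, labels = labels, sets = sets,
                 z_max = z_max),
            class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat("<cluster_annotation>\n")
  print(x$labels)
  invisible(x)
}

#' @rdname annotate_clusters
#' @param x,object A `cluster_annotation` object.
#' @param ... Unused.
#' @export
tidy.cluster_annotation <- function(x, ...) {
  as.data.frame.table(x$z, responseName = "z") |>
    tibble::as_tibble() |>
    dplyr::rename(cluster = "Var1", set = "Var2") |>
    dplyr::mutate(cluster = as.integer(as.character(.data$cluster)),
                  set = as.character(.data$set))
}

#' @rdname annotate_clusters
#' @export
autoplot.cluster_annotation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set,
                                   y = factor(.data$cluster),
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "DMR set", y = "cluster",
                  title = "CpG methylation z-scores over DMR sets")
}
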