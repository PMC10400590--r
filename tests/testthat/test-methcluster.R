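test_that("bin values are pooled rates and missing entries stay missing", {
  allc <- tibble::tibble(
    barcode = rep(c("c1", "c2"), each = 3),
    chrom = "chrA1",
    pos = c(10L, 20L, 150030L, 10L, 20L, 30L),
    strand = "+", context = "CGA", class = "CG",
    mc = c(1L, 1L, 5L, 0L, 0L, 0L),
    cov = c(1L, 1L, 5L, 1L, 1L, 1L))
  contigs <- tibble::tibble(contig = c("chrA1", "spike"),
                            length = c(2e5, 1e4),
                            species = c("A", "spike"),
                            is_spike = c(FALSE, TRUE))
  m <- build_meth_matrix(allc, contigs, bin_width = 1e5,
                         min_sites_per_bin = 2, min_cell_fraction = 0.5)
  # first bin: c1 rate 1.0 (2/2), c2 rate 0.0
  expect_equal(unname(m$values[c("c1", "c2"), 1]), c(1, 0))
  # second bin: c1 has only 1 site (< min) -> missing, not zero
  if (ncol(m$values) > 1) expect_true(is.na(m$values["c1", 2]))
})

test_that("pseudobulk bins equal coverage-weighted means of cell bins", {
  allc <- fx_allc_clean()
  cells <- unique(allc$barcode)[1:3]
  sub <- allc[allc$barcode %in% cells, ]
  g <- fx_genome()
  m <- build_meth_matrix(sub, g, bin_width = 5e4, min_sites_per_bin = 1,
                         min_cell_fraction = 1)
  merged <- merge_pseudobulk(sub, "bulk")
  mb <- build_meth_matrix(
    dplyr::bind_rows(merged, merged |> dplyr::mutate(barcode = "bulk2")),
    g, bin_width = 5e4, min_sites_per_bin = 1, min_cell_fraction = 1)
  # per bin: pooled pseudobulk rate == coverage-weighted mean of cells
  dt <- sub[sub$class == "CG" & sub$chrom != "spike", ]
  for (b in colnames(mb$values)) {
    parts <- strsplit(b, "[:-]")[[1]]
    sel <- dt$chrom == parts[1] & dt$pos - 1 >= as.integer(parts[2]) &
      dt$pos - 1 < as.integer(parts[3])
    expect_equal(unname(mb$values["bulk", b]),
                 sum(dt$mc[sel]) / sum(dt$cov[sel]), tolerance = 1e-12)
  }
})

test_that("normalization is per-cell scale-invariant with neutral imputation", {
  vals <- matrix(c(0.4, 0.8, NA, 0.2, 0.4, 0.6), nrow = 2, byrow = TRUE,
                 dimnames = list(c("c1", "c2"), c("b1", "b2", "b3")))
  m <- structure(list(values = vals, bins = NULL, cells = rownames(vals),
                      global = tibble::tibble(barcode = c("c1", "c2"),
                                              level = c(0.4, 0.4)),
                      class = "CG", normalized = FALSE),
                 class = "meth_matrix")
  n1 <- normalize_meth_matrix(m)
  expect_equal(unname(n1$values["c1", ]), c(1, 2, 1))  # NA -> neutral 1
  # doubling a cell's bins and its global leaves the row unchanged
  m2 <- m
  m2$values["c1", ] <- m$values["c1", ] * 2
  m2$global$level[1] <- 0.8
  n2 <- normalize_meth_matrix(m2)
  expect_equal(n2$values["c1", ], n1$values["c1", ])
  # a cell whose bins all equal its global becomes all ones
  expect_equal(unname(n2$values["c2", ]), c(0.5, 1, 1.5))
  m3 <- m
  m3$global$level[2] <- 0
  expect_warning(n3 <- normalize_meth_matrix(m3), "dropped")
  expect_false("c2" %in% rownames(n3$values))
})

test_that("global-shift-only types collapse together after normalization", {
  g <- sim_genome(n_contigs = 2, contig_length = 5e4, spike_length = 5000,
                  seed = 31)
  specs <- tibble::tibble(type = c("hi", "lo"),
                          target_mCG = c(0.7, 0.45),
                          target_mCH = c(0.01, 0.01))
  m <- sim_methylomes(g, specs, n_dmrs = 0, region_sd = 0,
                      site_concentration = 50, seed = 32)
  allc <- sim_type_allc(m, g, mean_cov = 20, conversion_rate = 1, seed = 33)
  mat <- build_meth_matrix(allc, g, bin_width = 1e4, min_sites_per_bin = 5,
                           min_cell_fraction = 1)
  raw_gap <- mean(mat$values["hi", ] - mat$values["lo", ])
  norm <- normalize_meth_matrix(mat)
  norm_gap <- mean(norm$values["hi", ] - norm$values["lo", ])
  expect_gt(abs(raw_gap), 10 * abs(norm_gap))
})

test_that("clustering separates planted structure and ignores duplication", {
  set.seed(34)
  centers <- matrix(rnorm(3 * 30), 3, 30)
  X <- centers[rep(1:3, each = 20), ] + matrix(rnorm(60 * 30, 0, 0.3),
                                               60, 30)
  rownames(X) <- sprintf("cell%02d", 1:60)
  m <- structure(list(values = X, cells = rownames(X), class = "CG",
                      global = NULL, normalized = TRUE),
                 class = "meth_matrix")
  cl <- cluster_cells(m, n_pcs = 10, knn_k = 10, seed = 35)
  expect_gt(ari(cl$membership$cluster, rep(1:3, each = 20)), 0.99)

  # duplicating every cell preserves co-membership
  X2 <- rbind(X, X)
  rownames(X2) <- c(rownames(X), paste0(rownames(X), "_dup"))
  m2 <- m; m2$values <- X2; m2$cells <- rownames(X2)
  cl2 <- cluster_cells(m2, n_pcs = 10, knn_k = 10, seed = 35)
  lab <- setNames(cl2$membership$cluster, cl2$membership$barcode)
  co1 <- outer(lab[rownames(X)], lab[rownames(X)], "==")
  co2 <- outer(lab[paste0(rownames(X), "_dup")],
               lab[paste0(rownames(X), "_dup")], "==")
  expect_true(all(co1 == co2))

  # a homogeneous population lands in one cluster for most seeds
  Xh <- matrix(rnorm(40 * 20), 40, 20,
               dimnames = list(sprintf("c%02d", 1:40), NULL))
  mh <- m; mh$values <- Xh; mh$cells <- rownames(Xh)
  ks <- vapply(1:10, function(s) {
    length(unique(cluster_cells(mh, n_pcs = 10, seed = s)$membership$cluster))
  }, numeric(1))
  expect_gte(sum(ks == 1), 6)

  # determinism under a fixed seed
  cl3 <- cluster_cells(m, n_pcs = 10, knn_k = 10, seed = 35)
  expect_identical(cl$membership, cl3$membership)
})

test_that("z-scores are column-standardized and label hypomethylation", {
  memb <- tibble::tibble(barcode = c("x", "y"), cluster = c(1L, 2L))
  allc <- tibble::tibble(
    barcode = rep(c("x", "y"), each = 10),
    chrom = "chrA1", pos = rep(seq(101L, 1001L, by = 100L), 2),
    strand = "+", context = "CGA", class = "CG",
    mc = c(rep(2L, 10), rep(8L, 10)), cov = 10L)
  sets <- tibble::tibble(chrom = "chrA1", start = 0L, end = 2000L,
                         set = "s1")
  ann <- annotate_clusters(memb, allc, sets, normalize = FALSE)
  expect_equal(unname(ann$z[, "s1"]), c(-sqrt(2) / 2, sqrt(2) / 2),
               tolerance = 1e-9)
  expect_equal(mean(ann$z[, "s1"]), 0, tolerance = 1e-12)
  expect_equal(sd(ann$z[, "s1"]), 1, tolerance = 1e-12)
  expect_identical(ann$labels$label[1], NA_character_)  # -0.707 > -1
})

test_that("annotation labels clusters with their true planted type", {
  g <- sim_genome(n_contigs = 2, contig_length = 1e5, spike_length = 5000,
                  seed = 36)
  m <- sim_methylomes(g, n_dmrs = 4, dmr_length = 4000, seed = 37)
  hits <- 0
  for (s in 1:5) {
    allc <- sim_type_allc(m, g, mean_cov = 2, seed = 400 + s)
    memb <- tibble::tibble(barcode = m$types$type, cluster = 1:3)
    ann <- annotate_clusters(memb, allc, m$dmrs)
    lab <- ann$labels$label[match(1:3, ann$labels$cluster)]
    if (identical(lab, m$types$type)) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # permuting cluster ids permutes labels coherently
  allc <- sim_type_allc(m, g, mean_cov = 2, seed = 444)
  memb <- tibble::tibble(barcode = m$types$type, cluster = 1:3)
  ann1 <- annotate_clusters(memb, allc, m$dmrs)
  memb2 <- tibble::tibble(barcode = m$types$type, cluster = c(2L, 3L, 1L))
  ann2 <- annotate_clusters(memb2, allc, m$dmrs)
  for (i in 1:3) {
    expect_identical(
      ann1$labels$label[ann1$labels$cluster == memb$cluster[i]],
      ann2$labels$label[ann2$labels$cluster == memb2$cluster[i]])
  }
})
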