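test_that("pseudobulk merge sums counts exactly and detects corruption", {
  one <- tibble::tibble(barcode = "c1", chrom = "chr1", pos = 10L,
                        strand = "+", context = "CGA", class = "CG",
                        mc = 1L, cov = 2L)
  expect_equal(merge_pseudobulk(one, "m")[, c("mc", "cov")],
               one[, c("mc", "cov")])
  two <- dplyr::bind_rows(one, one |> dplyr::mutate(barcode = "c2",
                                                    mc = 0L, cov = 3L))
  m <- merge_pseudobulk(two, "m")
  expect_equal(m$mc, 1L)
  expect_equal(m$cov, 5L)
  bad <- dplyr::bind_rows(one, one |> dplyr::mutate(barcode = "c2",
                                                    context = "CAA",
                                                    class = "CH"))
  expect_error(merge_pseudobulk(bad), class = "dropmeth_corrupt_input")
})

test_that("identical groups produce no DMRs", {
  pair <- sim_pseudobulk_pair(n_cpgs = 2000, n_dmrs = 0, seed = 41)
  out <- call_dmrs(pair$a, pair$a)
  expect_equal(nrow(out), 0)
})

test_that("planted DMRs are recovered with high interval overlap", {
  pair <- sim_pseudobulk_pair(n_cpgs = 5000, coverage = 30, n_dmrs = 4,
                              dmr_cpgs = 20, delta = 0.4, seed = 42)
  out <- call_dmrs(pair$a, pair$b)
  expect_gt(nrow(out), 0)
  # every planted DMR matched by a called region with Jaccard >= 0.8
  jac <- vapply(seq_len(nrow(pair$dmrs)), function(i) {
    d <- pair$dmrs[i, ]
    ov <- pmin(out$end, d$end) - pmax(out$start, d$start)
    un <- pmax(out$end, d$end) - pmin(out$start, d$start)
    max(ifelse(ov > 0, ov / un, 0))
  }, numeric(1))
  expect_true(all(jac >= 0.8))
  # differences are signed a - b and regions are coordinate-sorted
  expect_true(all(out$diff > 0))
  expect_true(all(diff(out$start) > 0 | out$chrom[-1] != head(out$chrom, -1)))
  expect_true(all(out$n_sig >= 3))

  # swapping the groups negates every difference, same region set
  rev <- call_dmrs(pair$b, pair$a)
  expect_equal(rev[, c("chrom", "start", "end", "n_cpgs")],
               out[, c("chrom", "start", "end", "n_cpgs")])
  expect_equal(rev$diff, -out$diff)

  # called regions are non-overlapping
  if (nrow(out) > 1) expect_true(all(out$start[-1] >= head(out$end, -1)))
})

test_that("null simulations rarely produce false regions", {
  false_counts <- vapply(1:10, function(s) {
    pair <- sim_pseudobulk_pair(n_cpgs = 10000, coverage = 30, n_dmrs = 0,
                                seed = 500 + s)
    nrow(call_dmrs(pair$a, pair$b))
  }, numeric(1))
  expect_gte(sum(false_counts <= 1), 9)
})

test_that("gene annotation follows promoter > body > nearest-TSS priority", {
  genes <- tibble::tibble(
    chrom = "chr1",
    start = c(10000L, 50000L, 52000L),
    end = c(20000L, 60000L, 62000L),
    name = c("alpha", "beta", "gamma"),
    strand = c("+", "+", "-"))
  regions <- tibble::tibble(
    chrom = "chr1",
    start = c(9000L, 15000L, 29998L, 70000L),
    end = c(9500L, 15500L, 30003L, 70500L),
    n_cpgs = 3L, mean_a = 0.5, mean_b = 0.1, diff = 0.4, q = 0.01,
    gene = NA_character_)
  ann <- annotate_genes(regions, genes)
  expect_identical(ann$gene[1], "alpha")  # promoter window of alpha TSS
  expect_identical(ann$gene[2], "alpha")  # body overlap
  # equidistant between alpha TSS (10000) and beta TSS (50000):
  # lexicographically first name wins
  expect_identical(ann$gene[3], "alpha")
  expect_identical(ann$gene[4], "gamma")  # nearest TSS is gamma (61999)
})

test_that("DMRs planted in gene bodies annotate to the owning gene", {
  pair <- sim_pseudobulk_pair(n_cpgs = 3000, coverage = 30, n_dmrs = 3,
                              dmr_cpgs = 20, delta = 0.4, seed = 43)
  out <- call_dmrs(pair$a, pair$b)
  genes <- pair$dmrs |>
    dplyr::mutate(start = pmax(.data$start - 3000L, 0L),
                  end = .data$end + 3000L,
                  name = sprintf("gene%d", dplyr::row_number()),
                  strand = "+") |>
    dplyr::select("chrom", "start", "end", "name", "strand")
  ann <- annotate_genes(out, genes)
  # each called region that matches a planted DMR names that DMR's gene
  for (i in seq_len(nrow(pair$dmrs))) {
    d <- pair$dmrs[i, ]
    hit <- which(ann$start < d$end & ann$end > d$start)
    expect_true(all(ann$gene[hit] == genes$name[i]))
  }
})
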