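test_that("deduplication keeps one representative per fragment locus", {
  aln <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"),
    barcode = c("b1", "b1", "b2", "b1"),
    contig = "c", start = 10L, end = 90L, mode = "OT",
    nm = c(2L, 0L, 1L, 0L), status = "unique", seq = "A")
  u <- dedup_alignments(aln)
  # same locus, same barcode collapses; other barcode survives
  expect_equal(nrow(u), 2)
  expect_identical(sort(u$barcode), c("b1", "b2"))
  # lowest edit distance then read id wins
  expect_identical(u$read_id[u$barcode == "b1"], "r2")
})

test_that("dedup recovers the simulated unique fraction", {
  sr <- fx_reads_noisy()  # duplication_rate = 0.3
  wl <- build_whitelist(barcode_counts(sr$reads),
                        sum(fx_experiment()$barcodes$class == "cell"))
  dx <- demultiplex(sr$reads, wl)
  aln <- align_mates(dx, fx_index())
  cell_aln <- aln[aln$status == "unique" &
                    aln$barcode %in% fx_experiment()$cells$barcode, ]
  u <- dedup_alignments(cell_aln)
  frac <- nrow(u) / nrow(cell_aln)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.3 * 0.7 / nrow(cell_aln)) + 0.02)
})

test_that("compiled methylation caller agrees with a pure-R oracle", {
  g <- fx_genome()
  aln <- dedup_alignments(fx_aln_clean())
  set.seed(13)
  pick <- aln[sample(nrow(aln), 60), ]
  allc <- call_methylation(pick, g)
  # independent recomputation, read by read
  expected <- purrr::pmap(
    list(pick$seq, pick$contig, pick$start, pick$mode, pick$barcode),
    function(seq, contig, start, mode, barcode) {
      out <- r_oracle_call(seq, g$seq[[contig]], start, mode)
      if (nrow(out)) {
        out$chrom <- contig
        out$barcode <- barcode
      }
      out
    }) |>
    purrr::list_rbind() |>
    dplyr::group_by(.data$barcode, .data$chrom, .data$pos, .data$strand,
                    .data$class) |>
    dplyr::summarise(mc = sum(.data$meth), cov = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$barcode, .data$chrom, .data$pos, .data$strand)
  got <- allc |>
    dplyr::select("barcode", "chrom", "pos", "strand", "class", "mc",
                  "cov") |>
    dplyr::arrange(.data$barcode, .data$chrom, .data$pos, .data$strand)
  expect_equal(as.data.frame(got), as.data.frame(expected))
  # count conservation: coverage equals the oracle's observation count
  expect_equal(sum(got$cov), sum(expected$cov))
})

test_that("called states equal simulated states under perfect conversion", {
  # conversion = 1, seq_error = 0: the pooled per-type allc methylation must
  # reproduce the truth-sidecar counts exactly in aggregate
  sr <- fx_reads_clean()
  allc <- fx_allc_clean()
  tr <- sr$truth
  ex <- fx_experiment()
  # restrict to singlet barcodes whose every mate aligned uniquely
  aln <- fx_aln_clean()
  aln_ok <- aln |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(all_unique = all(.data$status == "unique"))
  full <- tr$read_id[!tr$is_dup & !tr$is_noise &
                       tr$read_id %in%
                         aln_ok$read_id[aln_ok$all_unique]]
  # CG sites sit on both mates; compare pooled rates, not raw counts
  t2 <- tr[tr$read_id %in% full & tr$contig != "spike", ]
  truth_rate <- sum(t2$cg_meth) / sum(t2$cg_total)
  x <- allc[allc$class == "CG" & allc$chrom != "spike" &
              allc$barcode %in% unique(t2$barcode), ]
  called_rate <- sum(x$mc) / sum(x$cov)
  expect_equal(called_rate, truth_rate, tolerance = 0.02)
  expect_true(all(x$mc <= x$cov))
  expect_true(all(x$cov >= 1))
})

test_that("conversion-rate estimator and global levels compute pooled rates", {
  allc <- tibble::tibble(
    barcode = "b", chrom = c("spike", "spike", "chr1"),
    pos = c(10L, 20L, 30L), strand = "+",
    context = c("CAA", "CGA", "CGA"), class = c("CH", "CG", "CG"),
    mc = c(10L, 0L, 5L), cov = c(600L, 400L, 10L))
  expect_equal(conversion_rate(allc, min_calls = 1000), 0.99)
  expect_equal(conversion_rate(allc |> dplyr::mutate(mc = 0L),
                               min_calls = 1000), 1.0)
  expect_warning(v <- conversion_rate(allc[1, ], min_calls = 1000),
                 "withheld")
  expect_true(is.na(v))
  gl <- global_levels(allc, "CG")
  expect_equal(gl$level, 0.5)  # spike excluded
  allm <- allc |> dplyr::mutate(mc = cov)
  expect_equal(global_levels(allm, "CG")$level, 1.0)
})

test_that("simulated conversion rate is recovered from the spike-in", {
  allc <- fx_allc_clean()  # conversion_rate = 1
  expect_equal(conversion_rate(allc), 1.0, tolerance = 1e-6)
})

test_that("merging allc tables preserves coverage-weighted global levels", {
  allc <- fx_allc_clean()
  merged <- merge_pseudobulk(allc, "all")
  gl_m <- global_levels(merged, "CG")
  gl_c <- global_levels(allc, "CG")
  expect_equal(gl_m$level,
               sum(gl_c$level * gl_c$coverage) / sum(gl_c$coverage),
               tolerance = 1e-12)
  expect_equal(sum(merged$cov), sum(allc$cov))
})

test_that("saturation curve has the exact coupon-collector shape", {
  aln <- tibble::tibble(
    barcode = "b",
    contig = "c",
    start = rep(c(1L, 2L, 3L, 4L), c(4, 2, 1, 1)),
    end = rep(c(10L, 20L, 30L, 40L), c(4, 2, 1, 1)),
    mode = "OT", status = "unique")
  sat <- saturation_curve(aln, c(0L, 2L, 8L))
  expect_equal(sat$expected_unique[1], 0)
  expect_equal(sat$expected_unique[3], 4)  # full depth finds all fragments
  expect_true(all(diff(sat$expected_unique) >= 0))
  # Monte-Carlo oracle at depth 2
  set.seed(14)
  ids <- rep(1:4, c(4, 2, 1, 1))
  mc <- mean(replicate(20000, length(unique(sample(ids, 2)))))
  expect_equal(sat$expected_unique[2], mc, tolerance = 0.02)
  expect_warning(saturation_curve(aln, c(5L, 100L)), "truncated")
})

test_that("saturation approaches library complexity at high assigned depth", {
  sr <- fx_reads_noisy()
  wl <- build_whitelist(barcode_counts(sr$reads),
                        sum(fx_experiment()$barcodes$class == "cell"))
  dx <- demultiplex(sr$reads, wl)
  aln <- align_mates(dx, fx_index())
  bc <- names(sort(table(aln$barcode[aln$status == "unique"]),
                   decreasing = TRUE))[1]
  one <- aln[aln$barcode == bc & aln$status == "unique", ]
  complexity <- nrow(dedup_alignments(one))
  sat <- suppressWarnings(
    saturation_curve(one, as.integer(c(10, nrow(one), 10 * complexity))))
  expect_gt(sat$expected_unique[3], 0.95 * complexity)
  expect_true(all(diff(sat$expected_unique) >= -1e-9))
})

test_that("allc files round-trip through the allc format", {
  allc <- fx_allc_clean()
  small <- allc[allc$barcode %in% unique(allc$barcode)[1:2], ]
  d <- tempfile()
  paths <- write_allc(small, d)
  expect_true(all(file.exists(file.path(
    d, sprintf("allc_%s.tsv", unique(small$barcode))))))
  back <- read_allc(sort(list.files(d, full.names = TRUE)))
  expect_equal(as.data.frame(back |> dplyr::arrange(barcode, chrom, pos,
                                                    strand)),
               as.data.frame(small |> dplyr::arrange(barcode, chrom, pos,
                                                     strand)))
})
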