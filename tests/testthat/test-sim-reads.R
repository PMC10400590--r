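test_that("read architecture and truth bookkeeping are consistent", {
  sr <- fx_reads_clean()
  lay <- sr$layout
  expect_equal(nrow(sr$reads), nrow(sr$truth))
  expect_true(all(nchar(sr$reads$r2) >= lay$r2_clip))
  # the true barcode sits at R2 bases 25-39 for every read
  expect_identical(substr(sr$reads$r2, 25, 39), sr$truth$barcode)
  # fragment intervals stay inside their contigs
  tr <- sr$truth[!sr$truth$is_noise, ]
  g <- fx_genome()
  len <- setNames(g$contigs$length, g$contigs$contig)
  expect_true(all(tr$start >= 0 & tr$end <= len[tr$contig]))
  expect_true(all(tr$end - tr$start >= 150))
})

test_that("perfect conversion turns every unmethylated cytosine into T", {
  sr <- fx_reads_clean()  # conversion_rate = 1, seq_error = 0
  lay <- sr$layout
  spike <- !is.na(sr$truth$contig) & sr$truth$contig == "spike"
  expect_gt(sum(spike), 20)
  r2_gen <- substr(sr$reads$r2[spike], lay$r2_clip + 1, lay$read_length)
  # spike-in is fully unmethylated: the template read carries no C at all
  expect_false(any(grepl("C", r2_gen, fixed = TRUE)))
  # and the complementary-strand mate carries no G
  r1_gen <- substr(sr$reads$r1[spike], lay$r1_clip + 1, lay$read_length)
  expect_false(any(grepl("G", r1_gen, fixed = TRUE)))
})

test_that("spike-in C survival matches 1 - conversion_rate", {
  ex <- fx_experiment()
  sr <- sim_reads(ex, fx_methylomes(), fx_genome(), reads_per_cell = 300,
                  conversion_rate = 0.99, seq_error = 0,
                  duplication_rate = 0, spike_fraction = 0.2, seed = 301)
  lay <- sr$layout
  spike <- which(!is.na(sr$truth$contig) & sr$truth$contig == "spike")
  r2_gen <- substr(sr$reads$r2[spike], lay$r2_clip + 1, lay$read_length)
  # reconstruct each read's template window from the genome: the number of
  # template cytosines is known exactly, surviving Cs are binomial
  g <- fx_genome()
  tr <- sr$truth[spike, ]
  tmpl <- vapply(seq_along(spike), function(i) {
    s <- substr(g$seq[["spike"]], tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") {
      s <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                        collapse = ""))
    }
    substr(s, 1, lay$r2_genomic)
  }, character(1))
  n_sites <- sum(stringr::str_count(tmpl, "C"))
  n_c <- sum(stringr::str_count(r2_gen, "C"))
  expect_gt(n_sites, 1e4)
  p_surv <- n_c / n_sites
  expect_lt(abs(p_surv - 0.01), 3 * sqrt(0.01 * 0.99 / n_sites))
})

test_that("duplication model yields the expected unique fraction", {
  sr0 <- fx_reads_clean()
  tr0 <- sr0$truth[!sr0$truth$is_noise, ]
  expect_false(any(duplicated(tr0[, c("barcode", "contig", "start", "end",
                                      "strand")])))

  sr <- sim_reads(fx_experiment(), fx_methylomes(), fx_genome(),
                  reads_per_cell = 500, duplication_rate = 0.3,
                  spike_fraction = 0, noise_reads_mean = 0, seed = 302)
  tr <- sr$truth[!sr$truth$is_noise, ]
  n <- nrow(tr)
  uniq_frac <- 1 - mean(tr$is_dup)
  expect_lt(abs(uniq_frac - 0.7), 3 * sqrt(0.3 * 0.7 / n))
  # duplicates repeat an existing fragment of the same barcode exactly
  dup <- tr[tr$is_dup, ]
  orig <- tr[!tr$is_dup, ]
  key <- function(x) paste(x$barcode, x$contig, x$start, x$end, x$strand)
  expect_true(all(key(dup) %in% key(orig)))
})

test_that("per-fragment truth counts match the methylome in expectation", {
  sr <- fx_reads_clean()
  tr <- sr$truth[!sr$truth$is_noise & sr$truth$contig != "spike", ]
  m <- fx_methylomes()
  for (ty in unique(tr$type)) {
    x <- tr[tr$type == ty, ]
    rate <- sum(x$cg_meth) / sum(x$cg_total)
    target <- m$types$target_mCG[match(ty, m$types$type)]
    expect_lt(abs(rate - target), 3 * sqrt(0.25 / sum(x$cg_total)) + 0.03)
  }
})

test_that("FASTQ round-trip preserves reads; record mismatch errors", {
  sr <- fx_reads_clean()
  r1 <- tempfile(fileext = ".fastq.gz"); r2 <- tempfile(fileext = ".fastq.gz")
  write_fastq_pair(sr, r1, r2)
  back <- read_fastq_pair(r1, r2)
  expect_identical(back$r1, sr$reads$r1)
  expect_identical(back$r2, sr$reads$r2)
  r2b <- tempfile(fileext = ".fastq")
  write_fastq_pair(sr$reads[1:10, ], tempfile(fileext = ".fastq"), r2b)
  expect_error(read_fastq_pair(r1, r2b), class = "dropmeth_io_error")
})
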