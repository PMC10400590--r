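test_that("candidate selection takes the top multiplier-X barcodes", {
  counts <- tibble::tibble(barcode = sprintf("BC%04d", 1:4000),
                           n = 4000:1)
  cand <- select_candidates(counts, 1000)
  expect_equal(nrow(cand), 2500)
  expect_true(all(cand$n >= 1501))
  expect_warning(all4 <- select_candidates(counts[1:4, ], 2), "4")
  expect_equal(nrow(all4), 4)
})

test_that("a tight single cluster selects k = 1 with cutoff mean minus sd", {
  set.seed(21)
  x <- rnorm(500, 0.65, 0.01)
  fit <- fit_efficiency_mixture(x, k_range = 1:3)
  expect_equal(fit$k, 1)
  expect_equal(fit$cutoff, mean(x) - sd(x), tolerance = 1e-6)
  expect_equal(fit$cutoff, 0.64, tolerance = 0.005)
  # cutoff is definitionally mu - sigma of the selected component
  sel <- fit$components[fit$components$selected, ]
  expect_equal(fit$cutoff, sel$mu - sel$sigma)
})

test_that("EM recovers the generating two-component parameters", {
  set.seed(22)
  n <- 2000
  z <- runif(n) < 0.5
  x <- ifelse(z, rnorm(n, 0.65, 0.05), rnorm(n, 0.15, 0.08))
  fit <- fit_efficiency_mixture(x, k_range = 2:4)
  sel <- fit$components[fit$components$selected, ]
  expect_equal(sel$mu, 0.65, tolerance = 0.02)
  expect_equal(sel$sigma, 0.05, tolerance = 0.015)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-9)
  expect_true(all(fit$components$sigma > 0))
  expect_lt(fit$cutoff, sel$mu)

  # independent mixture fitter agrees on the top component
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  ref <- mclust::Mclust(x, G = fit$k, modelNames = "V", verbose = FALSE)
  expect_equal(sel$mu, max(ref$parameters$mean), tolerance = 0.01)
})

test_that("cell calling splits candidates at the cutoff, equality passing", {
  set.seed(23)
  cand <- tibble::tibble(barcode = sprintf("B%04d", 1:400),
                         efficiency = c(rnorm(200, 0.65, 0.05),
                                        rnorm(200, 0.15, 0.08)))
  fit <- fit_efficiency_mixture(cand$efficiency)
  calls <- call_cells(cand, fit)
  expect_setequal(calls$call, c("cell", "noise"))
  expect_equal(nrow(calls), 400)
  at_cut <- tibble::tibble(barcode = "X", efficiency = fit$cutoff)
  expect_identical(call_cells(at_cut, fit)$call, "cell")
  below <- tibble::tibble(barcode = "Y", efficiency = fit$cutoff - 1e-9)
  expect_identical(suppressWarnings(call_cells(below, fit)$call), "noise")
  # cells and noise partition the candidates
  expect_equal(sum(calls$call == "cell") + sum(calls$call == "noise"), 400)
})

test_that("species purity applies the strict >90% rule", {
  counts <- tibble::tibble(
    barcode = rep(c("b1", "b2", "b3"), each = 2),
    species = rep(c("A", "B"), 3),
    n = c(95L, 5L, 90L, 10L, 0L, 50L))
  sp <- species_purity(counts)
  calls <- setNames(sp$calls$call, sp$calls$barcode)
  expect_identical(unname(calls["b1"]), "pure_A")
  expect_identical(unname(calls["b2"]), "mixed")  # 0.90 is not > 0.90
  expect_identical(unname(calls["b3"]), "pure_B")

  # raising the threshold never increases the pure count
  set.seed(24)
  big <- tibble::tibble(
    barcode = rep(sprintf("c%03d", 1:200), each = 2),
    species = rep(c("A", "B"), 200),
    n = as.integer(rbinom(400, 100, rep(runif(200, 0.3, 1), each = 2) *
                            c(1, 0) + rep(c(0, 1), 200) *
                            rep(runif(200, 0, 0.7), each = 2))))
  pures <- vapply(c(0.7, 0.8, 0.9, 0.95), function(th) {
    sum(startsWith(species_purity(big, th)$calls$call, "pure"))
  }, numeric(1))
  expect_true(all(diff(pures) <= 0))

  # zero-read barcodes are excluded and tallied
  z <- dplyr::bind_rows(counts,
                        tibble::tibble(barcode = "b4",
                                       species = c("A", "B"), n = 0L))
  expect_equal(species_purity(z)$n_zero, 1)
})
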