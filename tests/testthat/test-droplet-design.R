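test_that("Poisson occupancy matches the closed form and its calibration", {
  expect_equal(poisson_occupancy(0, 0), 1.0)
  lam <- calibrate_lambda(0.10)
  expect_equal(lam, -log(0.9))
  expect_equal(poisson_occupancy(lam, 1, "at_least"), 0.10, tolerance = 1e-12)
  # double occupancy under 10% non-empty loading stays below 0.5%
  p2 <- poisson_occupancy(lam, 2, "exactly")
  expect_equal(p2, exp(-lam) * lam^2 / 2, tolerance = 1e-12)
  expect_equal(round(p2, 6), 0.004995)
  expect_lt(p2, 0.005)

  # calibration is the exact inverse on (0, 1)
  for (f in c(0.01, 0.1, 1 - exp(-1), 0.9)) {
    expect_equal(poisson_occupancy(calibrate_lambda(f), 1, "at_least"), f,
                 tolerance = 1e-12)
  }
  expect_equal(calibrate_lambda(1 - exp(-1)), 1.0)
  expect_equal(round(calibrate_lambda(0.10), 6), 0.105361)

  # pmf sums to one over the support
  for (lam in c(0.01, 0.1, 1)) {
    expect_equal(sum(vapply(0:50, poisson_occupancy, numeric(1),
                            lambda = lam)), 1, tolerance = 1e-9)
  }

  expect_error(poisson_occupancy(-1, 0), class = "dropmeth_invalid_parameter")
  expect_error(poisson_occupancy(1, -1), class = "dropmeth_invalid_parameter")
  expect_error(calibrate_lambda(0), class = "dropmeth_invalid_parameter")
  expect_error(calibrate_lambda(1), class = "dropmeth_invalid_parameter")
})

test_that("droplet count, generation rate and fusion runtime arithmetic", {
  # 4 uL/min for 10 min at 35 um diameter gathers ~1.78 million droplets
  n <- droplet_count(4, 10, 35)
  expect_equal(n, 1.78e6, tolerance = 0.02)
  # cubic scaling in diameter, linear in flow
  expect_equal(droplet_count(4, 10, 70), n / 8, tolerance = 1e-12)
  expect_equal(droplet_count(5, 1, 50), 76394, tolerance = 1e-4)
  expect_equal(generation_rate(4, 35), 2970, tolerance = 0.01)
  expect_equal(generation_rate(8, 35), 2 * generation_rate(4, 35))

  expect_equal(fusion_runtime(20000, 0.07, 132), 36.1, tolerance = 0.01)
  expect_equal(fusion_runtime(132 * 60, 1, 132), 1)
  expect_equal(fusion_runtime(20000, 0.035, 132),
               2 * fusion_runtime(20000, 0.07, 132))
  expect_error(droplet_count(0, 10, 35), class = "dropmeth_invalid_parameter")
  expect_error(fusion_runtime(100, 0, 132),
               class = "dropmeth_invalid_parameter")
})

test_that("expected barcoded-cell yield is the product of capture terms", {
  expect_equal(expected_barcoded_cells(1e5, 0.5, 0.5, 0), 0)
  expect_equal(expected_barcoded_cells(285714, 0.10, 0.07, 0.8), 1600,
               tolerance = 1e-4)
})

test_that("simulated experiments realize the closed-form design statistics", {
  des <- droplet_design()
  ex <- sim_experiment(des, c(typeA = 120, typeB = 120), seed = 7)
  # realized barcoded-cell yield within 3 binomial SD of the expectation
  p_occ <- poisson_occupancy(des$cell_lambda, 1, "at_least")
  p <- des$bead_occupancy * des$fusion_efficiency * p_occ
  n <- ex$params$n_pairings
  expected <- expected_barcoded_cells(n, p_occ, des$bead_occupancy,
                                      des$fusion_efficiency)
  realized <- sum(ex$barcodes$class == "cell")
  expect_lt(abs(realized - expected), 3 * sqrt(n * p * (1 - p)) + 1)

  # occupancy of fused droplets matches the Poisson non-empty fraction
  fused <- ex$barcodes[ex$barcodes$fused, ]
  f_occ <- mean(fused$n_cells >= 1)
  expect_lt(abs(f_occ - p_occ),
            3 * sqrt(p_occ * (1 - p_occ) / nrow(fused)))
})

test_that("design summary tibble exposes the derived quantities", {
  td <- tidy(droplet_design())
  expect_true(all(c("p_double", "droplet_count", "fusion_runtime") %in%
                    td$quantity))
  v <- setNames(td$value, td$quantity)
  expect_equal(unname(v["droplet_count"]), 1.78e6, tolerance = 0.02)
  expect_equal(unname(v["fusion_runtime"]), 36.1, tolerance = 0.01)
  expect_equal(unname(v["expected_barcoded_cells"]), 1600, tolerance = 1e-6)
  g <- glance(droplet_design())
  expect_equal(nrow(g), 1)
})
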