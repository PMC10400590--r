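#' Poisson droplet-occupancy probability
#'
#' Cells loaded into droplets at limiting dilution follow Poisson statistics:
#' with a mean of `lambda` cells per droplet the probability of observing
#' exactly `n` cells in a droplet is \eqn{e^{-\lambda}\lambda^n/n!}. Designs
#' typically target ~10% occupied droplets so that double encapsulation stays
#' below 0.5%.
#'
#' @param lambda Mean number of cells per droplet (>= 0).
#' @param n Occupancy class boundary, a non-negative integer.
#' @param class `"exactly"` for \eqn{P(X = n)} or `"at_least"` for
#'   \eqn{P(X \ge n)}.
#' @return A probability in `[0, 1]`.
#' @examples
#' poisson_occupancy(calibrate_lambda(0.10), 2) # double occupancy, < 0.5%
#' @export
poisson_occupancy <- function(lambda, n, class = c("exactly", "at_least")) {
  class <- match.arg(class)
  .check_number(lambda, "lambda", lower = 0)
  n <- .check_count(n, "n")
  if (class == "exactly") {
    stats::dpois(n, lambda)
  } else {
    if (n == 0L) 1 else stats::ppois(n - 1L, lambda, lower.tail = FALSE)
  }
}

#' Calibrate the Poisson loading rate from the occupied-droplet fraction
#'
#' Inverts the at-least-one occupancy probability: if a fraction `f` of
#' droplets contain one or more cells, the loading rate is
#' \eqn{\lambda = -\ln(1 - f)}.
#'
#' @param occupied_fraction Fraction of droplets with at least one cell,
#'   strictly inside (0, 1).
#' @return The mean number of cells per droplet.
#' @examples
#' calibrate_lambda(0.10)
#' @export
calibrate_lambda <- function(occupied_fraction) {
  .check_fraction(occupied_fraction, "occupied_fraction", strict = TRUE)
  -log(1 - occupied_fraction)
}

#' Droplets generated by a flow-focusing device
#'
#' The number of droplets is the dispensed aqueous volume divided by the
#' single-droplet volume \eqn{(\pi/6) d^3}.
#'
#' @param aqueous_flow Total aqueous flow rate in microlitres per minute.
#' @param run_time Collection time in minutes.
#' @param diameter Droplet diameter in micrometres.
#' @return Expected droplet count (a positive real; round as needed).
#' @examples
#' droplet_count(4, 10, 35) # ~1.78 million droplets
#' @export
droplet_count <- function(aqueous_flow, run_time, diameter) {
  .check_number(aqueous_flow, "aqueous_flow", lower = 0, strict_lower = TRUE)
  .check_number(run_time, "run_time", lower = 0, strict_lower = TRUE)
  .check_number(diameter, "diameter", lower = 0, strict_lower = TRUE)
  # 1 uL == 1e6 pL
  aqueous_flow * run_time * 1e6 / .droplet_volume_pl(diameter)
}

#' Droplet generation rate
#'
#' @inheritParams droplet_count
#' @return Droplets per second.
#' @examples
#' generation_rate(4, 35) # ~3000 droplets per second
#' @export
generation_rate <- function(aqueous_flow, diameter) {
  droplet_count(aqueous_flow, 1, diameter) / 60
}

#' Runtime of the droplet fusion device
#'
#' Time to push `n_beads` barcode beads through a fusion device producing
#' barcode droplets at `barcode_droplet_rate` droplets per second with a bead
#' in a fraction `bead_occupancy` of them.
#'
#' @param n_beads Number of barcode beads to process.
#' @param bead_occupancy Fraction of barcode droplets containing a bead, in
#'   (0, 1].
#' @param barcode_droplet_rate Barcode droplets generated per second.
#' @return Runtime in minutes.
#' @examples
#' fusion_runtime(20000, 0.07, 132) # ~36 min
#' @export
fusion_runtime <- function(n_beads, bead_occupancy, barcode_droplet_rate) {
  .check_number(n_beads, "n_beads", lower = 0, strict_lower = TRUE)
  .check_number(bead_occupancy, "bead_occupancy", lower = 0, upper = 1,
                strict_lower = TRUE)
  .check_number(barcode_droplet_rate, "barcode_droplet_rate", lower = 0,
                strict_lower = TRUE)
  n_beads / bead_occupancy / barcode_droplet_rate / 60
}

#' Expected barcoded-cell yield
#'
#' Mean number of barcode droplets that end up fused with a cell-containing
#' droplet: the product of the number of pairing opportunities, the fraction
#' of cell droplets that are occupied, the bead occupancy of barcode droplets,
#' and the fusion efficiency. This is the mean of the realized yield of
#' [sim_experiment()].
#'
#' @param n_pairings Number of barcode-droplet pairing opportunities.
#' @param cell_occupied_fraction Fraction of cell droplets with >= 1 cell.
#' @param bead_occupancy Fraction of barcode droplets containing a bead.
#' @param fusion_efficiency Fraction of barcode droplets successfully fused.
#' @return Expected number of barcoded cells.
#' @examples
#' expected_barcoded_cells(285714, 0.10, 0.07, 0.8)
#' @export
expected_barcoded_cells <- function(n_pairings, cell_occupied_fraction,
                                    bead_occupancy, fusion_efficiency) {
  .check_number(n_pairings, "n_pairings", lower = 0)
  .check_fraction(cell_occupied_fraction, "cell_occupied_fraction")
  .check_fraction(bead_occupancy, "bead_occupancy")
  .check_fraction(fusion_efficiency, "fusion_efficiency")
  n_pairings * cell_occupied_fraction * bead_occupancy * fusion_efficiency
}

#' Droplet-experiment design
#'
#' Bundles the physical parameters of a droplet bisulfite-sequencing run.
#' Defaults reflect a standard bench configuration: 35 um droplets, 4 uL/min
#' aqueous flow, 10 min collection, 10% occupied droplets, 7% bead occupancy,
#' 80% fusion efficiency, 132 barcode droplets per second and 20,000 beads.
#'
#' @param droplet_diameter Droplet diameter (um).
#' @param aqueous_flow Aqueous flow rate (uL/min).
#' @param run_time Droplet collection time (min).
#' @param cell_lambda Mean cells per droplet; default targets 10% occupancy.
#' @param bead_occupancy Fraction of barcode droplets containing a bead.
#' @param fusion_efficiency Fraction of barcode droplets fused with a cell
#'   droplet.
#' @param barcode_droplet_rate Barcode droplets per second.
#' @param n_beads Number of barcode beads.
#' @return A `droplet_design` object (a named list).
#' @examples
#' design <- droplet_design()
#' tidy(design)
#' @export
droplet_design <- function(droplet_diameter = 35,
                           aqueous_flow = 4,
                           run_time = 10,
                           cell_lambda = calibrate_lambda(0.10),
                           bead_occupancy = 0.07,
                           fusion_efficiency = 0.8,
                           barcode_droplet_rate = 132,
                           n_beads = 20000) {
  .check_number(droplet_diameter, "droplet_diameter", lower = 0,
                strict_lower = TRUE)
  .check_number(aqueous_flow, "aqueous_flow", lower = 0)
  .check_number(run_time, "run_time", lower = 0)
  .check_number(cell_lambda, "cell_lambda", lower = 0)
  .check_fraction(bead_occupancy, "bead_occupancy")
  .check_fraction(fusion_efficiency, "fusion_efficiency")
  .check_number(barcode_droplet_rate, "barcode_droplet_rate", lower = 0)
  .check_count(n_beads, "n_beads")
  structure(
    list(droplet_diameter = droplet_diameter,
         aqueous_flow = aqueous_flow,
         run_time = run_time,
         cell_lambda = cell_lambda,
         bead_occupancy = bead_occupancy,
         fusion_efficiency = fusion_efficiency,
         barcode_droplet_rate = barcode_droplet_rate,
         n_beads = as.integer(n_beads)),
    class = "droplet_design"
  )
}

#' @export
print.droplet_design <- function(x, ...) {
  cat("<droplet_design>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Summarise a droplet design
#'
#' @param x A [droplet_design()] object.
#' @param ... Unused.
#' @return `tidy()` returns one row per derived quantity (occupancy
#'   probabilities, droplet count, generation rate, fusion runtime, expected
#'   yield) with units; `glance()` returns a one-row tibble of headline
#'   numbers.
#' @export
tidy.droplet_design <- function(x, ...) {
  lam <- x$cell_lambda
  n_drop <- droplet_count(x$aqueous_flow, x$run_time, x$droplet_diameter)
  tibble::tribble(
    ~quantity, ~value, ~unit,
    "cell_lambda", lam, "cells/droplet",
    "p_occupied", poisson_occupancy(lam, 1, "at_least"), "fraction",
    "p_single", poisson_occupancy(lam, 1, "exactly"), "fraction",
    "p_double", poisson_occupancy(lam, 2, "exactly"), "fraction",
    "droplet_count", n_drop, "droplets",
    "generation_rate",
      generation_rate(x$aqueous_flow, x$droplet_diameter), "droplets/s",
    "fusion_runtime",
      fusion_runtime(x$n_beads, x$bead_occupancy, x$barcode_droplet_rate),
      "min",
    "expected_barcoded_cells",
      # pairing opportunities = barcode droplets needed to spend all beads
      expected_barcoded_cells(x$n_beads / x$bead_occupancy,
                              poisson_occupancy(lam, 1, "at_least"),
                              x$bead_occupancy, x$fusion_efficiency),
      "cells"
  )
}

#' @rdname tidy.droplet_design
#' @export
glance.droplet_design <- function(x, ...) {
  td <- tidy(x)
  v <- stats::setNames(td$value, td$quantity)
  tibble::tibble(
    p_single = v[["p_single"]],
    p_double = v[["p_double"]],
    droplet_count = v[["droplet_count"]],
    generation_rate = v[["generation_rate"]],
    fusion_runtime = v[["fusion_runtime"]],
    expected_barcoded_cells = v[["expected_barcoded_cells"]]
  )
}
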