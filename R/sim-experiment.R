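#' Simulate a droplet barcoding experiment with ground truth
#'
#' Realizes the droplet statistics of a design: barcode droplets are generated
#' until the expected barcoded-cell yield matches the requested number of
#' cells; each barcode droplet carries a bead with probability
#' `bead_occupancy`, fuses with a cell droplet with probability
#' `fusion_efficiency`, and the fused cell droplet contains a
#' Poisson(`cell_lambda`) number of cells. Beaded barcodes fused with an empty
#' droplet become noise barcodes (they later receive unalignable background
#' reads); barcodes with two or more cells are doublets. Every bead carries a
#' unique 15-nt barcode over the three-letter alphabet A/T/G.
#'
#' @param design A [droplet_design()] object.
#' @param n_cells_by_type Named integer vector (names are cell types from
#'   [sim_methylomes()]): requested expected number of captured cells per
#'   type.
#' @param type_species Optional named character vector mapping type to
#'   species tag (defaults to `"A"`). Needed for species-mixing designs.
#' @param forced_doublets Fraction of singlet cell barcodes upgraded to a
#'   cross-species doublet by adding one cell of the other species (requires
#'   two species; default 0).
#' @param seed Integer seed.
#' @return A `sim_experiment` object with `$barcodes` (one row per beaded
#'   barcode: `barcode`, `fused`, `n_cells`, `class` in cell/noise/unfused,
#'   `is_doublet`), `$cells` (`cell_id`, `barcode`, `type`, `species`) and
#'   `$params`.
#' @examples
#' ex <- sim_experiment(droplet_design(), c(typeA = 20, typeB = 20), seed = 1)
#' table(ex$barcodes$class)
#' @export
sim_experiment <- function(design, n_cells_by_type,
                           type_species = NULL, forced_doublets = 0,
                           seed = NULL) {
  stopifnot(inherits(design, "droplet_design"))
  if (is.null(names(n_cells_by_type)) || any(n_cells_by_type <= 0)) {
    abort("`n_cells_by_type` must be a named vector of positive counts.",
          class = "dropmeth_invalid_parameter")
  }
  .check_fraction(forced_doublets, "forced_doublets")
  types <- names(n_cells_by_type)
  if (is.null(type_species)) {
    type_species <- stats::setNames(rep("A", length(types)), types)
  }

  lam <- design$cell_lambda
  p_occ <- poisson_occupancy(lam, 1, "at_least")
  p_cell_barcode <- design$bead_occupancy * design$fusion_efficiency * p_occ
  n_total <- sum(n_cells_by_type)
  n_pairings <- max(1L, round(n_total / p_cell_barcode))

  .with_seed(seed, {
    has_bead <- runif(n_pairings) < design$bead_occupancy
    n_beaded <- sum(has_bead)
    fused <- runif(n_beaded) < design$fusion_efficiency
    n_cells <- ifelse(fused, rpois(n_beaded, lam), 0L)

    # forced cross-species doublets among fused singlets; the requested
    # fraction is realized by construction (rounded count, random subset)
    if (forced_doublets > 0) {
      singl <- which(fused & n_cells == 1L)
      if (length(unique(type_species)) < 2) {
        abort("forced_doublets requires two species.",
              class = "dropmeth_invalid_parameter")
      }
      n_up <- min(length(singl),
                  max(1L, round(forced_doublets * length(singl))))
      up <- singl[sample.int(length(singl), n_up)]
      n_cells[up] <- 2L
      forced_flag <- logical(n_beaded)
      forced_flag[up] <- TRUE
    } else {
      forced_flag <- logical(n_beaded)
    }

    barcode <- .unique_barcodes(n_beaded)
    barcodes <- tibble::tibble(
      barcode = barcode, fused = fused, n_cells = as.integer(n_cells),
      class = dplyr::case_when(!fused ~ "unfused",
                               n_cells == 0L ~ "noise",
                               TRUE ~ "cell"),
      is_doublet = n_cells >= 2L,
      forced_doublet = forced_flag)

    # assign types to cells in proportion to the requested mix
    cell_rows <- rep(seq_len(n_beaded), n_cells)
    n_cell <- length(cell_rows)
    ty <- sample(types, n_cell, replace = TRUE,
                 prob = n_cells_by_type / n_total)
    # forced doublets: second cell switched to the other species
    if (any(forced_flag)) {
      for (b in which(forced_flag)) {
        idx <- which(cell_rows == b)
        sp1 <- type_species[[ty[idx[1]]]]
        other <- types[type_species[types] != sp1]
        ty[idx[2]] <- sample(other, 1)
      }
    }
    cells <- tibble::tibble(
      cell_id = sprintf("cell%05d", seq_len(n_cell)),
      barcode = barcodes$barcode[cell_rows],
      type = ty,
      species = unname(type_species[ty]))

    structure(
      list(design = design, barcodes = barcodes, cells = cells,
           params = list(n_pairings = n_pairings,
                         n_cells_by_type = n_cells_by_type,
                         type_species = type_species,
                         forced_doublets = forced_doublets,
                         p_occupied = p_occ),
           seed = seed),
      class = "sim_experiment")
  })
}

.unique_barcodes <- function(n, len = 15L) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    new <- cpp_random_strings(need, len, c("A", "T", "G"), rep(1, 3))
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "<sim_experiment> %d pairings, %d beaded barcodes (%d cell / %d noise / %d unfused), %d cells (%d doublet barcodes)\n",
    x$params$n_pairings, nrow(x$barcodes),
    sum(x$barcodes$class == "cell"), sum(x$barcodes$class == "noise"),
    sum(x$barcodes$class == "unfused"), nrow(x$cells),
    sum(x$barcodes$is_doublet)))
  invisible(x)
}
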