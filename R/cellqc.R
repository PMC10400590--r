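#' Select candidate cell barcodes by raw read count
#'
#' Keeps the top `ceiling(multiplier * expected_cells)` barcodes by raw read
#' count (ties broken lexicographically), the candidate pool whose mapping
#' efficiencies feed the mixture fit.
#'
#' @param counts Data frame (`barcode`, `n`) or a raw barcode vector.
#' @param expected_cells Expected number of cells (X).
#' @param multiplier Selection multiplier (default 2.5).
#' @return Tibble (`barcode`, `n`) of candidates.
#' @export
select_candidates <- function(counts, expected_cells, multiplier = 2.5) {
  counts <- .as_barcode_counts(counts)
  expected_cells <- .check_count(expected_cells, "expected_cells", lower = 1)
  m <- as.integer(ceiling(multiplier * expected_cells))
  out <- .top_barcodes(counts, m)
  if (nrow(out) < m) {
    warn(sprintf("only %d distinct barcodes available; requested %d",
                 nrow(out), m))
  }
  out
}

#' Fit a normal mixture to mapping efficiencies
#'
#' Expectation-maximization fits of `k`-component normal mixtures to the
#' candidate barcodes' mapping efficiencies for each `k` in `k_range`; the
#' number of components is chosen by BIC. Initialization is deterministic
#' (component means at the within-range quantiles), so the fit depends only
#' on the data. The component with the highest mean is taken to hold the
#' cell-associated barcodes and the cell-calling cutoff is its mean minus
#' one standard deviation.
#'
#' @param efficiencies Numeric vector of per-barcode mapping efficiencies
#'   (>= 50 values).
#' @param k_range Component counts to try (default `2:4`; include 1 to allow
#'   a single-component fit).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param var_floor Variance floor (default 1e-6).
#' @return A `meth_mixfit` object: `$components` tibble (`component`,
#'   `weight`, `mu`, `sigma`, `selected`), `$cutoff` (mu - sigma of the
#'   selected component), `$k`, `$loglik`, `$bic`, `$converged`, `$n`.
#' @export
fit_efficiency_mixture <- function(efficiencies, k_range = 2:4, tol = 1e-8,
                                   max_iter = 500, var_floor = 1e-6) {
  x <- efficiencies[!is.na(efficiencies)]
  if (length(x) < 50) {
    abort("need at least 50 candidate efficiencies to fit the mixture.",
          class = "dropmeth_invalid_parameter")
  }
  fits <- lapply(k_range, function(k) .em_normal(x, k, tol, max_iter,
                                                 var_floor))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) {
    # single-component fallback is closed-form and always available
    fits <- c(fits, list(.em_normal(x, 1L, tol, max_iter, var_floor)))
    ok <- c(ok, TRUE)
    k_range <- c(k_range, 1L)
    if (!any(ok)) {
      abort("mixture fit failed to converge for every component count.",
            class = "dropmeth_fit_error")
    }
  }
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  bics[!ok] <- Inf
  best <- fits[[which.min(bics)]]

  comp <- tibble::tibble(component = seq_len(best$k),
                         weight = best$weight, mu = best$mu,
                         sigma = best$sigma)
  sel <- which.max(comp$mu)
  comp$selected <- seq_len(best$k) == sel
  structure(
    list(components = comp,
         cutoff = comp$mu[sel] - comp$sigma[sel],
         k = best$k, loglik = best$loglik, bic = best$bic,
         converged = best$converged, n = length(x),
         data = x,
         tried = tibble::tibble(k = k_range, bic = bics, converged = ok)),
    class = "meth_mixfit")
}

# deterministic quantile-initialized EM for a univariate normal mixture;
# asserts the monotone log-likelihood ascent EM guarantees
.em_normal <- function(x, k, tol, max_iter, var_floor) {
  n <- length(x)
  if (k == 1L) {
    mu <- mean(x); sg <- max(sd(x), sqrt(var_floor))
    ll <- sum(dnorm(x, mu, sg, log = TRUE))
    return(list(k = 1L, weight = 1, mu = mu, sigma = sg, loglik = ll,
                bic = -2 * ll + 2 * log(n), converged = TRUE, iter = 0L))
  }
  mu <- as.numeric(quantile(x, (2 * seq_len(k) - 1) / (2 * k), names = FALSE))
  sg <- rep(max(sd(x) / k, sqrt(var_floor)), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], sg[j]), numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    if (ll < ll_old - 1e-6) {
      abort("EM log-likelihood decreased; numerical failure.",
            class = "dropmeth_fit_error")
    }
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1e-8)) break  # empty component: non-convergent at this k
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk,
                    var_floor))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  npar <- 3 * k - 1
  list(k = k, weight = w, mu = mu, sigma = sg, loglik = ll_old,
       bic = -2 * ll_old + npar * log(n), converged = converged, iter = it)
}

#' @export
print.meth_mixfit <- function(x, ...) {
  cat(sprintf("<meth_mixfit> k = %d, loglik = %.2f, cutoff = %.4f\n",
              x$k, x$loglik, x$cutoff))
  print(x$components)
  invisible(x)
}

#' @rdname fit_efficiency_mixture
#' @param x A `meth_mixfit` object.
#' @param ... Unused.
#' @export
tidy.meth_mixfit <- function(x, ...) x$components

#' @rdname fit_efficiency_mixture
#' @export
glance.meth_mixfit <- function(x, ...) {
  sel <- x$components[x$components$selected, ]
  tibble::tibble(k = x$k, loglik = x$loglik, bic = x$bic,
                 converged = x$converged, n = x$n,
                 mu_selected = sel$mu, sigma_selected = sel$sigma,
                 cutoff = x$cutoff)
}

#' @rdname fit_efficiency_mixture
#' @param object A `meth_mixfit` object.
#' @export
autoplot.meth_mixfit <- function(object, ...) {
  df <- tibble::tibble(efficiency = object$data)
  grid <- seq(min(df$efficiency), max(df$efficiency), length.out = 400)
  comp <- object$components
  dens <- purrr::pmap(comp, function(component, weight, mu, sigma, selected) {
    tibble::tibble(component = factor(component), x = grid,
                   y = weight * dnorm(grid, mu, sigma))
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$efficiency)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$component)) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = "mapping efficiency", y = "density",
                  title = sprintf("mixture fit (k = %d), cutoff = %.3f",
                                  object$k, object$cutoff))
}

#' Call cells from candidate barcodes
#'
#' Candidates with mapping efficiency at or above the mixture cutoff
#' (mean minus one SD of the highest-mean component) are cells; the rest are
#' noise. Equality passes.
#'
#' @param candidates Tibble with `barcode` and `efficiency` columns.
#' @param fit A [fit_efficiency_mixture()] object.
#' @return The candidate tibble with a `call` column (`"cell"`/`"noise"`)
#'   and the cutoff attached as attribute `cutoff`.
#' @export
call_cells <- function(candidates, fit) {
  stopifnot(inherits(fit, "meth_mixfit"))
  candidates <- tibble::as_tibble(candidates)
  if (!all(c("barcode", "efficiency") %in% names(candidates))) {
    abort("`candidates` must have barcode and efficiency columns.",
          class = "dropmeth_invalid_parameter")
  }
  out <- candidates |>
    dplyr::mutate(call = ifelse(.data$efficiency >= fit$cutoff,
                                "cell", "noise"))
  if (!any(out$call == "cell")) warn("no candidate passed the cutoff.")
  attr(out, "cutoff") <- fit$cutoff
  out
}

#' Classify barcode species purity in a mixing experiment
#'
#' In a two-species (barnyard) design, a barcode is called pure for a
#' species when more than `threshold` of its uniquely aligned reads hit that
#' species' genome; otherwise it is mixed. Barcodes with zero aligned reads
#' are excluded and tallied.
#'
#' @param counts Long tibble (`barcode`, `species`, `n`) of uniquely aligned
#'   read counts per barcode and species (spike-in excluded).
#' @param threshold Purity threshold (default 0.90, strict inequality).
#' @return A `species_purity` object: `$calls` tibble (`barcode`, `total`,
#'   one `frac_<species>` column per species, `call`), `$summary` tibble of
#'   call counts with the pure fraction, `$threshold`, `$n_zero`.
#' @export
species_purity <- function(counts, threshold = 0.90) {
  .check_fraction(threshold, "threshold")
  counts <- tibble::as_tibble(counts)
  sp <- sort(unique(counts$species))
  if (length(sp) != 2) {
    abort("`counts` must contain exactly two species tags.",
          class = "dropmeth_invalid_parameter")
  }
  wide <- counts |>
    dplyr::group_by(.data$barcode, .data$species) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = "n",
                       values_fill = 0L)
  tot <- wide[[sp[1]]] + wide[[sp[2]]]
  n_zero <- sum(tot == 0)
  wide <- wide[tot > 0, ]
  tot <- tot[tot > 0]
  f1 <- wide[[sp[1]]] / tot
  f2 <- wide[[sp[2]]] / tot
  call <- dplyr::case_when(f1 > threshold ~ paste0("pure_", sp[1]),
                           f2 > threshold ~ paste0("pure_", sp[2]),
                           TRUE ~ "mixed")
  calls <- tibble::tibble(barcode = wide$barcode, total = as.integer(tot),
                          f1, f2, call = call)
  names(calls)[3:4] <- paste0("frac_", sp)
  summary <- calls |> dplyr::count(.data$call, name = "n")
  structure(list(calls = calls, summary = summary,
                 pure_fraction = mean(startsWith(call, "pure_")),
                 threshold = threshold, n_zero = n_zero,
                 species = sp),
            class = "species_purity")
}

#' @export
print.species_purity <- function(x, ...) {
  cat(sprintf("<species_purity> threshold %.2f, %.1f%% pure (%d zero-read excluded)\n",
              x$threshold, 100 * x$pure_fraction, x$n_zero))
  print(x$summary)
  invisible(x)
}

#' @rdname species_purity
#' @param x,object A `species_purity` object.
#' @param ... Unused.
#' @export
tidy.species_purity <- function(x, ...) x$calls

#' @rdname species_purity
#' @export
glance.species_purity <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, n = nrow(x$calls),
                 n_zero = x$n_zero, pure_fraction = x$pure_fraction)
}

#' @rdname species_purity
#' @export
autoplot.species_purity <- function(object, ...) {
  calls <- object$calls
  cols <- paste0("frac_", object$species)
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data[[cols[1]]] * .data$total,
                               y = .data[[cols[2]]] * .data$total,
                               colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = paste("reads:", object$species[1]),
                  y = paste("reads:", object$species[2]),
                  title = "species-mixing read counts per barcode")
}
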