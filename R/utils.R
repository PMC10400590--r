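.datatable.aware <- TRUE

# Internal validation and small sequence helpers.
#
# Conventions used throughout the package:
#   * lengths in micrometres, volumes in picolitres, flows in microlitres per
#     minute, durations in minutes (unit conversions live in .droplet_volume_pl)
#   * genomic intervals are 0-based half-open internally; 1-based inclusive
#     coordinates appear only at the allc-file boundary and in barcode
#     extraction, where the conventional coordinates are 1-based

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "dropmeth_invalid_parameter")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), class = "dropmeth_invalid_parameter")
  }
  invisible(x)
}

.check_fraction <- function(x, name, strict = FALSE) {
  .check_number(x, name, 0, 1, strict_lower = strict, strict_upper = strict)
}

.check_count <- function(x, name, lower = 0L) {
  .check_number(x, name, lower = lower)
  if (abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "dropmeth_invalid_parameter")
  }
  invisible(as.integer(round(x)))
}

# droplet volume in picolitres for a diameter in micrometres:
# (pi/6) d^3 [um^3], 1 um^3 == 1e-3 pL
.droplet_volume_pl <- function(diameter_um) {
  (pi / 6) * diameter_um^3 * 1e-3
}

.revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# seeded-RNG scope: run `expr` under a local RNG state seeded with `seed`
# (NULL leaves the global stream untouched)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# derive a stream-specific child seed below 2^31 from a master seed
.child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + stream * 7919) %% 2147483629
}
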