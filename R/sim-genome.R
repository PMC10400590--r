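#' Simulate a toy reference genome with an unmethylated spike-in contig
#'
#' Generates random-composition contigs for one or two species plus a single
#' spike-in contig that plays the role of the unmethylated phage control used
#' to measure bisulfite conversion. With two species, contigs are tagged
#' `"A"`/`"B"` round-robin so species-mixing (barnyard) designs can be
#' simulated.
#'
#' @param n_contigs Number of genomic contigs (excluding the spike-in).
#' @param contig_length Length of each contig in bp (>= 10 kb).
#' @param gc_fraction GC content in (0, 1).
#' @param n_species 1 or 2.
#' @param spike_length Length of the spike-in contig (default mirrors the
#'   ~48.5 kb phage genome).
#' @param seed Integer seed for reproducibility.
#' @return A `sim_genome` object: named character vector of sequences in
#'   `$seq` plus a `$contigs` tibble (`contig`, `length`, `species`,
#'   `is_spike`).
#' @examples
#' g <- sim_genome(n_contigs = 2, contig_length = 2e4, seed = 1)
#' g$contigs
#' @export
sim_genome <- function(n_contigs = 4, contig_length = 5e5, gc_fraction = 0.42,
                       n_species = 1, spike_length = 48000, seed = NULL) {
  n_contigs <- .check_count(n_contigs, "n_contigs", lower = 1)
  .check_number(contig_length, "contig_length", lower = 1e4)
  .check_fraction(gc_fraction, "gc_fraction", strict = TRUE)
  if (!n_species %in% c(1, 2)) {
    abort("`n_species` must be 1 or 2.", class = "dropmeth_invalid_parameter")
  }
  .check_number(spike_length, "spike_length", lower = 1e3)

  species <- if (n_species == 1) rep("A", n_contigs) else {
    rep(c("A", "B"), length.out = n_contigs)
  }
  nm <- sprintf("chr%s%d", species,
                stats::ave(seq_len(n_contigs), species, FUN = seq_along))

  .with_seed(seed, {
    w <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    seqs <- cpp_random_strings(n_contigs, as.integer(contig_length),
                               names(w), unname(w))
    spike <- cpp_random_strings(1L, as.integer(spike_length),
                                names(w), unname(w))
    seq <- stats::setNames(c(seqs, spike), c(nm, "spike"))
    structure(
      list(seq = seq,
           contigs = tibble::tibble(
             contig = names(seq),
             length = nchar(seq),
             species = c(species, "spike"),
             is_spike = c(rep(FALSE, n_contigs), TRUE)),
           gc_fraction = gc_fraction,
           seed = seed),
      class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d contigs, %.2f Mb, GC %.2f\n",
              nrow(x$contigs), sum(x$contigs$length) / 1e6, x$gc_fraction))
  print(x$contigs)
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome A [sim_genome()] object or a named character vector.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seq <- if (inherits(genome, "sim_genome")) genome$seq else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seq), path)
  invisible(path)
}

#' Load a genome from FASTA
#'
#' @param path FASTA path.
#' @param spike_contig Name of the unmethylated spike-in contig, if present.
#' @param species Optional named character vector mapping contig to species
#'   tag; defaults to a single species `"A"`.
#' @return A `sim_genome` object.
#' @export
load_genome_fasta <- function(path, spike_contig = "spike", species = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  seq <- stats::setNames(as.character(ss),
                         sub("\\s.*$", "", names(ss)))
  sp <- if (is.null(species)) {
    ifelse(names(seq) == spike_contig, "spike", "A")
  } else {
    unname(species[names(seq)])
  }
  structure(
    list(seq = seq,
         contigs = tibble::tibble(contig = names(seq), length = nchar(seq),
                                  species = sp,
                                  is_spike = names(seq) == spike_contig),
         gc_fraction = NA_real_, seed = NULL),
    class = "sim_genome")
}

# cytosine site index for one sequence: 0-based positions of top-strand C and
# bottom-strand C (forward G), with their CpG flags from the genomic context
.site_index <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(b)
  pos_top <- which(b == "C") - 1L
  pos_bot <- which(b == "G") - 1L
  nxt <- c(b[-1], "N")
  prv <- c("N", b[-L])
  list(pos_top = pos_top,
       cg_top = (nxt[pos_top + 1L] == "G"),
       pos_bot = pos_bot,
       cg_bot = (prv[pos_bot + 1L] == "C"))
}
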