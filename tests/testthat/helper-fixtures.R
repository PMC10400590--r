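# Shared fixtures, built once per test run and memoised. Sizes are chosen so
# the whole suite stays desk-scale; the stochastic recovery checks that need
# realistic depth build their own larger runs in test-acceptance.R.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, builder(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

# tiny two-contig genome + three-type methylomes
fx_genome <- function() fixture("genome", function() {
  sim_genome(n_contigs = 2, contig_length = 1e5, gc_fraction = 0.42,
             spike_length = 20000, seed = 101)
})

fx_methylomes <- function() fixture("methylomes", function() {
  sim_methylomes(fx_genome(), n_dmrs = 3, dmr_length = 3000, seed = 102)
})

fx_experiment <- function() fixture("experiment", function() {
  sim_experiment(droplet_design(),
                 c(typeA = 5, typeB = 5, typeC = 5), seed = 103)
})

# clean small read set: no errors, perfect conversion, no duplicates
fx_reads_clean <- function() fixture("reads_clean", function() {
  sim_reads(fx_experiment(), fx_methylomes(), fx_genome(),
            reads_per_cell = 400, conversion_rate = 1, seq_error = 0,
            duplication_rate = 0, spike_fraction = 0.05,
            noise_reads_mean = 30, store_states = TRUE, seed = 104)
})

# realistic small read set
fx_reads_noisy <- function() fixture("reads_noisy", function() {
  sim_reads(fx_experiment(), fx_methylomes(), fx_genome(),
            reads_per_cell = 400, conversion_rate = 0.99,
            seq_error = 0.001, duplication_rate = 0.3,
            spike_fraction = 0.05, noise_reads_mean = 30, seed = 105)
})

fx_index <- function() fixture("index", function() bs_index(fx_genome()))

# demultiplexed + aligned clean reads, shared by alignment/methcall tests
fx_aln_clean <- function() fixture("aln_clean", function() {
  sr <- fx_reads_clean()
  wl <- build_whitelist(barcode_counts(sr$reads),
                        sum(fx_experiment()$barcodes$class == "cell"))
  dx <- demultiplex(sr$reads, wl)
  align_mates(dx, fx_index())
})

fx_allc_clean <- function() fixture("allc_clean", function() {
  call_methylation(dedup_alignments(fx_aln_clean()), fx_genome())
})

# pure-R reference methylation caller used as the independent oracle for the
# compiled caller: walks one alignment and returns per-site calls
r_oracle_call <- function(seq, contig_seq, start0, mode) {
  revcomp1 <- function(s) chartr("ACGT", "TGCA",
                                 paste(rev(strsplit(s, "")[[1]]),
                                       collapse = ""))
  ov <- if (mode %in% c("CTOT", "CTOB")) revcomp1(seq) else seq
  S <- strsplit(contig_seq, "")[[1]]
  l <- nchar(seq)
  out <- list()
  if (mode %in% c("OT", "CTOT")) {
    for (j in seq_len(l)) {
      pos <- start0 + j  # 1-based
      if (S[pos] != "C") next
      b <- substr(ov, j, j)
      if (!b %in% c("C", "T")) next
      cls <- if (pos < length(S) && S[pos + 1] == "G") "CG" else "CH"
      out[[length(out) + 1]] <- list(pos = pos, strand = "+", class = cls,
                                     meth = as.integer(b == "C"))
    }
  } else {
    for (j in seq_len(l)) {
      pos <- start0 + l - j + 1  # 1-based forward coordinate
      if (S[pos] != "G") next
      b <- substr(ov, j, j)
      if (!b %in% c("C", "T")) next
      cls <- if (pos > 1 && S[pos - 1] == "C") "CG" else "CH"
      out[[length(out) + 1]] <- list(pos = pos, strand = "-", class = cls,
                                     meth = as.integer(b == "C"))
    }
  }
  dplyr::bind_rows(out)
}

# adjusted Rand index (mclust supplies the cross-checked implementation where
# available; this closed form is the fallback)
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
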