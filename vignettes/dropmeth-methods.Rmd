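---
title: "Models and methods behind dropmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dropmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dropmeth` models the computation of a droplet-based single-cell
whole-genome bisulfite sequencing (scWGBS) experiment: cells and barcode
beads meet in microfluidic droplets, barcoded DNA is bisulfite-converted so
unmethylated cytosine reads as thymine, and analysis must demultiplex an
in-read barcode, align three-letter reads, call per-cytosine methylation,
separate cell-associated barcodes from noise, and cluster cells from very
sparse methylomes. This vignette documents the models, the parameters that
matter, the numerical choices, and what the simulation does and does not
capture.

## Droplet statistics

Cell loading into droplets is Poisson: with mean `λ` cells per droplet,
`P(X = n) = e^{-λ} λ^n / n!`. Designs are usually quoted by the fraction of
occupied droplets `f = P(X ≥ 1)`, inverted by `calibrate_lambda(f) =
-ln(1-f)`. At the standard 10% occupancy, `λ ≈ 0.105`, single occupancy is
9.48% and double occupancy 0.4995% — just under the 0.5% rule of thumb.
"Double occupancy" here means exactly two cells; `P(X ≥ 2)` at the same λ is
0.52%, which is why the occupancy-class argument exposes both readings.

Droplet counts follow from dispensed aqueous volume over the single-droplet
volume `(π/6)d³`: all lengths are in µm, volumes in pL, flows in µl/min and
durations in minutes, with the conversion centralized in one helper. A
35 µm droplet is 22.4 pL, so 4 µl/min for 10 min gives 1.78 million droplets
and a generation rate of ~2970/s. The fusion-device runtime is
`n_beads / bead_occupancy / rate / 60`; the expected barcoded-cell yield is
the product `n_pairings × P(X ≥ 1) × bead_occupancy × fusion_efficiency`,
and `sim_experiment()` realizes it with binomial/Poisson draws whose mean is
exactly that product (checked to 3σ in the tests).

## The synthetic-data generator

The generator is the package's study design, not a fixture. Its defaults
describe one fixed set of conditions:

* **Genome** (`sim_genome()`): four 500 kb i.i.d.-composition contigs at
  42% GC plus one fully unmethylated 48 kb spike-in contig standing in for
  the phage control used to measure bisulfite conversion. Real genomes have
  isochores, repeats and CpG islands; none of these are modelled, so
  alignment here is easier than against a mammalian genome and mapping
  efficiencies are near 1 rather than the ~60–70% of real libraries. The
  cell/noise separation the cell caller relies on is therefore driven by
  the noise-read model, not by genome complexity.
* **Methylomes** (`sim_methylomes()`): per CpG-context cytosine, the
  methylation probability is `plogis(qlogis(target) + block effect)` with a
  `N(0, 0.7²)` logit-scale effect shared within 20 kb blocks —
  methylation-domain structure, which is what gives cell types
  distinguishable *binned* profiles after global-level normalization — plus
  Beta site noise (concentration 5). CH sites get Beta probabilities around
  the CH target (~1%). Default global mCG targets are 50.5%, 68.2% and
  63.0%, cell-line-like values spanning the realistic range. Each type owns
  8 planted DMRs of 5 kb, hypomethylated by 0.4 in that type only and
  disjoint across types; probabilities are then rescaled so each type's
  realized genome-wide mean matches its target to < 0.01 (the rescaling
  slightly shrinks the planted contrast, by ~2% at the defaults).
* **Experiment** (`sim_experiment()`): barcode droplets are Bernoulli
  beaded (7%) and Bernoulli fused (80%) with Poisson(λ)-occupied cell
  droplets; beads carry unique 15-mers over {A,T,G}. Fused-empty barcodes
  become noise barcodes; ≥2 cells is a doublet. A `forced_doublets`
  fraction converts that share of singlets into cross-species doublets *by
  construction* (rounded count, not per-barcode coin flips) so a stated
  doublet rate exists in every realization.
* **Reads** (`sim_reads()`): fragment lengths are truncated normal
  (mean 300, SD 80, minimum 150 bp — the short-fragment removal step);
  per-cell depth is lognormal (CV 0.2), echoing the depth unevenness that
  real droplet libraries show. Each pair is a fresh fragment with
  probability `1 - duplication_rate`, else a PCR re-emission of a previous
  fragment of the same cell with the *same* conversion pattern (conversion
  happens before amplification) and fresh sequencing errors. On the
  template strand every cytosine draws its state from the owning cell's
  methylome and unmethylated C → T with probability `conversion_rate`
  (0.99); R2 reads the template from its 5' end, R1 the random-primed
  complementary strand, so the two mates carry opposite-strand conversion
  patterns and the aligner must handle both. Raw reads are assembled as
  24 nt stub + barcode + 1 nt junction + genomic (R2) and 15 nt stub +
  genomic (R1), with the artificial bases regenerated per read — which
  makes the fixed clips (15/40) exactly correct. Noise barcodes receive
  low-complexity background: half adapter-dimer repeats, half scrambled
  genome-composition sequence, both designed to fail alignment since the
  cell caller assumes noise barcodes have low mapping efficiency.
  Sequencing error is uniform substitution applied after conversion.
  Quality modelling, polymerase bias, chimeras and CNVs are out of scope.

All randomness sits behind R's RNG under per-stage child seeds derived from
one master seed; identical seeds give byte-identical FASTQ.

## Demultiplexing

The barcode is R2 bases 25–39 (1-based, inclusive; the only place the
package uses 1-based inclusive coordinates besides allc output — internal
intervals are 0-based half-open). The whitelist keeps the top
`⌈2.5X⌉` barcodes by raw read count (X = expected cells), ties broken
lexicographically for determinism. Error correction is Hamming-distance-1
over A/C/G/T, unambiguous targets only: a neighbour reachable from two
accepted barcodes corrects to none. Trimming happens at demux time so no
downstream module ever sees artificial bases. Conservation (assigned +
unassigned + short = input) is asserted in the run report.

## Three-letter alignment

The index stores each contig twice in C→T space: the forward strand and the
reverse complement. A read is queried C→T-converted as-is (hits are OT/OB)
and as its reverse complement (CTOT/CTOB — the PBAT orientations; a
complementary-strand read reverse-complemented *is* a template-strand read,
which reduces four orientations to two query forms). Seeds are exact 24-mers
at the read start and mid-read; since simulated reads carry no indels,
extension is a substitution-only mismatch count with early abandoning,
`max_edit = 3`. Only a unique best hit — strictly better than the runner-up
across all candidates and orientations — is reported; ties are ambiguous.
Mates are aligned separately (R1 restricted to CTOT/CTOB, R2 to OT/OB) and
merged per barcode; no mate-rescue. Mapping efficiency is unique mates over
submitted mates, counted per mate, and is the cell-calling statistic.

## Methylation calling

After per-barcode deduplication on (barcode, contig, start, end,
orientation) — lowest edit distance, then lowest read id, wins — each
alignment is restored to template-strand orientation and walked against the
reference: at a reference cytosine on the informative strand, read C is a
methylated call, read T unmethylated, and any other base (a sequencing
error) is ignored rather than counted in coverage, to avoid biasing rates.
Context is the reference trinucleotide on the cytosine's own strand, CG if
the next base is G, else CH (no CHG/CHH split). CpG sites are not
strand-collapsed in allc output; `collapse_cpg()` provides the collapsed
view for CpG counting and DMR calling. The conversion rate is
`1 - Σmc/Σcov` over the spike-in contig, withheld below 1000 calls; global
mCG/CG and mCH/CH exclude the spike-in. "Unique reads" counts mates, not
pairs, since mates are aligned and deduplicated individually.
`saturation_curve()` uses the exact without-replacement expectation
`Σ_f (1 − C(N−m_f, d)/C(N, d))`, which is monotone, concave and plateaus at
library complexity.

## Cell calling and species purity

Mapping efficiencies of the top-2.5X candidates are fitted with univariate
normal mixtures by EM for k ∈ {2,3,4} (a closed-form k = 1 fallback exists
and k = 1 can be requested), selected by BIC. Initialization is
deterministic — component means at the `(2i−1)/2k` quantiles, equal weights,
pooled SD — so a fit depends only on the data; tolerance 1e-8 on the
log-likelihood, at most 500 iterations, variance floor 1e-6, and the EM
ascent property is asserted every iteration. The component with the highest
mean is declared the cell component and the cutoff is `μ − σ`; equality
passes. Note the operating characteristic this rule fixes: a threshold one
SD below the mean retains Φ(1) ≈ 84% of a normal cell component, so recall
against generative truth is ~0.84 by construction whenever the cell
component is genuinely normal — the rule trades recall for purity.

Species purity in two-species designs divides each barcode's uniquely
aligned reads (spike-in excluded) between the species tags; a barcode is
pure when one fraction strictly exceeds 0.90, else mixed; zero-read
barcodes are excluded and tallied.

## Binned clustering and annotation

The feature matrix is cells × fixed-width genome bins (100 kb default; 1 Mb
for very shallow data) of `Σmc/Σcov` for the chosen class, missing when a
cell covers fewer than 20 sites in the bin, and bins kept only when ≥ 50% of
cells observe them. Rows are divided by each cell's global level — removing
global differences so clustering reflects the *distribution* of methylation
— and missing entries are then imputed with the neutral value 1, which
avoids coverage-driven artifacts. PCA is centering-only (no unit-variance
scaling; bins share a scale), top 50 PCs or fewer when the matrix is
smaller; an unweighted symmetric kNN graph (k = 15, Euclidean in PC space)
feeds Louvain at resolution 1. Partitions with modularity below 0.3 are
collapsed to a single cluster: kNN graphs of homogeneous data yield
spurious partitions at modularity ~0.10–0.15 while genuinely structured
data score far higher (~0.67 in the three-type study), so 0.3 acts as a
no-structure guard. UMAP is deliberately absent — the 2-D PC coordinates
serve for plotting and nothing downstream depends on a projection.

Cluster annotation pools each cluster's CpG counts over every reference DMR
set and z-scales across clusters within each set (sample SD). Because
type-specific DMRs are *hypomethylated* in their own type, each cluster is
labelled with its minimum-z set, provided that minimum is below −1 (no-call
otherwise). The rates are first divided by each cluster's global mCG/CG —
the same normalization as the clustering matrix. This is a deliberate
design choice: with clusters whose global mCG spans 50–68%, raw-rate
z-scores confound global shifts with targeted hypomethylation and the
own-type minimum hovers around the −1 rule (−0.9 to −1.06 in three-cluster
studies); after normalization the own-type z approaches the three-cluster
bound −2/√3 ≈ −1.15. `normalize = FALSE` restores raw-rate scoring.

## DMR calling

Pseudobulk profiles are exact per-site sums over member cells. The caller
collapses CpG strands, keeps sites with ≥ 5× coverage in both groups, and
applies a two-sided two-proportion z-test with pooled variance; sites at
rate 0 or 1 in both groups are skipped. P-values are BH-adjusted; CpGs at
q ≤ 0.05 anchor regions. Anchors alone truncate and fragment true regions
at realistic coverage — at 30× and Δ = 0.4 the per-CpG power against the
BH threshold is only ~0.3 — so same-sign CpGs at nominal p ≤ 0.05 extend
and bridge anchored regions (hotspot extension, in the spirit of
methylKit/metilene). Supporting CpGs within 500 bp merge; a region needs
≥ 3 anchors and an absolute pooled difference ≥ 0.1. Since extension only
acts around BH-controlled anchors, the null stays clean (≈ 0 false regions
per 10⁴ null CpGs). Region q-values combine member z-scores (Stouffer)
with BH across regions. Swapping groups negates differences and preserves
regions. This caller is a self-contained approximation; it does not model
biological dispersion across replicates the way smoothing-based
shrinkage callers do, and its acceptance surface is planted-DMR recovery.
Gene annotation assigns at most one gene per region by promoter
(TSS ± 2 kb) > gene body > nearest TSS, ties by distance then name.

## Problem sizes and what the tests show

The test suite and the acceptance script run fixed, desk-scale studies
chosen by the package: the full-depth study uses 45 expected cells at
~11,000 read pairs/cell (≈ 15–17k unique mates after 30% duplication) on
the 2 Mb genome — enough for ±1.5-point recovery of the global mCG targets
and clean three-type clustering; conversion recovery uses ≥ 10⁴ spike-in
calls; the species-mixing study uses 120 expected cells with 1% ambient
contamination and 2% forced cross-species doublets; DMR recovery uses 20
planted DMRs (Δ = 0.4, 20 CpGs, 30×) over five replicate simulations with
a ten-seed matched null. The annotation-robustness loop regenerates
genome, methylomes and binomial counts per seed at coverage matched to the
full run's cluster pseudobulk (~2×), exercising the z-score labelling
across ten independent realizations without re-running the read-level
pipeline each time. Passing these tests shows the computation is correct
and well-calibrated *under the generator's assumptions*; it does not show
robustness to repeats, mappability artifacts, variable conversion
efficiency along fragments, or real ambient contamination structure.

## Known limitations

* Uniform-composition genomes: no repeats, so ambiguity handling is
  exercised only lightly; mapping efficiency is unrealistically high for
  cell barcodes.
* The aligner is substitution-only within its edit band and is not meant
  for large genomes.
* CH methylation is modelled i.i.d. per site; there is no gene-body mCH
  patterning, so CH-based clustering is not meaningfully testable here.
* The DMR caller's variance model is binomial-only (no biological
  dispersion between pseudobulk groups).
* The μ−σ cell-calling rule caps recall near 84% on a normal cell
  component, by design.
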