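---
title: "Classifying transcriptional memory in nuclear-transfer embryos"
author: "ntmemory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcriptional memory in nuclear-transfer embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntmemory)
```

## The biological question and the statistical model

Nuclear transfer (NT) places a differentiated somatic nucleus into an
enucleated egg. Reprogramming of the donor transcriptome is incomplete: some
transcripts "remember" the donor cell's expression state in the new embryonic
cell type. Comparing three groups — endoderm **donor** cells, ectoderm of
**IVF** control embryos, and ectoderm of **NT** embryos — defines the classes
this package assigns:

* **ON-memory**: up in donor relative to IVF ectoderm *and* still up in NT
  ectoderm relative to IVF. The donor's active state persists in the wrong
  cell type.
* **OFF-memory**: the mirror image; the donor's silent state persists.
* **Reprogrammed (down/up)**: donor-differential transcripts correctly reset
  to IVF levels in NT ectoderm.
* **Resistant-other**: significant in both Donor/IVF and NT/IVF but with
  discordant signs ("too much" up- or down-regulated after NT).

The classifier consumes three differential-expression contrasts (Donor/IVF,
NT/IVF, Donor/NT), each summarized per transcript by a log2 fold change and
an FDR, plus donor RPKM. All threshold comparisons are strict: the defaults
are FDR < 0.05, donor RPKM > 1 in **all** donor samples, and a "3FC"
subclass at |log2 FC| > 1.5 (a 2^1.5 ≈ 2.83-fold, i.e. roughly 3-fold,
change). A fold-change-only variant (`classify_human()`) supports designs
without replication, with strict cutoffs 2.3 and 1 on the log2 scale and a
2–5FC / >5FC split. Replicated designs can be filtered per experiment and
intersected (`intersect_replicates()`), and transcripts responding to a
donor-cell perturbation (e.g. a Kdm5b demethylase treatment) can be removed
before interpretation (`exclude_treatment_de()`).

### The differential-expression engine

Counts are modeled as negative binomial with mean \(m\) and variance
\(m + \phi m^2\); \(\phi = 0\) degenerates to Poisson. `exact_nb_test()`
is a self-contained exact conditional test in the Robinson–Smyth style:

1. library sizes (column totals) are equalized by scaling every sample to
   the geometric-mean library size;
2. a single common dispersion is estimated by a method-of-moments
   regression through the origin, \(\hat\phi = \sum (s^2 - \bar y) / \sum
   (\bar y^2 - s^2/n)\), pooling all transcript-by-group cells (the
   \(- s^2/n\) term corrects the upward bias of the squared sample mean);
3. for each transcript the pooled adjusted count is split between the two
   groups; conditional on the total, the split distribution is free of the
   underlying mean (negative hypergeometric; binomial when \(\phi = 0\)),
   and the two-sided p-value sums the probabilities of all splits no more
   likely than the observed one (the minimum-likelihood rule).

Fold changes are `log2((cpmA + c)/(cpmB + c))` with prior count `c = 0.5`
on per-million-scaled group means, which keeps logFC finite and
sign-faithful. FDR is Benjamini–Hochberg, applied across the transcripts
that pass the expression filter (CPM > 1 in all donor samples, or in ≥ 70%
of IVF or of NT samples).

The engine deliberately implements the *simplest* member of the exact-NB
family: common dispersion, total-count normalization, no covariates. Counts
of significant transcripts on real data will therefore differ from what a
tagwise-dispersion, TMM-normalized analysis reports; the package's claims
are property-based (calibration, recovery of planted effects), not
count-reproduction.

### Chromatin covariates of memory

H3K4me3 around the transcription start site is the chromatin covariate the
pipeline links to memory. Two measurements are implemented:

* **Intensity** (`tss_window_profiles()`): a 4-kb window centered on the
  TSS is cut into 50-bp bins and each bin gets the input-normalized,
  per-million level
  \[
  \mathrm{level} = \frac{\mathrm{Coverage_{IP}}}{N_{IP}/10^6}
                 - \frac{\mathrm{Coverage_{input}}}{N_{input}/10^6},
  \]
  where coverage is the *mean per-base depth* over the bin and \(N\) the
  track's total mapped reads. Mean-per-base (rather than summed) binning
  makes values bin-size invariant; negative levels are kept, because the
  formula permits them and flooring would bias set comparisons. Gene-set
  metaplots are per-bin arithmetic means, the per-gene summary is the
  integral (sum over bins), and sets are compared with a two-sample
  two-sided Kolmogorov–Smirnov test (asymptotic p). The window and bin are
  parameters: 2000/50 reproduces the narrower human reanalysis, and a 1-kb
  window is obtained the same way.
* **Breadth** (`tss_spanning_widths()`): from called peaks (broadPeak), the
  width of the peak containing the TSS base under half-open coordinates —
  a peak ending exactly at the TSS does not span it. When several peaks
  contain one TSS, the widest is taken: deterministic, and conservative in
  the sense that it can only understate a breadth *difference* between
  sets. Breadth distributions are compared by ECDF and KS.

Coordinates are 0-based half-open throughout the on-disk formats (BED,
bedGraph) and converted to R's 1-based closed convention at the boundary.
Bin 1 of a profile is always the most-upstream bin of the *gene*, i.e. bins
are reversed for minus-strand transcripts.

### Transcriptome structure

`double_zscore()` applies z-score scaling twice to the filtered CPM matrix:
per transcript within each batch, then per transcript across all samples.
The per-batch stage removes location/scale differences between batches
("experiments produced at the same time"); the test suite verifies exact
invariance to per-batch affine distortions of any transcript row. Rows are
the scaling axis — scaling columns could not remove gene-level batch
variability. Sample sd (n − 1) is the convention; batches of one sample are
an error, and constant rows are zeroed with a warning rather than dropped
so matrix shapes stay aligned.

Sample clustering uses the Ward criterion applied to the **unsquared**
Euclidean distance matrix (the `ward.D` convention) — this is what the
widely quoted R setting executes, and the test suite pins the full merge
history to an independent Lance–Williams implementation. PCA is
correlation-mode: transcripts are standardized to unit variance before the
eigendecomposition (zero-variance transcripts dropped with a warning).
Presentation tables are `heatmap_matrix()` (log2 FC over the mean IVF or
pooled reference, pseudocount 1, matching the `log2(1 + RPKM)` axis
convention) and `ma_table()` (NT/IVF logFC against mean donor
`log2(1 + RPKM)`).

## What the synthetic generator emulates — and what it does not

`simulate_expression()` plants the five classes with known group means:
baseline log2 relative expression is Normal(5, 2); the memory effect is a
`memory_log2fc` (default 3) log2 shift between donor and IVF; NT retains a
fraction `nt_retention` (default 0.8) of the donor effect for memory
classes and none for reprogrammed classes. Counts are negative binomial
(default \(\phi = 0.05\); 0.1 in the null-calibration runs) at library
sizes of 0.8–1.2 million reads. The default sample layout — 3 donor, 11
IVF, 12 NT samples over 3 batches — mirrors the real experimental design,
and the batch effect is a log-normal (sd 0.2) per-batch library-scale
multiplier, the minimal structure the double z-score stage is built to
remove. The effect-size distribution is a free parameter of the generator,
not an estimate from real data: no quantitative effect-size distribution
for memory genes is available, so defaults were chosen once as values a
bulk RNA-seq analyst would call a strong, detectable memory signal.

`simulate_chromatin()` places one TSS per transcript, non-overlapping and
equally spaced on a single synthetic chromosome, and draws base-resolution
read events: input is Poisson(background) everywhere; IP is
Poisson(background × enrichment) inside each transcript's planted peak
(centered on its TSS) and Poisson(background) outside, so enrichment 1
makes IP and input exchangeable. ON-memory transcripts default to 3000 ±
300 bp peaks at 6× enrichment versus 800 ± 150 bp at 3× for
reprogrammed-down — the qualitative contrast (broader *and* stronger) the
chromatin analyses are meant to detect.

Passing tests on this generator show that the machinery measures what it
claims to measure under its own model. They do **not** show robustness to
features of real data the generator omits: gene-length and GC biases,
tagwise dispersion, correlated genes, overlapping transcripts sharing a
TSS, read-length effects and duplicate reads, peak-caller artifacts, or
batch effects that are not pure library-scale shifts.

## Numerical choices and degenerate inputs

* Exact-test p-values are computed on the full split range with log-space
  normalization; ties in the minimum-likelihood rule use a `1e-10` relative
  slack, and p is capped at 1.
* Adjusted group totals are rounded to integers before the conditional
  test; the rounding error is at most half a count per group.
* All-zero sample columns, empty groups, out-of-bounds intervals,
  mismatched transcript universes and invalid p-values raise immediate
  errors naming the offender; TSS windows that leave the chromosome are
  skipped with a warning (a per-transcript data problem, not a usage
  error).
* Seeded determinism: the expression generator fixes the order of draws
  (classes, baselines, lengths, strands, peak widths, library sizes, batch
  factors, counts); the chromatin generator uses an offset seed so the two
  stages are independently reproducible. Identical configs produce
  byte-identical outputs.

## Problem sizes

The package's own verification runs use 5,000 transcripts with 4 + 4 + 4
samples for null calibration, 2,000 transcripts for classifier recovery,
500 transcripts (~200 per contrasted set) for the chromatin comparisons,
and 600 transcripts across 2 batches for the batch-robustness check —
sizes at which multinomial and Monte-Carlo error are small relative to the
tested margins while a full run stays fast on one CPU.

## Known limitations

* Common dispersion only; strongly heterogeneous dispersions will make the
  test anticonservative for high-dispersion transcripts.
* The donor-expression clause is applied as "RPKM > 1 in *all* donor
  samples", the stricter of the two printed readings; with many donor
  samples it becomes harsh.
* The donor-only reprogrammed-down exception needs per-sample IVF/NT RPKM;
  when only donor expression is available it cannot fire.
* Peak breadth ignores multiple transcripts sharing a TSS (each transcript
  contributes its own width; no deduplication).
* The KS p-values are asymptotic; for sets under ~10 genes prefer the
  exact test directly.
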