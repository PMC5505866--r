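# ntmemory

Transcriptional-memory analysis for nuclear-transfer (NT) embryos.

When a somatic nucleus is transplanted into an enucleated egg, reprogramming
of its transcriptome is incomplete: some transcripts keep the donor cell's
expression state in the new embryonic cell type. Comparing endoderm **donor**
cells, ectoderm of **IVF** control embryos and ectoderm of **NT** embryos,
`ntmemory` classifies every transcript as

| class | Donor/IVF | NT/IVF | meaning |
|---|---|---|---|
| ON-memory | up, FDR < 0.05 | up, FDR < 0.05 | donor's active state persists in NT |
| OFF-memory | down, FDR < 0.05 | down, FDR < 0.05 | donor's silent state persists |
| reprogrammed-down/up | up/down, FDR < 0.05 | not significant | correctly reset to IVF levels |
| resistant-other | significant | significant, discordant sign | over-shot reprogramming |

with a "3FC" subclass at |log2 FC(NT/IVF)| > 1.5 (2^1.5 ≈ 2.83 ≈ 3-fold), a
donor-expression clause (RPKM > 1 in all donor samples), a fold-change-only
variant for unreplicated human data (cutoffs 2.3 / 1 in log2), replicate
intersection, and exclusion of treatment-responsive transcripts.

Around the classifier the package provides the full pipeline:

* **Differential expression** — a self-contained exact conditional
  negative-binomial test (`exact_nb_test()`): geometric-mean library
  equalization, method-of-moments common dispersion φ (variance m + φm²),
  and an exact two-sided test on the split of the pooled count between
  groups, with Benjamini–Hochberg FDR (`bh_fdr()`) over the transcripts
  passing the expression filter (CPM > 1 in all donor or ≥ 70% of IVF or of
  NT samples).
* **H3K4me3 TSS signal** — input-normalized per-million levels,
  `Coverage_IP/(N_IP/10⁶) − Coverage_input/(N_input/10⁶)`, in 50-bp bins
  across 4-kb strand-aware TSS windows; gene-set metaplots; integral levels
  compared by two-sample Kolmogorov–Smirnov tests.
* **Peak breadth** — widths of called peaks spanning the TSS base
  (half-open containment, widest peak per TSS), ECDFs and KS comparisons.
* **Structure** — two-stage z-score batch scaling, Ward (`ward.D`,
  unsquared Euclidean) clustering of samples, correlation-mode PCA,
  heatmap/MA tables.
* **Synthetic data** — a seeded generator (`simulate_expression()`,
  `simulate_chromatin()`) that plants known memory classes into NB counts
  and matched IP/input coverage with class-dependent peak breadth and
  intensity, so the whole pipeline is testable end to end with no external
  downloads.

## Worked example

```r
library(ntmemory)

cfg <- sim_config(seed = 42, n_transcripts = 1000,
                  n_samples = c(donor = 4, IVF_ectoderm = 6, NT_ectoderm = 6),
                  dispersion = 0.05, memory_log2fc = 3, nt_retention = 0.8)
report <- run_full(pipeline_config(sim = cfg, out_dir = "run42", seed = 42))
#> [filter] 1000 of 1000 transcripts pass the expression filter
#> [de] Donor_vs_IVF: 544 transcripts at FDR < 0.05 (phi = 0.0336)
#> [de] NT_vs_IVF: 239 transcripts at FDR < 0.05 (phi = 0.0281)
#> [de] Donor_vs_NT: 496 transcripts at FDR < 0.05 (phi = 0.0321)
#> [classify] ON_memory=115, OFF_memory=98, reprogrammed_down=134,
#>            reprogrammed_up=161, ..., ON_memory_3FC=111, OFF_memory_3FC=71

report$ks$integral_level$D   # 0.965  ON-memory vs reprogrammed-down TSS signal
report$ks$breadth$D          # 0.965  ON-memory vs reprogrammed-down peak width
```

The run writes every stage artifact (counts, DE tables, `labels.tsv`,
TSS profiles and metaplots, peak widths and ECDFs, dendrogram, PCA, MA and
heatmap tables) plus a machine-readable `report.json` under `run42/`. With
the planted effect of 3 log2 units retained at 80% in NT, the classifier
recovers the planted ON-memory set almost completely (115 called vs the
~10% planted; the confusion matrix in `report.json` gives the exact
overlap), and the planted chromatin contrast — 3000-bp, 6× peaks at
ON-memory genes vs 800-bp, 3× peaks at reprogrammed-down genes — produces
near-total separation of both the integral TSS signal and the breadth
distributions (KS D ≈ 0.97).

A thin CLI over the same functions is in
`inst/scripts/ntmemory-cli.R` (`simulate` and `run-all` subcommands).

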