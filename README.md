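# m6adyn

Tools for studying how N6-methyladenosine (m6A), the most abundant internal
mRNA modification, reshapes the transcriptome during directed stem-cell
differentiation — written for the analyses that surround an m6A-seq
(MeRIP-seq) + RNA-seq experiment on hPSC → definitive endoderm → pancreatic
progenitor → islet-like organoid differentiation, where an m6A demethylase
(e.g. ALKBH5) destabilises methylated transcripts through reader-mediated
decay.

The package implements, as tested reusable functions:

* **mRNA stability profiling.** After actinomycin-D transcription shutoff,
  concentration follows dC/dt = −k·C, so ln(C/C0) = −k·t and
  t1/2 = ln(2)/k. Per-library TPM is converted to absolute attomoles by
  linear calibration against ERCC spike-ins of known amount, k is the
  negated least-squares slope of ln(C/C0) over the 0/1/2/3 h timepoints,
  and per-condition half-life tables feed Mann–Whitney distribution
  comparisons, m6A-stratified lifetime-change summaries, and per-transcript
  change classification (Wald test on the slope difference, BH-adjusted).
* **m6A peak dynamics.** Stage-to-stage inheritance (a peak is inherited
  when >50% of its span is covered by a previous-stage peak), origin
  tracing through the differentiation cascade, peak-count binning
  (0–1 / 2–4 / ≥5 peaks per gene), metagene profiles along the
  5'UTR/CDS/3'UTR axis, and DRACH ([A/G/U][A/G]AC[A/C/U]) motif scanning.
* **Simplified m6A quantification.** A windowed IP-vs-input peak caller
  (conditional binomial test, peak windows at ratio ≥ 1.5 and p < 1e-5),
  differential methylation (ratio-of-ratios z-test, |log2FC| ≥ 1,
  adjusted p < 0.05), gene-level relative m6A levels (NB Wald test;
  high-confidence m6A genes at input TPM > 5, FC > 1.5, adjusted p < 0.05),
  m6A–expression Pearson correlation (|r| > 0.5, p < 0.05), differential
  expression (NB Wald; FC > 1.5 or < 0.67, adjusted p < 0.05), and the
  hyper-methylated ∩ downregulated target screen.
* **Assay calculators.** m6A-RIP-qPCR enrichment (GAPDH-normalised ddCt),
  direct RIP enrichment 2^−[Ct(IP)−Ct(input)], and UHPLC-QQQ-MS/MS
  m6A/A percent ratios from standard curves.
* **A synthetic-data generator** with full ground truth (stage-structured
  expression, planted peaks with DRACH centers, NB IP/input counts,
  exponential decay courses with an m6A-dependent lifetime reduction, ERCC
  spike-ins, qPCR Ct tables), so every stage of the pipeline is testable
  without sequencing data.

Everything is tidyverse-shaped: functions take tibbles, return tibbles,
fitted objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
visualisations.

## Worked example

Simulate a 500-gene differentiation experiment in which m6A-tagged
transcripts lose 38% of their lifetime in a demethylase-knockout-like
condition, then estimate and compare half-lives:

```r
library(m6adyn)
library(dplyr)

cfg <- sim_config(n_genes = 500, n_replicates = 3, seed = 42)
truth <- simulate_truth(cfg)
course <- simulate_decay_course(truth)

wt <- estimate_halflives(filter(course, condition == "WT"), truth$spikeins)
ko <- estimate_halflives(filter(course, condition == "KO"), truth$spikeins)
compare_halflife_distributions(wt, ko)
#> <halflife_comparison>
#>   median WT: 6.79 h (n = 454)
#>   median KO: 5.85 h (n = 454)
#>   Mann-Whitney U = 1.213e+05, p = 4.06e-06
```

The knockout shortens half-lives overall, and stratifying the per-gene
lifetime ratio (KO/WT) by true m6A status shows the effect is confined to
methylated transcripts:

```r
status <- truth$m6a_status %>% filter(stage == "PP") %>%
  select(gene_id, m6a)
stratify_lifetime_changes(wt, ko, status)$strata
#> # A tibble: 2 × 5
#>   m6a       n mean_ratio median_ratio median_log2fc
#>   <lgl> <int>      <dbl>        <dbl>         <dbl>
#> 1 FALSE   255      1.63         0.993       -0.0108
#> 2 TRUE    199      0.726        0.630       -0.667
```

Unmethylated transcripts sit at a median ratio of ~1 (no change), while
m6A-tagged transcripts drop to 0.63 — recovering the planted 38%
reduction. `classify_halflife_changes(wt, ko)` labels the individual
transcripts (here 33 decreased, 3 increased, 464 unchanged), and
`autoplot()` on the comparison draws the cumulative distributions.

The m6A-seq arm works the same way: `simulate_m6a_counts()` →
`call_peaks()` → `differential_peaks()` → `screen_targets()`, or run the
whole flow with `run_pipeline()`, which writes TSV/BED outputs plus a JSON
manifest with seeds, thresholds and file checksums.

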