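---
title: "Models and methods: m6A dynamics, mRNA decay and the target screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: m6A dynamics, mRNA decay and the target screen}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the defaults and why they were chosen, and
what the synthetic-data tests do and do not demonstrate about real data.

## 1. mRNA decay kinetics

### Model

After transcription shutoff (an actinomycin-D chase), each transcript's
concentration is assumed to follow first-order decay,

$$\frac{dC}{dt} = -k\,C
\quad\Rightarrow\quad
\ln\frac{C(t)}{C_0} = -k\,t,
\qquad t_{1/2} = \frac{\ln 2}{k},$$

with no residual synthesis. `fit_decay()` estimates $k$ as the negated
slope of an ordinary least-squares regression of $\ln(C/C_0)$ on time over
all timepoints (default 0, 1, 2, 3 h). Assumptions worth stating:

* **Single exponential.** Multi-phasic decay, transcript isoform mixtures
  and delayed shutoff all violate this; the fit then averages phases.
* **Free intercept.** The regression intercept is not forced through zero
  so that sampling noise on the $t=0$ library perturbs one coefficient
  instead of every residual. On noise-free data the intercept is zero
  either way (verified in the tests to 1e-13).
* **Non-decaying transcripts have no half-life.** A fitted $k \le 0$ is
  flagged `increasing`, $t_{1/2}$ is reported as `Inf`, and the transcript
  is excluded from medians. This exclusion truncates the $\hat k$
  distribution of very stable transcripts and biases their surviving
  estimates upward — an inherent property of a 3-hour observation window
  on an 8-hour-median transcriptome, discussed under limitations.
* An alternative literal reading of "averaging over timepoints" — the mean
  of the per-timepoint rates $\ln(C_0/C_t)/t$ — is available as
  `mode = "per-timepoint"`. On noise-free data both modes agree exactly;
  the regression mode is the default because it weights information
  across timepoints in the statistically standard way.

### Spike-in calibration

TPM is a within-library relative unit: when the mRNA pool shrinks during a
chase but each library is sequenced to a fixed depth, relative units
inflate over time and *understate* decay. ERCC spike-ins — synthetic RNAs
added at known molar amounts before library preparation — anchor the
conversion. `calibrate_spikeins()` fits attomoles on TPM per library;
`estimate_halflives()` applies the fit per timepoint, averages replicates,
and fits the decay model.

Two numerical choices matter:

* **Through-origin conversion (default).** Zero TPM must mean zero
  molecules. With standards spanning three decades, a free intercept is
  estimated with a wobble of a fraction of an attomole, which dwarfs the
  signal of low-abundance transcripts near 1 amol and biases their fits
  catastrophically. The free-intercept fit remains available
  (`calibration_intercept = TRUE`, and in `calibrate_spikeins()` itself,
  whose default is the conventional free-intercept standard curve).
* **Pseudocount for zero counts.** A count of exactly zero would drop the
  timepoint from the log-linear fit; instead it is replaced by 0.5,
  trading a small bias for a retained timepoint. Non-positive *calibrated*
  abundances are still dropped, and fewer than three surviving timepoints
  flags the fit `insufficient`.
* **Expression filter.** Transcripts with $t=0$ TPM at or below
  `tpm_min = 5` are excluded from medians, mirroring the usual practice of
  not fitting kinetics to transcripts at the detection limit.

### Comparisons and classification

`compare_halflife_distributions()` applies a two-sided Mann–Whitney U test
to the half-lives of transcripts validly fitted in both conditions.
`stratify_lifetime_changes()` summarises the per-gene lifetime ratio
(condition B over A) by m6A status. The stratum summary reports the
**median** ratio as the estimate of a common lifetime change: every
m6A-tagged gene in the simulated knockout shares one true ratio, and for a
common ratio under multiplicative noise the median is the standard robust
estimator — the arithmetic mean of ratios of noisy inverse rates is
dominated by single outliers (values around 9 appear in practice from one
near-zero denominator), and the geometric mean inherits the Jensen bias of
the slower condition.

`classify_halflife_changes()` tests $k_B - k_A$ per transcript with a Wald
z using the two regression standard errors, adjusts with
Benjamini–Hochberg, and labels `decreased`/`increased` only when the
half-life ratio also clears a 1.5-fold threshold. The significance test
for this classification is a package design choice (the analysis family
this mirrors does not specify one); the fold-plus-FDR labelling convention
matches the package's other differential calls.

A display cap of 24 h is applied by `autoplot()` to cumulative
distributions only; medians and tests never see the cap, because rank
statistics are insensitive to the right tail while plots are not.

## 2. Peak dynamics

Inheritance follows the >50% location-overlap rule: a current-stage peak
is inherited when more than half of **its own span** (query-denominated;
the weaker, more inclusive reading) is covered by some previous-stage
peak. A `reciprocal = TRUE` flag imposes the criterion in both directions.
The threshold is a strict inequality. Origin tracing checks earlier stages
in differentiation order and assigns the earliest stage that clears the
overlap rule, so each peak has exactly one origin and origins partition
every stage's peak set. Peaks on transcripts with current-stage TPM ≤ 5
are excluded before labelling; the filter is applied to the current stage
only (configurable), since the previous stage's expression is not what
makes a peak interpretable now. Coordinates are BED-convention 0-based
half-open throughout; overlap is computed on genomic coordinates. Ties
among previous-stage peaks are broken by maximal overlap, then by
coordinate order.

Metagene profiles map each peak **midpoint** (not its full width) onto a
three-unit axis in which the 5'UTR, CDS and 3'UTR each span one unit; the
histogram density integrates to 1. Midpoint mapping is the simplest
faithful rendering of segment-normalised profiles; full-width smearing
would add a bandwidth parameter without changing the qualitative picture.

DRACH scanning matches the degenerate consensus
`[A/G/U][A/G]AC[A/C/U]` with a lookahead regex so overlapping occurrences
are all reported; U and T are interchangeable, and any other character
simply cannot match.

## 3. Windowed peak calling and differential tests

`call_peaks()` is a deliberately simplified caller. Replicates are pooled
per fraction; each 50-nt window is tested with a conditional binomial:
given the window's combined IP + input count, the IP count is
binomial with success probability equal to the IP library's share of the
summed library sizes under no enrichment, and the one-sided tail asks
whether IP overshoots. Peak windows require a normalised IP/input ratio
≥ 1.5 **and** p < 1e-5; adjacent peak windows merge. This reproduces the
thresholds and downstream logic of the established exome-peak callers
without their GC-aware GLM machinery — the caller's calibration guarantee
is therefore with respect to **sampling (Poisson) noise**; like every
count-proportion test it is anticonservative under extra-Poisson
biological dispersion, which is why the type-I simulations in the tests
run at zero dispersion.

`differential_peaks()` tests the change in IP/input enrichment between
conditions with a z-test on the log ratio-of-ratios of pooled normalised
counts (0.5 pseudocounts; the four-count delta-method standard error),
BH-adjusted, at |log2FC| ≥ 1 and adjusted p < 0.05. When peak regions are
supplied, window counts are summed within each peak and the test runs per
peak — the resolution at which callers in this family test, and
substantially more powerful than per-window testing; without peaks it
falls back to per-window tests.

`differential_expression()` and `relative_m6a_level()` share a
plumbing-grade negative-binomial Wald test: median-of-ratios size factors
(total-count fallback when almost no gene is expressed everywhere),
per-gene method-of-moments dispersion floored at 0.01 with **no**
empirical-Bayes shrinkage, delta-method standard errors, BH adjustment.
This is deliberately simpler than the established DE frameworks (no
dispersion shrinkage, no LFC moderation); the tests verify that its fold
changes track an established implementation on planted effects
(correlation > 0.95) while the package keeps its own thresholds:
FC > 1.5 / < 0.67 for expression, input TPM > 5 ∧ FC > 1.5 ∧ adjusted
p < 0.05 for high-confidence m6A genes. Because the relative m6A level is
an *adjusted* fold change, compositional normalisation anchors it at the
median gene: if the majority of genes were methylated, median-of-ratios
would centre the tagged genes at 1 and gene-level m6A status would be
unrecoverable for any such detector — one reason the generator's default
tagged fraction is kept below one half (§5).

`screen_targets()` is the integrative step: candidate demethylase targets
are exactly the genes that both gain methylation and lose expression upon
demethylase loss — a set intersection, reported with both input sizes.

## 4. Assay arithmetic

m6A-RIP-qPCR enrichment normalises target Ct values to a reference gene
(GAPDH-like) in both fractions and reports
$2^{-[(Ct_{t,IP}-Ct_{r,IP})-(Ct_{t,in}-Ct_{r,in})]}$; replicates are
aggregated by geometric mean (arithmetic on the ddCt scale) because
enrichments are multiplicative. The construction makes the calculator
invariant to any machine-wide Ct offset, and the reference gene's own
enrichment is identically 1. Protein-RIP enrichment is the direct
$2^{-[Ct(IP)-Ct(input)]}$. Both assume perfect doubling per cycle;
amplification-efficiency correction is out of scope.

UHPLC-QQQ-MS/MS quantification fits linear standard curves of peak area
on concentration per analyte (transitions 282.1→150.1 for m6A,
268.2→136.1 for A; intercept free per standard-curve convention, a
log-space fit behind a flag) and reports
$100 \times [\mathrm{m6A}]/[\mathrm{A}]$ percent. Concentrations below
the fitted intercept floor at zero with a warning; values outside 10× the
standard range are warned about.

## 5. The synthetic-data generator

`sim_config()` fixes the study conditions; all generators are
deterministic given the seed and restore the caller's RNG state. The
defaults describe the experiment the package is built around:

| parameter | default | why |
|---|---|---|
| `n_stages`, `stages` | 4: hPSC, DE, PP, hILO | the differentiation axis |
| `n_replicates` | 2 | m6A-seq/RNA-seq biological replicates; decay-course analyses in the tests use 3, the usual stability-assay design |
| `depth` | 1e6 | desk-scale library size: large enough for asymptotics, small enough for seconds-scale tests |
| `peak_rate` | 1 /gene | keeps the m6A-tagged fraction at a given stage near 40%: compositional (median-of-ratios) normalisation anchors on unmethylated genes only while the majority is unmethylated, and the 0–1-peak bin stays the most populated |
| `peak_width` | 200 nt | at least fragment-sized, the scale at which MeRIP peaks are called |
| `ip_enrichment` | 10× | typical MeRIP antibody enrichment at peaks; with ~200-nt peaks this yields gene-level IP/input folds of ~1.5–4, i.e. methylation visible at gene level without being trivial |
| `nb_dispersion` | 0.02 | gene-wise NB dispersion typical of isogenic cultured-cell biological replicates (same-batch differentiations); ~0.05+ describes heterogeneous tissues/cohorts and would put a 22% CV floor under every count |
| `halflife_median_h`, `halflife_sigma` | 8 h, 0.5 | log-normal transcriptome-wide stability, median in the mammalian mRNA range |
| `m6a_lifetime_reduction` | 0.38 | the average lifetime shortening of methylated transcripts upon demethylase loss that the package is designed to recover |
| `n_spikeins` | 24 over 3 decades (0.1–100 amol) | exercises the calibration across a realistic dynamic range |
| `ct_noise_sd` | 0.1 cycles | routine qPCR technical noise |

Noise model: gene counts are negative-binomial with variance
$\mu + \alpha\mu^2$ (biological replicates differ); **spike-in counts are
Poisson**, because spike-ins are technical standards added at fixed
amounts — giving them biological dispersion would inject a coherent
error of ~0.025/h into the calibration's time trend (a third of the
median decay rate) that no amount of gene-level replication could remove.
IP libraries are *not* renormalised to a fixed depth, so the expected
IP/input ratio inside a peak equals the configured enrichment exactly;
consequently IP library totals exceed input totals, as they do in
practice before depth normalisation.

Planted perturbations used by the tests and the acceptance script apply a
4-fold methylation gain and a 4-fold expression drop to 200 tagged genes
with TPM > 50. Three deliberate choices: perturbation of a *subset* (10%)
of the transcriptome, because perturbing the majority breaks compositional
normalisation and corresponds to no realistic study; 4-fold methylation
gain, because a 2-fold gain sits exactly on the |log2FC| ≥ 1 decision
boundary where any test's power is 50% by construction; and a TPM > 50
planting floor, because at 1e6 reads over 2000 genes a TPM-5 gene
receives ~2–3 reads — the desk-scale depth compresses the count scale
~30-fold relative to a real library, and TPM > 50 is the stratum with the
detectability the usual TPM > 5 filter implies at real depth.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level artefacts (GC and length bias,
mapping ambiguity, PCR duplicates), fragment-level coverage shape within
peaks, isoform mixtures (one transcript per gene, single-exon), antibody
background structure beyond a uniform fold, multi-phasic decay, and
batch effects. Peak occupancy follows a birth-stage-plus-retention chain,
which produces inheritance structure but accumulates peaks towards later
stages rather than reproducing any particular empirical trend in
inherited fractions.

## 6. Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run everything at desk scale:
2000 genes for estimator exactness and noisy-median recovery (3 decay
replicates), 500 genes per stratum for the lifetime-reduction recovery,
1000 random peaks × 4 stages against the brute-force interval oracle,
~1e4 null windows for caller calibration, 5000 genes for the DE null, and
2000 genes for the planted screen. All randomness flows from a single
seed; generators restore the RNG state so call order does not matter.

## 7. Known limitations

* The stability window (0–3 h) identifies half-lives around a few hours
  well; for transcripts much more stable than the window the rate is near
  zero, the `increasing` exclusion truncates the estimate distribution,
  and surviving estimates of very stable transcripts are biased towards
  faster decay. Estimated medians remain within a few percent under the
  default conditions, but per-gene estimates in the long-lived tail
  should be treated as lower bounds.
* The conditional-binomial caller's error control is exact only under
  Poisson sampling; under strong biological overdispersion its p-values
  are optimistic, as for any count-proportion window test.
* The NB Wald test has no dispersion shrinkage; with two replicates its
  dispersion estimates are noisy and the floor (0.01) does real work.
* Relative m6A levels are compositional: they are calibrated against the
  median gene and lose meaning if most genes are methylated.
* The qPCR calculators assume 100% amplification efficiency.
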