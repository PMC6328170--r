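---
title: "Spike-in QC and two-step pooling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in QC and two-step pooling: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echopool)
```

# The problem

Miniaturized mNGS library preparation processes up to 384 samples at
nanoliter scale on an acoustic liquid handler. Two quantitative questions
follow the wet-lab work. First, was each library prepared faithfully, and
how much RNA actually went in? Clinical samples span orders of magnitude of
input and sub-nanogram amounts defeat fluorometric quantification. Second,
how should hundreds of libraries of unequal concentration be combined so
that each receives an equal share of a flow cell?

`echopool` answers both with the statistics of the spike-in controls and of
the pooling procedure itself.

# Spike-in dose response and mass back-calculation

A known mass of ERCC control RNA (default 25 pg) is added to every sample.
The controls are 92 transcripts of varying length laid on a concentration
ladder spanning six decades. Two properties are exploited:

* **Linearity.** Reads per transcript should be proportional to spike-in
  concentration. `fit_dose_response()` regresses
  `log10(normalized count)` on `log10(concentration)` by ordinary least
  squares over the *detected* (nonzero) transcripts. A slope near 1 and a
  high R² indicate uniform amplification; departures flag preparation
  failure.
* **Mass ratio.** Spike-in reads and sample reads compete for the
  sequencer in proportion to their masses, so
  `total_mass = spike_mass * total_reads / spike_reads`
  (`back_calculate_mass()`). The estimator is scale-invariant in the read
  counts and exact in the noiseless limit; under multinomial sampling it is
  the ratio of a constant to a binomial count, consistent as depth grows.

Numerical choices:

* Zero-count transcripts are **excluded** from the regression rather than
  pseudocounted, and reported via `n_detected`. A pseudocount would impose
  an arbitrary floor exactly where the ladder probes sensitivity.
* The default normalization is counts per million total reads, which needs
  no external quantification; counts per picogram of input is available
  when a mass estimate exists. Whether published dose-response figures were
  length-normalized is not always stated, so neither behaviour is asserted
  as canonical; the regression always uses the concentration column as
  given.
* At least three detected transcripts are required for a fit; fewer is an
  error, not a degenerate fit.
* `sample_mass = total_mass - spike_mass` is reported separately from the
  total: at nanogram inputs the spike is negligible and the two are often
  conflated, but at the low inputs this protocol targets the 25 pg spike is
  not.

# Two-step pooling

Let `f_i` be library *i*'s fraction of assigned reads in an equal-volume
pilot pool. Because pilot volumes were equal, `f_i` is proportional to the
library's molar concentration, so dispensing volume `v_i ∝ 1/f_i`
equalizes molar contributions — and hence, in expectation, read shares —
in the re-pool.

The dispenser imposes hard constraints: every transfer is an integer
multiple of the droplet quantum (25 nL) within a practical range
(160–3800 nL). `plan_equimolar()` therefore:

1. computes raw volumes `v_i ∝ 1/f_i`, anchored (default `anchor_min`)
   so the most-abundant library sits at the minimum attainable volume —
   this maximizes retained material — or scaled to a requested total
   (`fixed_total`);
2. quantizes to the nearest droplet multiple, ties rounding up, recording
   the pre-quantization request in `quantized_from`;
3. clips to the attainable range, flagging `clipped_low`/`clipped_high`.

Since the printed 160 nL minimum is not itself a multiple of 25 nL, the
attainable range is quantized inward: volumes lie between the smallest
multiple of the quantum at or above `v_min` and the largest at or below
`v_max`. Both published constraints then hold simultaneously for every
emitted volume.

Degenerate inputs produce flagged plans, not failures: a library with zero
pilot reads has no usable abundance estimate, receives the maximum volume,
and is flagged — low-count libraries are exactly the ones that show the
greatest re-pool variability, so dropping them silently would be worse.

`predict_fractions()` closes the loop before sequencing: predicted deep-run
shares are `f_i v_i`, renormalized. For an unclipped equimolar plan the
prediction is uniform up to a quantization bound of
`n * quantum / total_volume`; for the equal-volume plan it reproduces the
input fractions identically.

Success is judged by `compare_variance()`: the ratio of share variances
before and after re-pooling against the F distribution with
`(n_a − 1, n_b − 1)` degrees of freedom. The test is **two-sided** (the
direction of the change is an empirical claim, not an assumption), and the
summary form `list(sd =, n =)` is accepted so published standard
deviations can be tested directly:

```{r}
compare_variance(list(sd = 0.125, n = 265), list(sd = 0.087, n = 265))
```

# Detection metrics

* `rpm()` — unique reads per million total; the denominator (pre- or
  post-filter totals) is whatever the caller supplies, making the
  convention explicit.
* `downsample_counts()` — depth-matching by sampling **without
  replacement** (sequential hypergeometric draws), so each category's
  downsampled count has the exact multivariate-hypergeometric marginal and
  never exceeds its input.
* `coverage_stats()` — breadth is the percentage of positions with depth
  ≥ 1; mean and SD of depth are computed over **all** positions, zeros
  included, with the population (divide-by-N) SD, since the depth vector is
  the complete population of positions, not a sample. The
  covered-positions-only mean is reported as a secondary field because both
  conventions appear in practice.
* `rank_correlation()` — Spearman's ρ with average ranks for ties and the
  large-sample p-value; constant vectors are an error because rank
  correlation is undefined for them.

# What the synthetic-data generator emulates

`sim_config()` defaults encode the study conditions the planner targets:

| parameter | default | rationale |
|---|---|---|
| `n_libraries` | 265 | pool size of the reference experiment |
| `molarity_cv` | 0.33 | ratio of the published pilot share SD to its mean (0.125/0.377) |
| `pilot_depth` | 4.5e6 | shallow calibration run |
| `deep_depth` | 1e7 | desk-scale deep run; production flow cells are orders of magnitude deeper, and depth is configuration, not a constant |
| `dispense_cv` | 0.05 | relative volume error per acoustic transfer |
| `ercc_spike_mass_pg` | 25 | spike mass per sample |
| `mean_input_mass_pg` | 500 | mean true input; the sub-nanogram regime the protocol targets |
| `seed` | 1 | every stochastic stage derives its stream from it |

The noise model is deliberately minimal: lognormal library molarities
(mean 1, configured CV), multiplicative Gaussian dispensing error applied
at the re-pool dispense, and multinomial read assignment at fixed total
depth. Per-library spike-in read totals are binomial at the mass-ratio
share. This is the smallest model that reproduces the qualitative two-step
result — a significant variance tightening — and makes every consuming
module testable.

What it does **not** emulate: read-level structure (no FASTQ, error
profiles, duplicates), index hopping or unassigned reads, GC/length bias
beyond the optional concentration-by-length weighting of spike-in counts,
pilot-dispense error (the pilot is treated as exactly equal volumes; only
the re-pool dispense is perturbed), and library degradation over time.
Consequently the simulated post-re-pool spread (~0.02 percentage points at
default settings) is *tighter* than spreads observed on real instruments
(~0.09): real residual variance includes error sources the model omits and
that published work does not decompose. Passing tests therefore show the
planner's algebra, constraint handling, and statistical machinery are
correct — not that any particular real-world residual spread will be
achieved.

`gen_ercc_reference()` lays concentrations on an exact geometric ladder
spanning `log10_span` decades with lengths uniform on 250–2000 bases. The
bundled `inst/extdata/ercc_mix1_synthetic.tsv` is such a synthetic table
written in the vendor file layout (it is *not* the vendor's values); real
concentration files load through the same `read_ercc_table()` path.

# Problem sizes and determinism

The test suite runs the full 265-library experiment at pilot depth 4.5e6
and deep depth 1e7, repeated over 100 seeds for the variance-tightening
property and 100 seeds for the 500 pg mass-recovery property; the
downsampling distributional check uses 10,000 seeded draws. These sizes
give Monte-Carlo standard errors well below the margins being asserted
while keeping the whole suite in seconds. All randomness flows through
explicit seed arguments (`withr::with_seed`); no function mutates the
caller's RNG state, and identical seeds give bit-identical results.

# Known limitations

* Source-plate dead volume is not accounted for: a plan can request more
  total volume than a well can supply.
* The re-pool uses raw read fractions; refining per-library concentration
  estimates with the spike-in fits before re-pooling is possible in
  principle but not implemented, since the evidence that it helps is
  ambiguous.
* The F test assumes approximately normal shares; with 265 libraries and
  shares far from 0 and 1 this is mild, but for small pools a
  permutation-based comparison would be preferable.
* `read_depth_profile()` consumes per-base depth tables; extracting depth
  from alignments is left to standard tools (`samtools depth`) upstream.
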