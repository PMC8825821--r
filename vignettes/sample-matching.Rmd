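---
title: "Genotype-based sample matching for multiplexed proteomics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-based sample matching for multiplexed proteomics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smapkit)
```

## The inference problem

A multiplexed TMT batch measures up to 11 samples in one MS run; each
channel's reporter-ion intensity quantifies one sample. A variant peptide —
one whose sequence carries a non-synonymous coding variant — is only
produced by samples carrying the alternate allele, so across the channels of
one batch its intensity pattern encodes the samples' genotypes at that SNP:
background for non-carriers (AA), roughly half dose for heterozygotes (AB),
full dose for mutant homozygotes (BB). `smapkit` turns those patterns into
per-channel genotype calls and matches them against a reference panel to
verify or correct each channel's identity.

Three modelling assumptions underlie the whole pipeline:

1. **Dose proportionality.** Within one peptide, relative reporter
   intensity is monotone in allele dosage. Everything downstream uses only
   ranks and min-max positions, so any monotone distortion of the intensity
   scale is tolerated.
2. **Noise floor.** Non-carrier channels measure background whose log2
   intensity is approximately Gaussian, separable from carrier signal by a
   two-component mixture.
3. **Independent SNPs.** Concordance scores treat SNPs as exchangeable and
   independent; linkage disequilibrium is ignored.

## Preprocessing

Raw reporter intensities pass through a fixed chain
(`preprocess_batch()`): isotope impurity correction (solving
`T · P = O` for the true signal `T` given the reagent leakage matrix `P`),
trimmed-median loading normalization, and log2 transform. The chain is
order-sensitive: impurity correction must happen on the linear scale before
any rescaling, and scaling to `[0, 1]` happens last, after noise filtering.

Numerical choices:

* **Zero intensities** are legitimate (true absence) but have no finite
  log; they are floored at the batch's smallest positive intensity and
  flagged `floor_imputed`. This keeps zero-signal peptides usable without
  inventing sub-noise values.
* **Trim fraction** for the loading median defaults to 0.1. The median
  itself is robust; trimming matters when missingness is asymmetric across
  channels.
* **Constant peptides** (max = min after scaling) carry no genotype signal
  and are dropped rather than mapped to 0.5, which would fabricate
  heterozygote evidence.
* **Mean-centering across channels** is subsumed by min-max scaling and is
  not a separate step; scaling operates on log2 values directly.
* **Internal-control channels** participate in impurity correction and
  loading normalization and, by default, in the per-peptide min/max: a
  pooled control is an average over carriers and non-carriers, so it sits
  mid-range and does not distort the extremes. `scale_batch(include_controls
  = FALSE)` exists for designs where the control is not a balanced pool.

## The noise model

`fit_two_gaussian_em()` fits the distribution of per-peptide minimum
signals (`peptide_min_signal()`). The minimum across channels is the right
statistic: for any peptide whose SNP segregates in the batch, the weakest
channel is almost surely a non-carrier, so the minima trace the noise
floor. The reference fit used throughout the tests and simulator has noise
N(14.06, 1.39²) and signal N(18.22, 1.29²) on the log2 scale; the derived
cutoff `noise mean + 1.5 · SD = 16.145` coincides, for that fit, with
`signal mean − 1.5 · SD = 16.285` to within 0.14 log2 units, which is what
makes 1.5 a natural multiplier: it is the symmetric separation point of the
two modes.

EM details: initialization splits the data at the median and uses each
side's moments — deterministic, no random restarts in the common case;
component SDs are floored at `1e-3` of the data range to prevent collapse
onto a point; the log-likelihood trace is kept and is asserted
non-decreasing in the tests; components are relabeled by mean so `noise` is
always the lower one. Convergence is `|Δ loglik| < 1e-8` with a 500
iteration cap; non-convergence is reported, not hidden.

Three peptide filters follow (`filter_peptides()`), each with a tunable
threshold in `filter_config()`:

| parameter | default | meaning |
|---|---|---|
| `cutoff_multiplier` | 1.5 | SDs above the noise mean for the minimum-signal cutoff (log2 units) |
| `snr_min` | 3 | linear-scale mean(signal side) / mean(noise side), split at the cutoff |
| `maf_min` | 0.01 | panel minor-allele frequency must exceed this |

The S/N ratio needs a concrete definition because "signal-to-noise" alone
is ambiguous for an 11-value row: we use the ratio of linear-scale means on
either side of the noise cutoff, which contrasts the BB-like channels
against the AA-like channels. Filtering is applied per peptide; a
per-SNP-aggregate alternative would couple peptides of unequal quality.
The mixture can be fit per batch (default) or once on pooled minima
(`cutoff_scope = "global"` in `run_match()`) when batches share an
acquisition protocol.

## Genotype calling

`infer_genotypes_quartile()` implements the quartile rule. With all three
classes present in the panel, the scaled values are split at their own
25th/75th percentiles; with exactly two classes, at 0.5. Choices that the
rule's verbal description leaves open, fixed here:

* **Quantile convention:** linear interpolation between order statistics
  (R's type 7). Because data points are compared against an interpolated
  quantile of themselves, three-class calls depend only on ranks — the
  property tests verify invariance under strictly increasing transforms.
* **Boundary ties:** a value exactly at either quartile is called AB (the
  interquartile class is closed on both ends).
* **Two-class generalization:** the 0.5 cutoff separates whichever two
  classes the panel shows, ordered by dosage (AA < AB < BB); 0.5 itself
  goes to the higher class. Panels showing `{AA, AB}` or `{AB, BB}` are
  handled by the same rule.
* **Monomorphic SNPs** (one class in the panel) are excluded: they cannot
  discriminate identities.
* **Multiple peptides per SNP** are combined per channel by majority vote;
  ties become missing rather than arbitrarily resolved.

The quartile rule assumes the batch's channels spread over the three
classes in roughly 25/50/25 proportion. Under Hardy–Weinberg class
frequencies this is generally false (AA usually dominates), so per-call
accuracy is imperfect by construction — errors concentrate at the quartile
boundaries. Identity matching tolerates this because the errors are
near-symmetric across candidates: what must hold is only that the true
candidate's concordance stays above every impostor's.

## Scoring and assignment

`cscore()` counts exact call matches over jointly non-missing positions.
Two scales are provided. Fraction mode (default) is the literal "fraction
matched" definition, in `[0, 1]`, threshold 0.80. Weighted mode credits a
matched AA/AB/BB with weight 1/2/3 and divides by positions compared —
matching a rare mutant homozygote is stronger identity evidence than
matching the ubiquitous AA — giving scores on a > 1 scale with threshold
1.50. The weighting acknowledges score magnitudes in prior practice without
claiming to reproduce an undocumented formula; both modes are exposed and
threshold defaults are scoped per mode.

Design choices:

* `min_compared = 20`: a score computed on fewer than 20 shared SNPs is
  reported as missing. Tiny overlaps produce spuriously perfect scores.
* A tie for best candidate forces ΔCscore = 0 and status `unassignable`:
  identity cannot be claimed when two references explain the data equally
  well (the duplicated-reference test pins this).
* A single candidate gets ΔCscore = 1 — there is no runner-up to confuse
  it with — a degenerate case fixed by convention.
* Every channel is scored against the full panel, not just its batch's
  labels, so cross-batch swaps are detectable.
* Thresholds gate *assignment*, not *ranking*: recovery statistics in the
  simulation are rank-based and threshold-free.

`classify_swaps()` reduces corrections to a directed graph (label →
assigned identity) and classifies weakly connected components: a 2-cycle is
a reciprocal swap, a longer cycle is cyclic, anything open is one-way. With
`n` nodes and `m` edges in a component, `m = n` identifies a single cycle
and `m < n` an open chain; corrected samples each contribute exactly one
edge, so the decomposition is exhaustive.

## The simulator

Two generators make the pipeline testable without external data.

`generate_genotype_matrix()` draws an HWE panel: per SNP, MAF ~ uniform on
[0.05, 0.5], genotypes i.i.d. with frequencies ((1−p)², 2p(1−p), p²). The
default 420 × 500 grid is the benchmark scale used throughout.

`simulate_quant_batch()` emits one variant-peptide row per SNP with log2
intensities drawn from the genotype's mode — noise N(14.06, 1.39²) for AA,
signal N(18.22, 1.29²) for BB, the midpoint mode for AB — plus per-channel
loading biases (log2-normal, SD 0.2) that the preprocessing chain must
remove, and an optional pooled-control channel carrying the linear-scale
channel mean. What it deliberately does **not** emulate: peptide
identification errors, PSM-level replication with correlated noise,
missingness mechanisms (values are complete unless injected), allelic
expression imbalance, batch-specific channel failures, or LD between SNPs.
Passing end-to-end tests therefore demonstrates the statistical machinery —
scaling, mixture fitting, filtering, calling, scoring — not robustness to
every failure mode of real acquisitions.

### The shuffle and its replacement rule

`shuffle_genotypes()` corrupts a chosen sample: estimate each SNP's class
frequencies across the panel, select `round(α/100 · n_snps)` distinct
positions, replace each with a draw from that SNP's frequencies. Two
replacement policies are provided, and the distinction matters:

* **`"frequency"` (default):** the draw comes from the full class
  distribution and may coincide with the current call. The shuffled
  sample's concordance with its true identity then decays from 1 toward
  the panel's *baseline* concordance — the expected agreement between two
  unrelated HWE samples, `E[Σ_g p_g²] ≈ 0.49` under the default MAF
  distribution — rather than to zero. This is the right null for "how much
  corruption can identification survive": even a fully shuffled sample
  looks like a random cohort member, not like an adversarial anti-match.
  Under this policy, identity recovery on the 420 × 500 benchmark stays
  ≥ 95% up to roughly α = 80 (20% intact genotypes) and collapses shortly
  after — the margin `(1 − α/100)(1 − baseline)` sinks into the noise of
  the best impostor around there.
* **`"different_class"`:** the draw is restricted to classes other than
  the current call (renormalized), making α the exact realized error rate:
  exactly `round(α/100 · n_snps)` positions differ, and the true-identity
  concordance is exactly `1 − α/100`. This variant gives deterministic
  error-rate control for unit tests and calibration, but as a mix-up null
  it is unrealistically hostile (true concordance drops below baseline
  once α exceeds ~50, so no method could rank the true sample first).

Positions whose SNP is monomorphic in the panel cannot change under the
different-class rule and are excluded from selection there, with the count
made up from the remaining positions.

`run_recovery_curve()` wires shuffle and scoring together; `recovered`
means the true sample's score is strictly the unique maximum. Replicates
default to 50 per α.

## Problem sizes and runtime

The test suite exercises: EM recovery at n = 500 and 5,000; brute-force
score oracles on ≤ 6 samples × ≤ 20 SNPs (exhaustive pairwise counting);
the recovery benchmark at 420 × 500 with 200 replicates at α = 80; and 20
seeded end-to-end batches of 11 channels × 300 SNPs at the reference noise
parameters (measured channel-to-identity recovery: 100%). The acceptance
script runs the full α = 10…100 grid at 50 replicates per α, about 4,500
pipeline evaluations, in under a minute thanks to integer-coded vectorized
scoring. These sizes were chosen as the smallest at which the binomial
error of the reported rates is comfortably below the decision margins.

## Known limitations

* Per-call genotype accuracy under realistic noise is modest (~50–60%
  concordance on HWE batches); identification works through score margins,
  not per-call correctness, and fraction-mode thresholds must be
  calibrated to the data regime — internal-control channels are the
  instrument for that (their ΔCscore shows what "matches no one" looks
  like).
* A batch whose channels lack class diversity at a SNP (e.g. all carriers)
  miscalibrates the quartile split for that peptide; the dosage prior
  mitigates only the cases the *panel* shows as two-class.
* Heterozygote-only panels (`{AB}` monomorphic) are excluded, and `{AA,
  AB}` vs `{AB, BB}` two-class splits assume the 0.5 midpoint, which is
  not validated against expression-imbalanced loci (imprinting,
  dominant/recessive expression).
* The simulator's HWE-uniform MAF spectrum is idealized; panels dominated
  by rare variants raise the baseline concordance and shrink score
  margins, so recovery curves on real cohorts can sit below the synthetic
  benchmark.
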