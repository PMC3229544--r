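---
title: "Probe-level rank-based differential expression: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-level rank-based differential expression: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Most expression-array pipelines summarize the several probes of a probe set
into one expression value per gene before testing. probeRank takes the
opposite route: it keeps every probe as an independent witness and asks, per
transcript, whether an improbable number of its probes tell the same
differential-expression story. The method rests on two assumptions about
oligonucleotide arrays: a probe's signal reflects the abundance of targets it
is sequence-complementary to, and probes that report the same target
faithfully should share a differential-expression profile across conditions.

The workflow:

1. **Alignment.** Every 25-nt probe is mapped to the transcriptome; a hit
   requires an ungapped exact match of at least 22 nt between the probe and
   the transcript's minus strand (equivalently, between the probe's reverse
   complement and the plus strand). Probes with no hit are discarded; the
   retained count is `T`.
2. **Rank normalization.** Within each array, intensities are replaced by
   relative ranks (mid-ranks for ties, divided by `T`), making the signal
   distribution identical on every array by construction. The per-array sum
   of relative ranks is exactly `(T + 1) / 2`, ties or not — a cheap
   invariant the tests exploit.
3. **Exact rank tests.** For each of seven planned two-group comparisons,
   each probe's relative ranks are tested with an exact Mann-Whitney test:
   both one-sided tail probabilities of the rank-sum statistic are computed
   by full enumeration over all `choose(n1 + n2, n1)` group assignments of
   the pooled mid-ranks, each tail including the observed statistic. Group
   sizes here are 3-5 arrays, so enumeration is exact and instantaneous, and
   it remains exact under ties — where the classical null tables (and
   `wilcox.test`'s exact mode) give up.
4. **Expression strings.** Each comparison contributes a letter: `H` if the
   upper tail is at most 0.05 (higher in the experimental group), `L` for
   the lower tail, `E` otherwise. The threshold is inclusive (p = 0.05
   fires). Concatenated in plan order the letters form the probe's
   expression string, e.g. `"EELEELL"`; probes are clustered by exact string
   identity.
5. **Attribution.** For transcript `X` and profile cluster `A`, with `X^A`
   of the transcript's `X^T` probes inside the cluster of size `A` among `T`
   retained probes, the chance of being mistaken when attributing profile
   `A` to `X` is the hypergeometric upper tail
   `pAX = sum_{i = X^A}^{min(A, X^T)} hg(i; X^T, T - X^T, A)`.
   All (transcript, profile) records with at least one supporting probe are
   tested — except the all-`E` profile, which encodes "nothing happened" —
   and Benjamini-Hochberg adjustment is applied over the whole record
   family. Transcripts with an adjusted p strictly below 0.05 are called
   differentially expressed with the profile's letters.

Downstream, the package derives per-comparison DE lists with effect sizes
(the mean relative-rank difference of the supporting probes between the two
groups, bounded in (-1, 1)), reliability rankings of transcripts DE in both
genotypes by the ascending product of their adjusted p-values, and
genotype-contrast sets (differential already between naive animals;
consistently differential at both hypoxia timepoints but not in naive mice;
differential at exactly one timepoint). Gene-list over-representation uses
the same upper-tail construction on gene counts
(`sum of dhyper densities from the observed intersection upward`), and a
delta-delta-Ct utility converts qPCR cycle thresholds to fold changes with
amplification efficiency exactly 2.

## The experimental design

The default design carries six (genotype, timepoint) groups — naive
wild-type (n = 3), naive knockout (n = 5), 90-min hypoxia wild-type and
knockout (n = 5 each), 24-h hypoxia wild-type (n = 5) and knockout (n = 4) —
and the canonical comparison plan orders the seven comparisons as: knockout
vs wild-type at naive, 90 min and 24 h (positions 1-3), hypoxic wild-type vs
naive wild-type at 90 min and 24 h (positions 4-5), and the same time course
within the knockout (positions 6-7). `H` always means higher in the
experimental member (the knockout, or the hypoxic group). The string order
itself is a package convention — the underlying study lists the comparisons
without fixing an order — and is configurable through the plan argument.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | inclusive per-comparison letter threshold and strict DE threshold on adjusted p |
| `min_match` | 22 nt | minimal ungapped probe-transcript match |
| `probes_per_transcript` | 9 | simulator tiling density |
| `baseline_log_mean`, `baseline_log_sd` | 6, 1 | per-probe log-intensity affinity intercept |
| `noise_sd` | 0.25 | log-scale measurement noise (0.25 x the affinity spread) |

Because the statistics are rank-based, `baseline_log_mean` is pure scale and
irrelevant to every result; `baseline_log_sd` and `noise_sd` matter only
through their ratio, which controls how often noise reorders probes within
an array.

## What the simulator emulates — and what it does not

The generator produces random transcriptomes, probes as reverse complements
of distinct transcript windows (so the minus-strand alignment rule is
load-bearing), decoy probes rejection-sampled until the aligner finds no
22-nt match (exercising the discard pathway), optional multi-mapping probes
created by duplicating a window into a second transcript, and intensities
from a log-additive model: per-probe affinity intercept, plus
`ln(2) * log2FC` on the arrays of each planted effect's experimental group,
plus Gaussian log-scale noise. The underlying study gives no generative
model for intensities — it only ranks them — so this model is a declared
stand-in chosen for two properties: fluorescence behaves multiplicatively,
and a rank-based method only sees the ordering, so conclusions from passing
tests transfer to any monotone re-parameterization of the intensity scale.

The simulator does **not** emulate CEL-file structure, spatial artifacts,
background or cross-hybridization, probe-sequence affinity biases (GC
content), or correlated noise between arrays processed together. Passing
recovery tests therefore demonstrate that the statistical machinery is
implemented correctly and is well calibrated under clean multiplicative
noise — not that the method overcomes every artifact of real array data.

One consequence of ranking deserves emphasis: ranks are compositional.
Planting a fold change on one group's arrays displaces the ranks of *other*
probes on those arrays, and in the noiseless limit even a one-position
displacement is perfectly reproducible across arrays and thus significant
under an exact test. Two visible effects: (a) a transcript planted only in
the wild-type time course (positions 4-5) also separates the genotype
comparisons at the shifted timepoints, so its noiseless end-to-end string is
`ELLHHEE`, not `EEEHHEE`; (b) in small noiseless simulations the displaced
bystander probes form large co-moving clusters that dilute the planted
transcript's attribution. Both effects are properties of the model, not
bugs; realistic noise scatters the bystanders and they vanish at scale.

## Numerical and design choices

* **Exact matching.** "Ungapped 22-nt alignment" is operationalized as exact
  contiguous identity; near-matches with mismatches are not chased. This
  makes the aligner deterministic and verifiable against a brute-force
  window-scan oracle, which is all its probe-counting role requires.
  Coordinates are 1-based inclusive on the plus strand; per (probe,
  transcript) pair one hit is kept — maximal length, leftmost on ties —
  since only membership feeds the statistics.
* **Tests on post-normalization ranks.** The pipeline normalizes first and
  tests the relative ranks, following the published step order literally.
  Absent cross-array ties the letters are identical to testing raw
  intensities.
* **Exact tails, both including the observed point.** Hence
  `p_upper + p_lower = 1 + P(W = observed)` without ties, and `H`/`L` can
  never co-fire at any `alpha < 0.5`. Mid-ranks are half-integers, so all
  tail comparisons are exact in floating point.
* **All-`E` exclusion.** The all-`E` cluster typically holds most probes;
  testing it would only ever "attribute" the absence of differential
  expression while dominating the BH family. Only non-null profiles are
  tested, matching a readout that reports DE transcripts only.
* **Global BH family.** All emitted records are adjusted together; the
  source material does not describe stratification by profile, and a global
  family is the conservative reading.
* **Conflict resolution.** A transcript can carry significant records with
  opposite letters at one position (multi-mapping or split probes). DE
  membership is resolved to the minimal-adjusted-p record and the transcript
  is flagged `ambiguous`, so downstream lists are deterministic while the
  conflict stays visible.
* **Determinism.** Seeds are explicit parameters; the generator never
  touches global RNG state (it saves and restores `.Random.seed`). All
  output tables print floats at 6 significant digits, so repeated runs are
  byte-identical.
* **Degenerate inputs.** Empty transcript sets, all-tied groups
  (`p_upper = p_lower = 1`), zero aligned probes (hard abort), `X^A = 0`
  (tail = 1) and single-record BH (identity) are all defined and tested.

## Validation problem sizes

The test suite validates the exact statistics against enumeration oracles
(all count tuples with `T <= 12` for the attribution tail, universes up to
15 genes for enrichment, 200 random inputs per design group-size pair for
the rank test, 1000 random vectors for BH), and the pipeline end-to-end on
simulated experiments of 200 transcripts x 9 probes at the study's group
sizes: ten null runs for the false-discovery bound and ten runs with 20
transcripts planted at |log2FC| = 2 under `noise_sd = 0.25` for recovery,
plus a noiseless run for direction errors. These sizes give stable
estimates while keeping a full validation run in the low minutes on one
core; they are the package's reference conditions, and
`scripts/acceptance.R` re-runs exactly these computations.

## Known limitations

* Transcript-level attribution only; no gene-level aggregation across
  transcripts, no isoform deconvolution of multi-mapping probes (a probe
  supports every transcript it hits).
* The aligner is exact-match; probes hybridizing with mismatches are
  invisible to it.
* The enrichment universe size is a required user input — it depends
  entirely on the annotation in use and is deliberately not hard-coded.
* The delta-delta-Ct utility assumes amplification efficiency 2 exactly.
* CEL files are not parsed; users convert upstream and supply the
  probe-by-array TSV.
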