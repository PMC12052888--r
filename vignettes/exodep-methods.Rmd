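---
title: "Methods: the conjunction gate for differential spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the conjunction gate for differential spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exodep)
```

## The procedure

exodep implements the decision procedure used in label-free comparisons of
RPE-exosome proteomes between myopic and non-myopic eyes: a small two-group
design (4 vs 7 biological replicates in the motivating study) measured by
spectral counting, with a three-criterion conjunction deciding differential
expression.

**Evidence filtering.** Peptide records are kept when the sequence is
strictly longer than 5 amino acids, the precursor is not singly charged
(MH+1), and the peptide probability strictly exceeds 0.80. Proteins are
kept with at least 2 distinct retained peptide sequences, protein
probability strictly above 0.99, and protein FDR strictly below 0.01. The
spectral count is the number of retained records per protein per sample —
total spectra, not distinct peptides, which is the standard spectral-count
unit; distinct peptides enter only the two-peptide rule. Whether the
two-peptide rule counts per sample or across the experiment is genuinely
ambiguous; exodep counts across the experiment, the more permissive and
more common reading, and exposes the threshold if the stricter one is
wanted.

**Normalization (N-SC).** Each sample column is scaled by the ratio of the
mean library size to its own total, so all column totals equalize and the
grand total is conserved. This is the common Scaffold-style total-count
normalization; no exact formula is published for the original data, so
conservation and idempotence were the selection criteria. Length-based
(NSAF) normalization is deliberately out of scope.

**The three criteria.** For a protein with group means $\mu_1, \mu_2$ and
sample SDs ($n-1$ denominator) $\delta_1, \delta_2$ of N-SC:

1. SAM-like weight $W = (\mu_1-\mu_2)/(\delta_1-\delta_2)$, passing when
   $|W| > 0.8$;
2. Welch unequal-variance $t$, one tail taken in the direction of the
   observed mean difference (so $p \le 0.5$), passing when $p < 0.05$;
3. signed fold change $\mathrm{FC}$, the ratio $\mu_1/\mu_2$ reported as
   the negative reciprocal when below one, passing when
   $|\mathrm{FC}| \ge 1.5$ (calibratable on $[1.5, 2.0]$).

All three must pass. Proteins detected in only one group (by default, at
least one nonzero sample; the minimum is configurable) are classified as
group-unique, skip the gate entirely, and are excluded from the
multiple-testing family. Benjamini–Hochberg adjusted p-values are computed
across the tested proteins and reported for the volcano representation;
the gate itself uses the raw p, as published.

## Design choices where the source was open

**The W denominator.** The printed formula divides by the *difference* of
the group SDs, which is sign-unstable and explodes when the two spreads are
similar; the accompanying prose ("the SD decreases") reads like a single
spread quantity, suggesting a typo for a sum. exodep implements the printed
difference form as the default and offers `w_variant = "sum"`. Neither is
asserted to be the intended formula. The choice matters for error control:
the difference form passes a large fraction of null proteins (its
denominator is frequently near zero), so the conjunction's null call rate
is dominated by the other two criteria, while the sum form is genuinely
selective — the test suite verifies that the sum-variant conjunction keeps
the per-protein null call rate under 0.05, and the acceptance checks
measure the default gate's null rate honestly (it lands above 0.05; see
below).

**The one-tailed direction.** No fixed alternative is stated, so the tail
follows the observed difference, making the test two-direction-capable with
$p \le 0.5$. The analytic consequence: at cutoff 0.05 the t-criterion alone
passes 10% of null proteins (5% per direction). Under the conjunction rule
the overall false-call rate is below that, but whether it reaches 0.05
depends on how selective the other two criteria are — with the as-printed W
it does not, which is reported as measured rather than adjusted away.

**Fold-change calibration.** "Inner-quartile data from control experiments
using ln-ln plots" is implemented as: proteins whose mean ln abundance lies
within [Q1, Q3] form the calibration set (`trim = "ratio"` gives the
alternate reading); the Pearson correlation of the ln-ln scatter is
reported; the threshold is the smallest grid point in [1.5, 2.0] whose
symmetric ratio band covers the target fraction (default 0.99) of the set,
clamped at 2.0 with a warning when unreachable. Zeros are excluded from the
logs and counted. Which samples form the control pair is unstated; a seeded
random halving of one group stands in (`split_control_pairs()`).

**Pseudocount.** Default 0: one-sided zero means are presence/absence
information and are handled structurally as group-unique, not forced into
a ratio. A pseudocount of 0.5 is available for exploratory fold changes on
sparse data.

**Report ranking.** The original "top 40" volcano selection used a
proprietary tool; exodep ranks by adjusted p and then |log2 FC|, a
documented divergence.

## The synthetic-study generator

`sim_config()` encodes the study conditions: 506 proteins, 48 unique to
group A and 41 to group B, 4 vs 7 samples, and 79/70 planted up/down
effects (the published up-/down-regulated counts). Counts are negative
binomial — the standard overdispersed model for spectral counts — with
log-normal per-protein baselines, log-normal per-sample size factors, and
planted effects multiplying the group-A mean by $2^{\mathrm{lfc}}$ with
$|\mathrm{lfc}|$ uniform on [0.8, 2.0], deliberately straddling the
1.5-fold gate. The remaining defaults are not published anywhere and were
chosen once as field-realistic for Scaffold-style counts: baseline
`log`-mean $\log 25$ (median expected count 25), `log`-SD 1.2 (abundances
spanning roughly three decades), dispersion $\phi = 0.15$ (biological
replicate CV approaching $\sqrt{\phi} \approx 0.39$ at high abundance),
size-factor `log`-SD 0.15.

Presence classes are exact by construction: a unique-A protein's group-B
cells are structural zeros, and any protein whose sampled row would violate
its class (an all-zero group for a common protein, or no nonzero own-group
count for a unique protein) is redrawn from its own deterministic
substream, with a bounded retry count. This makes the Venn partition of a
simulated study deterministic given the configuration, which is what the
structural acceptance checks rely on. One RNG stream is seeded from
`config$seed` and per-protein substream seeds derive from it, so studies
are bit-identical under a fixed config.

What the generator does *not* emulate: peptide-to-protein inference
ambiguity, shared peptides, correlated proteins (complex stoichiometry),
batch structure, or intensity-dependent missingness. Tests passing on
simulated studies therefore demonstrate that the pipeline implements its
stated decision rules and recovers effects under clean overdispersed
counts — not that the biological conclusions of any particular real data
set would replicate.

## Numerical conventions and degenerate inputs

* W with $|\delta_1-\delta_2| < 10^{-12}$ (or the sum analogue) is flagged
  `NaN` with a warning and fails the gate; a zero numerator wins and gives
  $W = 0$.
* Welch p with two zero-variance groups is 0.5 when the means agree
  (t = 0 convention) and 0 when they differ.
* Both group means zero is an error for the fold change; such proteins
  cannot arise from assembled evidence.
* BH adjustment is the standard step-up, clipped to 1, original order
  restored; a single-protein family leaves p unchanged.
* PCA uses `log2(N-SC + 1)`, per-protein centring, exact SVD; component
  signs are fixed by making each component's largest-magnitude loading
  positive. Heatmap ordering z-scores rows and uses average-linkage
  (UPGMA) agglomeration; `hclust` tie behaviour is deterministic for fixed
  input order.
* Calibration coverage uses a $10^{-12}$ tolerance on the band edge so a
  ratio exactly at the threshold counts as covered.

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations to be
informative yet quick: 200 effect-free studies of 150 proteins for the
null operating characteristic (30,000 null decisions, binomial SE about
0.13 percentage points), and three pooled 300-protein studies with 240
planted effects each — baselines fixed at 100 expected counts — for the
slope and power measurements. The oracle comparisons use 1,000 random
Welch pairs, 50 random hypergeometric configurations, 10-row agglomeration
problems, and 50 × 11 PCA inputs.

## Known limitations

* The conjunction gate with the as-printed difference-denominator W does
  not control the per-protein null call rate at 0.05 under these study
  conditions; the acceptance output reports the measured rate. Use
  `w_variant = "sum"` if error control at the t-test's nominal level is
  the priority.
* Empirical FDR of the default gate on overdispersed 4-vs-7 counts is
  substantial (the worked example in the README shows ~22% against ground
  truth); the procedure predates moderated-variance methods and no
  empirical-Bayes shrinkage is applied, by design.
* Protein FDR is consumed as supplied by the upstream tool, never
  recomputed from decoys.
* Calibration cannot reproduce the original control data's correlation;
  those sample-level controls are unpublished.
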