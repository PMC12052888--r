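# exodep

Differential spectral-count proteomics for two-group label-free
experiments, built around the analysis used to compare retinal pigment
epithelium (RPE) exosome proteomes between myopic and non-myopic eyes.
It is aimed at proteomics analysts who have a Scaffold-style evidence
export or a protein × sample spectral-count matrix for a small two-group
design and want the full published decision procedure — not just a t-test —
as reproducible, tested R functions.

## The method

Starting from peptide evidence, records are retained only when the peptide
is longer than 5 residues, is not a singly-charged (MH+1) precursor, and has
peptide probability > 80%; proteins are kept with ≥ 2 distinct peptides,
protein probability > 99.0%, and protein FDR < 1%. Spectral counts are
normalized between samples to the mean library size (N-SC). For each
protein with group means μ₁, μ₂ and sample SDs δ₁, δ₂:

* **SAM-like weight** W = (μ₁ − μ₂)/(δ₁ − δ₂), gated at |W| > 0.8
  (a sign-stable variant with denominator δ₁ + δ₂ is available);
* **Welch t-test**, single tail in the direction of the observed
  difference, gated at p < 0.05 (Benjamini–Hochberg adjusted values are
  reported alongside);
* **signed fold change** FC = μ₁/μ₂ reported as −μ₂/μ₁ when the ratio is
  below 1 (so |FC| ≥ 1 always), gated at |FC| ≥ 1.5, where the 1.5–2.0
  threshold can be calibrated empirically from inner-quartile ln-ln control
  comparisons.

A protein is called differential only when **all three** criteria pass.
Proteins detected in only one group are classified structurally as
group-unique (the Venn partition) rather than tested. Downstream helpers
provide hypergeometric over-representation analysis against GMT sets,
volcano/PCA/heatmap tables, and a negative-binomial study simulator with
known ground truth for benchmarking the whole gate.

## Worked example

```r
library(exodep)

study <- simulate_counts(sim_config(seed = 1))   # 506 proteins, 4 vs 7
dep   <- run_dep(study$counts, study$samples)
glance(dep)
#>   n_proteins  n_up n_down  n_ns n_unique_a n_unique_b w_cut p_cut fc_cut
#> 1        506    54     89   274         48         41   0.8  0.05    1.5

venn_partition(detect_presence(study$counts, study$samples))
#> Venn partition: 506 proteins = 417 common + 48 only-A + 41 only-B

evaluate_recovery(dep, study)
#>     tpr   fdr venn_exact fc_bias fc_rmse
#> 1 0.745 0.224 TRUE        -0.191   0.549
```

The `glance()` row says the gate called 54 proteins up and 89 down out of
506, with 48/41 classified as group-unique — the unique counts match the
planted structural zeros exactly (hence `venn_exact = TRUE`). The recovery
row scores the calls against the simulator's ground truth: 74.5% of truly
differential proteins were recovered at an empirical FDR of 22% under the
default 4-vs-7, overdispersed-count conditions. The strongest calls look
like:

```r
head(dplyr::arrange(tidy(dep), p), 3)
#>   protein_id   mu_a  mu_b     w          p       q    fc status
#> 1 P0119      154.    46.9 -7.14 0.00000496 0.00119  3.28 up
#> 2 P0208       15.2   56.9  7.55 0.00000569 0.00119 -3.74 down
#> 3 P0187       60.8  159.   9.95 0.0000294  0.00409 -2.61 down
```

`autoplot(dep)` draws the volcano, `autoplot(pca_scores(...))` the score
plot, and `run_pipeline()` chains every stage into TSV/JSON artifacts with
a digest manifest.

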