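# delimkit

Integrative molecular species delimitation for single-locus barcode data,
written for the workflow used in integrative taxonomy of species-rich,
under-described faunas (the motivating case is 16S rRNA barcoding of
Amazonian *Scinax* treefrogs): delimit lineages with two independent
molecular algorithms, reconcile their disagreements under an explicit
conservatism rule, confront the units with morphological, bioacoustic and
prior-reference evidence, and quantify how much of the observed richness
is undescribed.

## What it computes

* **K2P distances** (`k2p_matrix()`): Kimura two-parameter distances
  `d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)` with pairwise deletion, per-pair
  comparable-site counts and explicit saturation flags.
* **Barcode-gap delimitation** (`abgd_delimit()`): detects the first gap
  in the ranked distance distribution that exceeds the local gap scale,
  beyond a prior intraspecific divergence `prior_P` (default 3%), splits
  by single linkage at the gap midpoint, and recurses into the resulting
  units (default 10 rounds, relative gap width 1.0).
* **Single-threshold GMYC** (`gmyc_fit()`): on an ultrametric gene tree,
  fits a threshold age `T` separating Yule-like speciation branching
  (rate `lambda_S k^p_S`) from within-species coalescence (rate
  `lambda_C sum_j [n_j(n_j-1)]^p_C`), maximizing
  `sum_i (ln b_i - b_i x_i)` over inter-event intervals; the one-process
  null is nested, and a chi-square likelihood-ratio test (default df = 3)
  decides significance. `upgma_tree()` supplies an ultrametric fallback
  when no chronogram is available.
* **Reconciliation and classification** (`reconcile_partitions()`,
  `classify_units()`): conflicts between the two delimitations resolve to
  the side with fewer units unless morphology, calls or a prior
  multi-locus reference supports the split; final units are classified as
  nominal species (NS), confirmed candidate species (CCS), unconfirmed
  candidate species (UCS) or deep conspecific lineages (DCL).
* **Richness statistics** (`richness_stats()`): with `U = |CCS| + |UCS|`
  undescribed units and `D` described species,
  `percent_undescribed = 100U/(U+D)` and `percent_increase = 100U/D`,
  rounded half-up.
* **Synthetic data with ground truth** (`make_dataset()`): Yule species
  tree, multispecies-coalescent gene tree, K2P sequence evolution and
  stochastic evidence tables, for end-to-end validation.

## Worked example

```r
library(delimkit)

# simulated 8-species dataset, 4 samples each, divergences >= 3.2 My
ds <- make_dataset(sim_config(seed = 7, min_depth = 3.2))
m <- k2p_matrix(ds$alignment)
m
#> K2P distance matrix: 32 sequences, 0 saturated pair(s)
#>   finite distances: 0.0000 - 0.3280

abgd_delimit(m)
#> Delimitation: 32 sequences in 8 unit(s)

gmyc_fit(ds$gene_tree)
#> Single-threshold GMYC fit
#>   threshold T_hat : 2.26701
#>   entities        : 8 (8 cluster(s), 0 singleton(s))
#>   logL alt / null : 58.0687 / 40.0583
#>   LR = 36.0209, df = 3, p = 7.412e-08
```

Both methods recover the 8 simulated species exactly: the distance
distribution has a clean barcode gap (intraspecific distances well below
the 3% prior, interspecific above it), and the fitted GMYC threshold
(2.27 My) falls between the within-species coalescent depths (~0.2 My)
and the shallowest species divergence (>= 3.2 My).

The bundled `inst/extdata/scinax_pmir` fixture encodes a published
regional study: two input delimitations (13 distance-based vs 12
tree-based units) plus the morphological/bioacoustic evidence table.

```r
fx <- system.file("extdata", "scinax_pmir", package = "delimkit")
ev <- read_evidence_csv(file.path(fx, "evidence_pairs.csv"),
                        file.path(fx, "lineages.csv"))
cons <- reconcile_partitions(
  read_partition_csv(file.path(fx, "partition_abgd.csv")),
  read_partition_csv(file.path(fx, "partition_gmyc.csv")), ev)
cl <- classify_units(cons, ev)
cl
#> OTU classification: 12 unit(s) -- 2 NS, 7 CCS, 2 UCS, 1 DCL

richness_stats(cl, baseline_D = 2)
#> Richness: U = 9 undescribed vs D = 2 described
#>   82% of total richness undescribed; +450% over described
```

The nine CCS+UCS units against the two regional nominal species give 82%
of the regional richness undescribed (a 450% increase); against the wider
list of 21 ungrouped Amazonian congeners (`baseline_D = 21`) the same
units give 30% and 43%.

`run_pipeline()` orchestrates all stages from a config list or YAML file
and writes a canonical JSON report; `inst/cli/delimkit.R` exposes the
same stages as `simulate` / `distances` / `abgd` / `gmyc` / `classify` /
`run` subcommands for shell use.

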