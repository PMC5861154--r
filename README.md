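# refstab

Reference-gene stability evaluation for qRT-PCR.

Relative quantification by qRT-PCR reports a target gene's expression
relative to one or more *reference* (housekeeping) genes, so every result
is only as trustworthy as the references' own stability. Classic mammalian
references (*actb*, *gapdh*, *18s*) are frequently unstable in
non-mammalian species, across tissues and developmental stages, and under
environmental challenges such as herbicide exposure or salinity shifts —
so candidates must be validated per species and experimental design.
`refstab` is for molecular physiologists and ecotoxicologists doing
exactly that validation: it takes a table of cycle-threshold (Ct) values
with sample metadata and ranks candidate reference genes by expression
stability.

## What it computes

Four established stability estimators, each exposed as its own function
and fed by the same complete-case gene × sample Ct block:

* **Comparative ΔCt** — for each gene pair (j,k), the sample SD of
  `ΔCt = Ct_j − Ct_k`; a gene's value is its mean pairwise SD
  (`dct_stability`).
* **geNorm** — relative quantities `q = E^(minCt − Ct)`; the M-value
  `M_j = mean_k SD(log2 q_j/q_k)`, stepwise exclusion of the highest-M
  gene (final pair tied at ranks 1.5/1.5), and the pairwise variation
  `V(n/n+1)` between normalisation factors built from the top n vs n+1
  genes (`genorm_m`, `genorm_stepwise`, `genorm_pairwise_variation`).
* **NormFinder-type model-based value** — sample-centred Ct decomposed
  into intragroup variance `σ²_ig` (with a method-of-moments correction
  for the centring) and shrunken intergroup deviations `d̃_ig`, combined
  as `ρ_i = mean_g(|d̃_ig| + σ_ig/√n_g)`; also the best two-gene
  combination via pseudo-gene averaging (`normfinder_stability`,
  `normfinder_best_pair`).
* **BestKeeper** — per-gene Ct descriptives (geometric/arithmetic mean,
  extremes, SD/MAD dispersion, CV%), the per-sample geometric-mean-of-Ct
  index, and each gene's Pearson `r` with the index (`bestkeeper`).

Per-method ranks (ties averaged) are combined into a consensus by the
geometric mean of ranks — lowest geometric mean = most stable
(`aggregate_consensus`). `run_full_analysis` drives the whole thing over
a stratified multi-factor design (treatment × age × tissue) and
`write_report` emits per-stratum TSV tables plus a machine-readable
summary. A synthetic Ct generator with known ground-truth stability
(`silverside_design_config`, `generate_ct_data`, `recovery_eval`)
supports validation, and `fit_standard_curve` handles dilution-series
efficiency QC (`E(%) = (10^(−1/slope) − 1)·100`).

## Worked example

```r
library(refstab)

sim <- generate_ct_data(silverside_design_config(seed = 1))
sim
#> synthetic Ct dataset: 8 genes x 108 samples (2592 wells), seed 1
#> true stability ordering (best to worst): h3a > ef1a > actb > eif3g > 18s > gapdh > tuba > atp1a

report <- run_full_analysis(sim$ct, sim$meta, verbose = FALSE)
report$pooled$consensus
#> consensus ranking (geometric mean of per-method ranks; lower = more stable)
#>   gene rank_dct rank_genorm rank_normfinder rank_bestkeeper geomean final_rank
#>    h3a        1         1.5               6               1    1.73          1
#>   ef1a        2         1.5               3               2    2.06          2
#>  eif3g        3         4.0               1               3    2.45          3
#>   actb        4         3.0               2               4    3.13          4
#>    18s        5         5.0               4               5    4.73          5
#>   tuba        6         6.0               5               6    5.73          6
#>  gapdh        7         7.0               7               7    7.00          7
#>  atp1a        8         8.0               8               8    8.00          8
```

The simulated design is 3 treatments × 3 ages × 3 fish × 4 tissues in
technical triplicate. The consensus puts the quiet histone gene (`h3a`)
first and the treatment-responsive ion pump (`atp1a`) last, matching the
injected truth; `gapdh`/`tuba`, given inflated biological variance, land
just above it. Each row shows the gene's rank under every method and the
geometric mean that orders the final column.

```r
recovery_eval(20, silverside_design_config(seed = 1))
#> recovery over 20 seeds:
#>   least-stable gene ranked last: 95.0%
#>   most-stable gene in top 2:     95.0%
#>   mean Spearman(truth, consensus): 0.959
```

A command-line wrapper covers the same workflow
(`exec/refstab analyze|simulate|benchmark`); try
`Rscript exec/refstab analyze --simulate --seed 7 --out-dir results`.

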