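---
title: "Evaluating qRT-PCR reference genes: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating qRT-PCR reference genes: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Relative quantification by qRT-PCR divides a target gene's signal by that
of one or more reference ("housekeeping") genes, so the whole measurement
inherits the stability of the references. Classic mammalian references
(*actb*, *gapdh*, *18s*) are often unstable in other taxa and under
environmental challenge, so candidates must be validated per species,
tissue, developmental stage and condition. `refstab` implements the four
estimators that dominate this literature plus their standard consensus, a
stratified driver for multi-factor designs, and a synthetic Ct generator
with known ground truth so the whole pipeline can be exercised and
validated end to end.

All methods operate on cycle-threshold (Ct) values. Ct is the PCR cycle at
which fluorescence crosses a detection threshold, so it is a *logarithmic*
measure of template abundance: one cycle is one doubling at perfect
efficiency. That motivates two conventions used throughout:

* noise models are Gaussian on the Ct scale (log-normal expression);
* relative quantities are `E^(minCt - Ct)` with `E` the per-gene
  amplification factor, `E = 2` being perfect doubling.

## The four estimators

**Comparative delta-Ct** (`dct_stability`). For every unordered gene pair
the per-sample difference `Ct_j - Ct_k` is formed; its sample SD (n−1)
measures how much the pair's ratio wobbles. A gene's stability value is
its mean pairwise SD. Differences cancel per-sample constants, so the
statistic ignores global mRNA-content/loading shifts.

**geNorm** (`genorm_m`, `genorm_stepwise`, `genorm_pairwise_variation`).
Quantities `q = E^(minCt - Ct)` are formed per gene; `M_j` is the
arithmetic mean over partners `k` of `SD(log2(q_j/q_k))`. Stepwise
exclusion removes the highest-M gene until two remain; those two cannot be
separated by the method and share ranks 1–2 (tie-averaged to 1.5 each).
The pairwise variation `V(n/n+1)` is the SD of
`log2(NF_n/NF_{n+1})` where `NF_n` is the per-sample geometric mean of the
top-n quantities; it indicates how many references suffice. With exactly
two genes and `E = 2`, `M` reduces algebraically to the delta-Ct pairwise
SD — a useful cross-method identity that the test suite checks exactly.

**NormFinder-type model-based value** (`normfinder_stability`,
`normfinder_best_pair`). The published descriptions of this method are
prose plus software; the decomposition committed here is spelled out in
one place (`R/normfinder.R`) so it can be audited:

1. sample-centre: `z = Ct - mean_genes(Ct)` per sample;
2. per gene `i` and group `g`: group mean `zbar_ig`, residual variance
   `s2_ig` (n−1);
3. intragroup variance with a method-of-moments correction for the
   centring, floored at zero:
   `sigma2_ig = max(0, (s2_ig - mean_i(s2_ig)/I) / (1 - 2/I))`, `I` =
   number of genes (hence the `I >= 3` requirement);
4. intergroup deviation `d_ig = zbar_ig - mean_g(zbar_ig)` (unweighted
   over groups);
5. empirical shrinkage
   `dtilde = d * gamma2_g / (gamma2_g + sigma2_ig/n_g)` with
   `gamma2_g = max(0, var_i(d_ig) - mean_i(sigma2_ig/n_g))` (`var_i` uses
   the n−1 denominator — a committed choice);
6. stability `rho_i = mean_g(|dtilde_ig| + sigma_ig/sqrt(n_g))`; with a
   single group `rho_i = sigma_ig`.

The best two-gene combination averages two genes' centred values into a
pseudo-gene, re-estimates its `d` and `sigma2` empirically with the full
set's correction and shrinkage constants, and reports the pair minimising
`rho`. Opposite treatment responses cancel in the average, so a pair can
beat both members.

**BestKeeper** (`bestkeeper`). Descriptive statistics of raw Ct per gene,
the per-sample geometric mean of Ct across candidates (the *index*), and
each gene's Pearson correlation with the index (two-sided p from the t
transform, n−2 df). Two rankings: ascending dispersion (conservative;
default consensus feed) or descending `|r|`. Because BestKeeper works on
raw Ct it is deliberately sensitive to global per-sample shifts — that is
part of the method, not a defect to engineer away.

**Consensus** (`rank_genes`, `aggregate_consensus`). Each method's values
are ranked (ties averaged everywhere, so ranks always sum to n(n+1)/2) and
each gene receives the geometric mean of its per-method ranks; lowest
geometric mean is the consensus best. Tables print the geometric mean to
2 decimals while machine-readable output keeps full precision.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `efficiency` | 2.0 | per-cycle amplification factor per gene; override from dilution-series fits via `efficiency_factor()` |
| `ct_range` | 5–40 cycles | plausible Ct window; violations warn, never error |
| `max_missing_fraction` | 0.2 | validation threshold for flagging genes/samples |
| `range_threshold` | 0.5 cycles | technical-replicate range above which `outlier_drop` removes the well farthest from the median |
| `genorm_mean` | arithmetic | partner-mean dialect for M; a geometric-mean dialect exists for compatibility with descriptions that phrase M as a geometric mean of SDs |
| `bestkeeper_dispersion` | sd | `sd` (sample SD) or `mad` (mean absolute deviation around the mean, the original tool's dialect); both always reported |
| `consensus_bestkeeper` | sd | which BestKeeper ranking feeds the consensus |
| `min_samples` | 3 | smallest stratum analysed |

Missing data are handled by complete-case analysis per stratum: every
estimator needs a full gene-by-sample block, and imputation would inject
assumptions none of the methods make. Dropped-sample counts are logged.

## The stratified driver

`run_full_analysis()` mirrors the standard design of exposure studies:
one stratifying factor (treatment) crossed with secondary factors (age,
tissue). Per treatment it analyses the treatment-level data and each
age level (pooled over tissues) and tissue level (pooled over ages),
plus a pooled all-data consensus. NormFinder grouping inside a stratum
uses the first residual factor with at least two levels of three or more
complete samples (tissue inside a treatment-by-age stratum, age inside a
treatment-by-tissue stratum, treatment for the pooled data); with no such
factor the single-group model is used, and every choice is logged.

## The synthetic generator and what it does (not) emulate

`generate_ct_data()` draws
`Ct = mu_g + delta_{g,t} + a_s + b_{g,s} + e_{g,s,w}` with per-sample
mRNA-content effects `a_s` (drawn per animal-by-tissue sample, since each
tissue is an independent RT reaction), per-gene biological noise
`b`, and technical well noise `e`. The default
`silverside_design_config()` emulates a 3-treatment (control, herbicide,
seawater) by 3-age by 3-fish by 4-tissue design (108 samples) in
technical triplicate: `sigma_sample = 0.8`, `sigma_tech = 0.15` cycles;
per-gene SDs make the histone gene the quietest (0.2), the classic
workhorses intermediate (0.3–0.5), *gapdh*/*tuba* noisy (0.8); and the
ion-pump gene *atp1a* carries +1.5/+2.0-cycle shifts under the two
exposures, playing the treatment-responsive control. Gene baselines
(12–23 cycles, ribosomal RNA most abundant) and effect sizes are
field-realistic defaults chosen once; they are configuration, not claims
about any particular dataset. The injected ground-truth instability score
is `sqrt(sigma_g^2 + var_t(delta))`, so the implied true ordering has the
histone best and the ion pump worst.

What the generator does **not** emulate: amplification curves and Cq
calling, inter-plate batch effects, efficiency heterogeneity, pipetting
dropouts, or age-specific expression shifts (a hook exists via the
`shifts` matrix). Passing recovery tests therefore show that the pipeline
recovers orderings under its own generative assumptions — not that any
particular field dataset satisfies those assumptions.

`recovery_eval()` judges recovery on the pooled cross-treatment consensus
(NormFinder grouped by treatment), because the truth score includes the
treatment shifts and only the pooled analysis sees them all. Over 100
simulated datasets the consensus puts the truth-worst gene last and the
truth-best gene in the top two in roughly 99% of runs, with a mean
truth-to-consensus Spearman correlation near 0.96 (these are the
quantities `scripts/acceptance.R` recomputes).

## Numerical choices and degenerate inputs

* Pairwise SD matrices are computed from the gene-level covariance matrix
  (`Var(x - y) = Var x + Var y - 2 Cov`); tiny negative values from
  rounding are clamped to zero before the square root.
* geNorm stepwise ties on the highest M are broken by excluding the
  lexicographically last gene; every tie-break is logged. Fully tied
  inputs are annotated as such.
* A constant gene (or constant index) makes the BestKeeper correlation
  undefined; `|r|` is set to 0 with a warning so rankings stay total.
* All lower-is-stable statistics are exactly zero on data whose defining
  variation vanishes (the NormFinder intragroup estimate floors at zero).
* Ranks use average-tie ranking everywhere, including the geNorm final
  pair (1.5/1.5), keeping aggregation order-independent.
* All simulation randomness flows from one integer seed; identical
  config + seed reproduces outputs byte-for-byte.

## Known limitations

* The BestKeeper index is the geometric mean of **raw Ct** (the method's
  canonical definition, and what the worked examples in the documentation
  compute). Consequently the index correlation `r` is *not* invariant to
  adding a constant to one gene's Ct: such a shift perturbs the index
  non-affinely and moves `r` at the 1e-3 to 1e-1 level on typical data.
  The dispersion statistics (SD, MAD) are row-shift invariant, which is
  one more reason the dispersion ranking is the default consensus feed.
  An exactly shift-invariant index would have to average on the
  expression scale (equivalently, use the arithmetic mean of Ct), which
  would no longer be BestKeeper.
* With few genes, weak group shifts and substantial noise, the
  model-based shrinkage floors its intergroup variance estimate
  `gamma2` at zero and group deviations are shrunk away: in a 6-gene,
  2-group-of-10 simulation with a +1-cycle shift against 1-cycle
  triplicate technical noise, the shifted gene tops the ranking in only
  about three quarters of runs (the unshrunk variant reaches ~95%). This
  conservatism is inherent to the committed decomposition; detection is
  essentially certain at realistic technical noise (0.15 cycles) or
  larger shifts, as the test suite demonstrates.
* Consensus geometric means depend on the tie policy of the per-method
  rankings; published consensus values computed with undocumented tie
  policies cannot generally be reproduced number-for-number, so orderings
  — not magnitudes — are the meaningful comparison surface.
* Problem sizes used by the checks: 8 genes by 20–108 samples, 50–100
  simulated datasets per recovery estimate.

## Worked example

```{r, eval = FALSE}
library(refstab)

sim <- generate_ct_data(silverside_design_config(seed = 1))
report <- run_full_analysis(sim$ct, sim$meta)
report$pooled$consensus           # geometric-mean consensus, all data
write_report(report, "results")   # per-stratum TSVs + summary.json

recovery_eval(100, silverside_design_config(seed = 1))
```
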