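# pmadbench

Exhaustive benchmarking of intensity-processing **analysis chains** for
label-free (DIA/SWATH-MS) proteomics, scored by replicate precision.

An analysis chain is an ordered triple of processing methods applied to a
protein-by-sample intensity matrix: a **transformation** (Box-Cox, cube
root, log, power, or none), a **normalization** (auto scaling, cyclic
loess, EigenMS, lowess, mean, median, MAD, Pareto, probabilistic
quotient, quantile, robust linear regression, total ion current, trimmed
mean of M-values, VSN, Z-score, or none) and a **missing-value
imputation** (background, Bayesian PCA, censored half-minimum, KNN,
iterative SVD, zero, or none). With the identity option at every stage
the registry spans 5 × 16 × 7 = **560 chains**, each labelled by
three-letter codes, e.g. `LOG-MED-NON`.

Every chain is scored on every dataset by the **pooled intragroup median
absolute deviation (PMAD)**: for protein *i* in replicate group *g*,

```
MAD_ig = median_j | x_ij − median_j' (x_ij') |        (observed j in g)
PMAD   = mean over groups g of ( mean over proteins i of MAD_ig )
```

with no 1.4826 consistency factor. Lower PMAD = tighter replicates =
better technical precision; PMAD ≤ 0.3 is conventionally *superior*,
≤ 0.7 *good*, > 0.7 *poor*. Chains with a PMAD on every dataset form
per-chain performance vectors that are Ward-clustered (Euclidean distance
on log10 PMAD) and cut into partitions ordered best to worst
(`A1, A2, A3, B, C, D` at the default k = 6); chains that are good
everywhere — individually or via their partition — are flagged as
**consistently well-performed analysis chains (CWPACs)**, and per-method
contribution tables show which transformations and normalizations drive
consistent precision.

A seeded synthetic-data module generates two-group SWATH-like benchmark
suites (log-normal abundances, per-sample scaling biases, log-scale
noise, left-censored + random missingness) so the entire pipeline runs
and is tested without any external data.

## Worked example

```r
library(pmadbench)

suite  <- generate_benchmark_suite(n_datasets = 3, n_proteins = 300, seed = 42)
chains <- c("LOG-TIC-KNN", "LOG-MED-NON", "POW-TMM-ZER",
            "CUB-QUA-SVD", "NON-NON-NON")
sw <- sweep_chains(suite, chains, chain_params(seed = 42))
a  <- assess_chains(sw)
dplyr::filter(a, dataset_id == "D1")
#>   chain              pmad log10_pmad category  rank
#> 1 LOG-TIC-KNN       0.400     -0.398 good         2
#> 2 LOG-MED-NON       0.124     -0.908 superior     1
#> 3 POW-TMM-ZER      52.3        1.72  poor         4
#> 4 CUB-QUA-SVD       3.34       0.524 poor         3
#> 5 NON-NON-NON 2022848.         6.31  poor         5
```

On this dataset log transformation followed by median normalization
leaves a pooled replicate MAD of 0.124 (superior precision), while the
untreated chain's PMAD of ~2 × 10^6 simply reflects the raw intensity
scale — the ranking is what matters. Clustering the three-dataset
performance vectors separates the untreated chain from everything else:

```r
pm    <- performance_matrix(a)
parts <- cut_partitions(ward_cluster(pm$matrix), k = 2, pmad_matrix = pm$matrix)
parts
#> <chain_partitions> 5 chains in 2 partitions (best -> worst)
#>   partition n_chains mean_log10_pmad
#> 1 P1               4           0.276
#> 2 P2               1           6.36
identify_cwpacs(parts, a)
#>   chain       partition strict partition_based frac_good
#> 1 CUB-QUA-SVD P1        FALSE  FALSE                 0.5
#> 2 LOG-MED-NON P1        TRUE   FALSE                 0.5
#> 3 LOG-TIC-KNN P1        TRUE   FALSE                 0.5
#> ...
```

`LOG-MED-NON` and `LOG-TIC-KNN` are strict CWPACs (PMAD ≤ 0.7 on every
dataset). `run_pipeline()` wires the whole workflow together (sweep →
assessment → clustering → CWPACs → report files including a Newick
dendrogram), `autoplot()` / `plot_chain_ranking()` /
`plot_method_contribution()` draw the standard figures, and
`tidy()` / `glance()` give broom-style summaries. A thin command-line
wrapper lives at `inst/scripts/run-benchmark.R`.

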