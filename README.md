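# scle — single-cell landscape entropy for critical-transition detection

`scle` locates the **critical (pre-deteriorated) stage** along an ordered
series of single-cell subpopulations — for example the pseudotime clusters of
an epithelial deterioration trajectory — and extracts the
**dynamic network biomarker (DNB)** gene module that drives the signal. It is
aimed at systems biologists who have (i) a gene × cell expression matrix,
(ii) a cell → stage assignment with a known stage order, and (iii) a
protein–protein interaction (PPI) edge list such as a STRING export.

## The statistic

DNB theory says that just before an abrupt transition a small, tightly
connected group of genes starts to fluctuate collectively: its standard
deviation (SD_in) and internal correlation (PCC_in) rise sharply while its
correlation with the rest of the network (PCC_out) falls. `scle` detects this
through an entropy-weighted dispersion score on PPI ego networks.

For gene *g* with *Q* first-order neighbours in the template network, at
stage *t*:

    H_t(g) = [ -1/ln(Q) * Σ_i p_i(t) ln p_i(t) ] × SD(g(t))

where the weights `p_i(t)` are the absolute Pearson correlations
`|PCC(g, neighbour_i)|` across the stage's cells, normalized to sum to one.
The stage score `H_t` is the sum of the `R = ⌈top_fraction × M⌉` largest
local scores (default: the top 5 % of the `M` network genes). `H_t` spikes
at the critical stage; the call is the argmax, reported with its fold change
and an optional stage-permutation p-value. The DNB module is the set of
genes composing the spike; its first-order neighbours are then scanned for
post-critical trend reversal ("flip-flop") with a two-slope statistic.

## Worked example

The package bundles a seeded simulator that plants a 20-gene DNB module at
stage 4 of a 6-stage series (200 genes, 60 cells per stage):

```r
library(scle)

sim    <- simulate_transition(simulation_config(seed = 1, neighbor_reversal = TRUE))
series <- assemble_stage_series(normalize_log1p(sim$expression),
                                sim$labels, sim$stage_order)
fit    <- scle(series, sim$network)
fit
#> Single-cell landscape entropy profile
#>   200 network genes, 6 stages, R = 10 (top 5.0%)
#>   stage scores H_t:
#>      S1      S2      S3      S4      S5      S6
#>  5.4524  5.4450  5.4717 13.0896  5.3457  5.4180
#>   critical stage: S4 (fold change 2.39)
```

The score is flat (≈ 5.4) away from the transition and jumps 2.4-fold at the
planted stage. A stage-label permutation test calibrates the peak:

```r
scle_permutation_test(fit, series, sim$network, B = 99, seed = 1)$p.value
#> [1] 0.01
```

Extracting the module at the module-sized cut (`top_fraction = 0.1`, i.e.
R = 20) recovers the planted genes exactly, and the reversal scan puts the
generated flip-flop neighbour far ahead of the noise floor:

```r
dnb <- identify_dnb_genes(scle(series, sim$network, top_fraction = 0.1))
mean(sim$truth$planted_module %in% dnb)
#> [1] 1

rv <- reversal_scan(series, find_dnb_neighbors(sim$network, dnb),
                    fit$critical_stage)
head(rv[, c("gene", "slope_before", "slope_after", "reversal_score", "reversed")], 3)
#>   gene slope_before slope_after reversal_score reversed
#>  G0001   0.61422944 -0.94880461    0.582783724     TRUE
#>  G0039  -0.04783673  0.11285640    0.005398681     TRUE
#>  G0089   0.07236743 -0.07401645    0.005356380     TRUE
```

`dnb_report()` bundles the module, its neighbours and the per-stage
SD_in / PCC_in / PCC_out curves; `run_scle_pipeline()` is the file-to-file
version (TSV/MatrixMarket in, TSV + JSON manifest out), also exposed as a
command line under `inst/cli/scle-cli.R` with `simulate`, `run`, `score`
and `report` subcommands.

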