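# scbcsec

Analysis of multiplexed single-cell secretomic data from antibody-barcode
microchamber chips (SCBC), for labs quantifying how many proteins individual
T cells secrete, at what rate, and how that changes with priming conditions.

An SCBC isolates cells in ~1500 nanoliter microchambers, each carrying an
11-stripe antibody barcode that captures secreted proteins over an on-chip
window T₂. The analysis starts at the merged chamber table (cell count +
per-analyte fluorescence per chamber) and proceeds:

1. **Background** — per analyte, per chip, from 0-cell chambers: Gaussian
   fit (moments or 20-bin histogram least squares), Kolmogorov–Smirnov
   diagnostic, optional linear device-gradient correction estimated from
   0-cell chambers and applied chip-wide.
2. **Secretion calling** — a single cell secretes analyte *a* when its raw
   intensity exceeds the cutoff **μₐ + 2σₐ** (strict); net signal is
   max(raw − μₐ, 0), and rates are net / T₂ (AU/h).
3. **Polyfunctionality** — with *k* the number of called analytes per cell,
   the polyfunctional strength index per stratum is
   **pSI_k = (n_k / n) · mean_k(Σ called rates)** and
   pSI_total = Σ_{k≥1} pSI_k, with an exact per-analyte decomposition.
4. **Cohort comparison** — per-analyte and total fold changes of ensemble
   mean rates between conditions (T₁ priming sweeps, density sweeps),
   secretion composition, and PCA/k-means embedding of single-cell
   profiles.

Because raw chip data for the motivating studies is not publicly deposited,
the package includes a calibrated synthetic chip generator
(`generate_chip()`, scenario constructors) that reproduces the occupancy,
background, and condition-dependent secretion structure the pipeline
assumes; every stage is tested end to end against it. Calibration inverts
the multiplexed false-positive floor of the 2σ rule (~22% of silent cells
fire ≥ 1 of 11 analytes by chance), so the *measured* headline fractions
match their targets — see the methods vignette
(`vignettes/scbc-methods.Rmd`).

## Worked example

```r
library(scbcsec)

chips <- generate_cohort(ot1_tetramer_scenario(), seed = 1)   # T1 sweep, T = 24 h
res   <- lapply(chips, run_chip_pipeline)                     # gradient -> background -> calls -> pSI
cmp   <- compare_conditions(lapply(res, function(r) r$profile))
print(cmp)
```

```
<scbc_summary>
 condition T1_hours T2_hours n_cells fraction_secreting fraction_polyfunctional
   T1_0.2h      0.2     23.8     400             0.2125                  0.0275
     T1_4h      4.0     20.0     400             0.4425                  0.3000
    T1_16h     16.0      8.0     400             0.5900                  0.4825
   psi_total  total_rate
    1.157345    3.719884
  389.553964  392.328418
 1395.470735 1401.730240
```

Reading the table: after 0.2 h of bulk priming only ~21% of single cells
show any detectable secretion; 4 h of cell–cell contact raises that to
~44% and multiplies the total pSI by ~300×; by 16 h a majority of cells
are polyfunctional (k ≥ 2). The fitted background for one analyte and the
IL2 fold change across the sweep:

```r
print(res$T1_4h$models$IFNg)
#> <scbc_background> IFNg: mu = 106.66, sigma = 16.85, cutoff = 140.37 (n = 300, KS p = 0.518)
fold_change(cmp, "T1_0.2h", "T1_4h", "IL2")
#> [1] 11.04027
psi_display_bins(res$T1_4h$profile)
#>   stratum  n fraction        psi
#> 1       1 57   0.1425   7.628302
#> 2       2 23   0.0575  17.768968
#> 3      3+ 97   0.2425 364.156693
```

The pooled 3+ stratum dominates the index — polyfunctional cells secrete
by far the most — which is the behavior the pSI statistic is designed to
expose.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that produce the
shipped result tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the four study cohorts and writes chamber tables |
| `02_background.R` | fits per-analyte backgrounds + KS/gradient diagnostics |
| `03_call_secretion.R` | calls secretion, tabulates detectable/polyfunctional fractions |
| `04_polyfunctionality.R` | pSI profiles, display bins, per-analyte decomposition |
| `05_cohort_comparison.R` | fold changes, composition stability, PCA/k-means embedding |

Run them in order from the repository root (`Rscript analysis/01_simulate.R`, ...).

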