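# ymcoupling

Phase-coupling analysis between the yeast metabolic cycle (YMC) and the
cell division cycle (CDC) in single cells.

Single budding-yeast cells oscillate between metabolic states every
~100–300 minutes, visible as a rise and fall of endogenous flavin
(FAD/FMN) autofluorescence. Time-lapse experiments show that these
oscillations are tightly phase-locked to division: the Whi5-mCherry
nuclear-localization pulse peaks tens of minutes before the flavin peak,
and mother–daughter nuclear separation happens near a flavin trough.
Under rapamycin the division cycle slows far more than the metabolic
oscillator, so several metabolic cycles fit inside one division.

`ymcoupling` is for researchers analyzing such single-cell fluorescence
time series. It provides:

* a **coupled-oscillator simulator** (`ymc_regime()`, `simulate()`) that
  generates unsynchronized cohorts of flavin + Whi5 traces with
  ground-truth peak/trough/division annotations, under trough-gated
  (`gated_1to1`) or rapamycin-like (`decoupled`) coupling;
* the **trace-processing chain** used for such microscopy data: strict
  <4.5 h track exclusion, order-7 polynomial detrending, normalization by
  the maximum, Savitzky–Golay smoothing, prominence-based peak/trough
  detection, autocorrelation period estimation and sick-cell censoring;
* **division-cycle annotation**: the top-5-brightest-pixel Whi5
  nuclear-localization score from mask images, per-division Whi5 peaks,
  and division periods from nuclear-separation event lists;
* the **coupling statistics**: peak-to-peak (T_P) and trough-to-trough
  (T_M) metabolic periods, division periods (T_CDC), the signed lag
  ΔT = t_separation − t_nearest trough (and ΔT/T_M), the per-division
  Whi5-to-flavin lag ΔP = t_Whi5 peak − t_flavin peak, metabolic cycles
  per division, period return maps (T_P[n], T_P[n+1]), cohort summaries
  and two-sample Kolmogorov–Smirnov comparisons.

The central interface is one fitting call returning a classed object:

```r
fit <- ymc_coupling(cohort)          # cohort from simulate() or read_cohort()
print(fit); summary(fit); coef(fit); plot(fit)
```

## Worked example

```r
library(ymcoupling)
coh <- simulate(ymc_regime("ynb_1x", n_cells = 40, seed = 1))
fit <- ymc_coupling(coh)
fit
#> Metabolic-cycle / division-cycle coupling fit
#>   40 cells (0 excluded), 309 complete divisions
#>   [ynb_1x] T_P 132.9 +/- 25.4 min (n=317); delta_T -0.7 +/- 13.2 min; single-cycle divisions 96.4%
round(coef(fit), 2)
#>            mean_T_P            mean_T_M          mean_T_CDC        mean_delta_T
#>              132.89              132.13              136.71               -0.74
#>          sd_delta_T        mean_delta_P mean_cycles_per_cdc   frac_single_cycle
#>               13.19              -32.52                1.04                0.96
```

Reading the numbers: the detected peak-to-peak metabolic period averages
~133 min against the preset's configured 136-min mean; divisions sit on
average within a minute of the nearest metabolic trough (mean ΔT ≈ −0.7
min) with a spread of ~13 min, reflecting the configured 10-min gating
jitter plus the localization error of trough detection at 5-min sampling;
the Whi5 localization peak precedes the flavin peak by ~33 min on
average; and 96% of divisions contain exactly one metabolic cycle, as
expected for trough-gated 1:1 coupling with a 5% stall probability.

The `rapamycin` preset decouples the two cycles; rerunning the same two
lines with `ymc_regime("rapamycin")` drops the single-cycle fraction
below one half and roughly doubles the mean cycles per division.

A file-based pipeline (`run_simulate()`, `run_analyze()`,
`run_report()`, or `run_pipeline()` for everything) writes trace tables
(TSV), event lists and summaries (JSON), regimes (YAML) and report
figures; `inst/cli/ymcoupling.R` exposes the same steps as shell
subcommands (`simulate`, `analyze`, `report`, `all`).

See the methods vignette (`vignettes/ymc-coupling-methods.Rmd`) for the
generator model, parameter defaults and their rationale, numerical
choices and known limitations.

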