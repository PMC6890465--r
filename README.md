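# circafly

Quantitative analysis of Drosophila circadian behavior and molecular
rhythms, built for the workflow of an RNAi period screen: estimate each
fly's free-running period from locomotor activity, call rhythmicity,
quantify behavioral phase under light pulses and temperature cycles, fit
damped reporter rhythms, call screen hits against batch-stratified
cutoffs, and quantify transcript levels from qPCR Ct tables.  It is
aimed at chronobiologists who record flies in beam-break activity
monitors and at anyone who needs a tested, scriptable replacement for
the spreadsheet-and-legacy-software pipeline such screens typically use.

Everything is tidyverse-native: functions take data frames first,
return tibbles, and compose with the pipe; results have `autoplot()` /
`plot_*()` views and fitted objects have broom-style `tidy()` /
`glance()` methods.  A synthetic-data module generates activity,
luciferase, screen and qPCR datasets with known ground truth, so every
stage of the pipeline is testable without any external download.

## The statistics at the core

**Chi-squared periodogram (Sokolove–Bushell).**  For a trial period of
*P* bins, fold the series into *K* complete cycles and compare the
variance of the *P* circadian-phase column means to the total variance:

    Q_P = N * sum_c K_c (M_c - Mbar)^2  /  sum_i (x_i - Mbar)^2

Under the null, `Q_P ~ chi-squared(P - 1)`.  The peak of `Q_P` above the
`1 - alpha` chi-squared line gives the period; **power** (peak excess)
`> 20` and **width** (supra-threshold span) `> 1.5 h` define
rhythmicity, as in standard screening practice.

**Damped cosinor.**  Reporter rhythms are fitted on the first two days
of constant darkness with
`y(t) = M + A exp(-gamma t) cos(2 pi (t - phi)/tau)` by multi-start
bounded least squares.

**Stratified 2-SD hit calling.**  Line-level mean periods are cut at
`mean ± 2 SD` within each RNAi-collection × driver stratum (TRiP /
pooled VDRC / 40D-KK separately), because collection backgrounds,
drivers, and the 40D landing site each shift period systematically.

**2^-ΔΔCt.**  Relative expression from triplicate Ct values, normalized
to a reference gene and a calibrator sample, with optional group-mean
rescaling and standard-curve efficiency QC.

## Worked example

```r
library(circafly)

# a control and a short-period knockdown cohort: 3 LD days, 5 DD days
ctl <- simulate_locomotor_cohort(n_flies = 16, tau = 24.8,
                                 genotype = "driver_ctl", seed = 11)
kd  <- simulate_locomotor_cohort(n_flies = 16, tau = 23.6,
                                 genotype = "Psi_kd", seed = 12)

pg <- chi_squared_periodogram(dplyr::bind_rows(ctl$activity, kd$activity))
summarize_rhythms(pg)
#> # A tibble: 2 × 7
#>   genotype       n pct_rhythmic mean_period sem_period mean_power sem_power
#>   <chr>      <int>        <dbl>       <dbl>      <dbl>      <dbl>     <dbl>
#> 1 Psi_kd        16          100        23.7     0.0340       145.      6.22
#> 2 driver_ctl    16          100        24.9     0.0491       124.      3.58
```

Per genotype: flies tested, percent passing the power/width rhythmicity
criteria, and the mean ± SEM of the periodogram peak period over
rhythmic flies — the knockdown runs ~1.2 h faster than its control, as
programmed.  The same table is what a screen summary reports per line.

```r
lux <- simulate_luciferase_series(tau = 23.5, damping = 0.03,
                                  noise_sd = 2, seed = 5)
fit_damped_cosinor(lux)
#> Damped cosinor fit (97 points, window 0-48 h)
#>   period  23.408 h   damping 0.0303 /h   amplitude 29.26
#>   mesor   100.13     acrophase 6.06 h   RSS 336   converged: TRUE
```

The fitted period lands within 0.1 h of the generating 23.5 h despite
noise and damping.  `autoplot(pg)`, `autoplot(fit)` and
`plot_screen_histogram()` draw the standard views; `tidy()` and
`glance()` extract coefficients.

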