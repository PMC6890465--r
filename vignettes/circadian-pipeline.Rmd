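---
title: "Methods: the circafly circadian analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the circafly circadian analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circafly)
```

`circafly` implements the quantitative workflow of a Drosophila circadian
RNAi screen: period estimation and rhythmicity calling from locomotor
activity, behavioral phase quantification, damped cosinor fitting of
luciferase reporter rhythms, batch-stratified hit-calling, and qPCR
relative quantification.  This vignette is the package's own account of
the underlying models, the tunable parameters, the numerical choices,
and what the synthetic-data tests do and do not establish.

## The chi-squared periodogram

For a trial period of $P$ analysis bins, the activity series is folded
into its first $K = \lfloor N_{avail}/P \rfloor$ complete cycles and the
Sokolove–Bushell statistic is formed from the column (circadian phase)
means $M_c$ and the grand mean $\bar M$:

$$ Q_P \;=\; \frac{N \sum_{c=1}^{P} K_c\,(M_c - \bar M)^2}
                  {\sum_{i=1}^{N} (x_i - \bar M)^2}, $$

where $K_c$ is the number of observations in phase column $c$ ($K_c = K$
when no bins are missing) and $N$ is the number of non-missing
observations.  Under the null of no rhythm, $Q_P$ is approximately
chi-squared with $P-1$ degrees of freedom; the significance line is the
$1-\alpha$ quantile of that distribution.  We verified the null
calibration by simulation (homogeneous Poisson series), and an
independent brute-force fold-and-variance oracle reproduces the
implementation to relative error below $10^{-12}$.  Note the
column-sum-of-squares must carry the $K_c$ weighting: the unweighted
ratio is bounded above by $P$ and could never cross the chi-squared
line, so no series would ever test rhythmic.

The peak is the global maximum of $Q_P$ minus the significance line over
the trial-period grid; **power** is that excess at the peak and
**width** is the contiguous grid span around the peak where $Q_P$
exceeds the line.  A fly is **rhythmic** iff power $> 20$ and width
$> 1.5$ h, both strict — the conventional screening criteria.  These
power/width definitions are stated conventions: the screening software
that popularized them does not publish its internal normalization, so we
calibrate their semantics by the null rate (about 0% of amplitude-zero
flies pass the joint criterion; the bound we test is 5%), not by
numerical equality with any legacy tool.

Choices worth knowing:

* **Grid**: 18–30 h in 0.1 h steps.  Raw counts are aggregated to 0.1 h
  analysis bins so every trial period is an exact integer number of
  bins; screen period histograms are conventionally binned at the same
  0.1 h resolution.
* **Truncation**: the incomplete final cycle is discarded ($K$ complete
  cycles), keeping the degrees of freedom exact.  We measured the
  alternative (folding all bins with unequal column counts) on synthetic
  cohorts and it did not improve recovery, so the simpler rule stands.
* **Missing bins** (monitor status errors) are excluded pairwise from
  the column means and from $N$; they are never imputed.
* **Degenerate windows** (constant or all-missing) return a flagged
  non-rhythmic result rather than an error; a window shorter than two
  cycles of the longest trial period is a precondition error.
* $\alpha = 0.05$ by convention.

With the default study design (3 LD + 5 DD days, modulation depth 0.8,
16 flies per genotype) the median absolute period error is at the grid
resolution, 0.1 h.  The estimate is grid-quantized, so this is the
expected floor.

## Eduction and phase

An **eduction** folds the selected days at the cycle length (24 h for
entrained protocols) and averages per phase bin: within fly over days,
then across flies, with the SEM taken across flies.  All flies enter
phase analyses regardless of rhythmicity, matching how phase-shift
experiments are scored.

The **peak phase** is read from the profile after a centered *circular*
4 h moving average (the profile is a circular object; on raw multiday
traces a linear edge-truncated average would be used instead).  The
grid argmax is then refined by the vertex of a local quadratic fit over
±1 h.  The refinement is the package's replacement for the traditional
human peak reading: a 4 h average over a ~2 h activity bump flattens the
peak top, so the raw argmax alone carries avoidable bin-level noise; the
quadratic vertex is exact for symmetric peaks, never moves the estimate
by more than 1 h, and empirically cuts readout noise about threefold.
Ties are broken toward the earliest time and flagged; an all-equal
smoothed profile yields an undefined phase.

**Phase shifts** (light-pulse experiments) are
`peak(unpulsed) − peak(pulsed)` on group-average profiles over the same
post-pulse days, as a circular difference mapped to $(-12, +12]$;
advances are positive.  **Relative evening phase** (temperature-cycle
experiments) is `peak(test) − peak(control)` in the same convention, so
an advanced knockdown is negative.  A difference of exactly half a cycle
is reported as $+12$.

Under a 12:12 warm/cold temperature cycle the warm phase (thermophase)
plays the role of day, with time 0 at the cold-to-warm transition.  The
evening peak is searched inside the thermophase with a margin,
`c(3, 11)` in the shipped analyses: the default `c(6, 18)` half-cycle
window is appropriate for free-running data, but under a square-wave
temperature cycle the startle bump at the warm-to-cold transition,
smeared ±2 h by the 4 h average, can form a secondary maximum reaching
down to phase 10, and an advanced knockdown peak can approach phase 6
from below.  Restricting the search to the startle-free part of the
thermophase is exactly what such windows are for.  Day-to-day peak
drift across the analysis days above 0.5 h triggers a warning (not an
error) that entrainment may not be stable.

**Anticipation scores** quantify phase under LD without reading a peak:
the morning score is the percent of ZT 17.5–23.5 activity falling in
ZT 20.5–23.5, the evening score the percent of ZT 5.5–11.5 activity in
ZT 8.5–11.5.  Window edges snap to the nearest bin edge.  A uniform
profile scores exactly 50% (3 h of 6 h); an empty window is flagged
undefined rather than dividing by zero.

## Damped cosinor

Luciferase reporter rhythms damp quickly in constant darkness, so the
period is fitted on the first two days (48 h, overridable) with

$$ y(t) = M + A\,e^{-\gamma t}\cos\!\big(2\pi (t-\phi)/\tau\big) + \varepsilon. $$

The mesor $M$ does not damp and no baseline trend is removed by default
(`detrend` adds a linear pre-detrend); this is the simplest form
consistent with an "exponentially damped cosinor", declared rather than
inferred.  Fitting is multi-start bounded Levenberg–Marquardt: $\tau$ on
a 0.5 h grid over [18, 30] h crossed with damping starts
$\{0, 0.02, 0.05\}$ /h, an exact linear sub-fit of $(M, a, b)$ in the
`a cos + b sin` parameterization at each start, and refinement of the
five best starts.  The internal parameterization makes $A \ge 0$ and
$\phi \in [0, \tau)$ unique by construction — a sign-flipped amplitude
is the same model with $\phi$ shifted by $\tau/2$, and `atan2` resolves
it canonically.  The returned RSS never exceeds any start's RSS.
`converged` is false when the optimizer hit the period or damping
bounds or the iteration cap, and for flat (zero-variance) input, which
returns an undefined period rather than an error.  Noiseless input is
recovered to at least four significant figures in all five parameters;
with Gaussian noise at 10% of the amplitude, the median period error
over 100 replicates is about 0.12 h (tested bound 0.3 h).

Genotype-level summaries average the period over converged wells, one
well (a few pooled flies) being one trace.

## Screen hit-calling

The screen's unit is the line × driver cross, summarized as the mean
period over rhythmic flies.  Period distributions differ systematically
by RNAi collection background (TRiP lines run ~0.3 h shorter than VDRC)
and by driver (a dominant ~0.8 h lengthening), and KK-collection lines
with an insertion at the 40D landing site carry an extra non-specific
lengthening (~0.6 h with the PDF-neuron driver).  Hit-calling therefore
stratifies: TRiP, pooled VDRC (GD + non-40D KK), and 40D-KK lines are
cut independently per driver, and the 40D stratum is never pooled back.
Within a stratum the cutoffs are mean ± 2 SD of the *line-level* means
(whether the original screen took the SD over line means or pooled fly
periods is not recorded; line means match how the period histograms are
binned, one entry per line, and is the choice here).  Classification is
strict: a line exactly at a cutoff does not pass.  Lines whose flies
were all arrhythmic are routed to a separate rhythmicity-candidate
report — a period screen cannot classify them.

Under a pure normal null the two-sided 2-SD rule passes
$2\Phi(-2) = 4.55\%$ of lines; the simulated 1000-line null reproduces
this within Monte-Carlo error, and injected effects of ±3 per-fly SD
(±1.5 h, about 7 line-mean SDs at 6 flies per cross) are recovered
essentially always.  Note that an effect of 3 *line-mean* SDs would be
recovered only ~84% of the time against a 2-SD cutoff — calibration
benchmarks should inject clearly separable effects so that a miss
indicates a bug, not sampling noise.

`read_screen_table()` loads an external line-level table through a
column mapping, so a published screen export can be re-cut with the same
stratified rule; `screen_panel_counts()` tallies passing lines per
panel, driver and direction for comparison with published histogram
legends.  The package does not implement the repeat-confirmation logic
of a multi-round screen; it classifies single datasets.

## qPCR

Technical replicates are averaged on the Ct scale (the Livak
convention), then per sample and target
$\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{reference}$,
$\Delta\Delta Ct = \Delta Ct - \Delta Ct_{calibrator}$, and
$2^{-\Delta\Delta Ct}$ is the relative expression.  The reference
defaults to *RpL32*.  Replicate SD above 0.5 cycles is flagged.  An
optional rescaling group divides each target's series by the group's
mean relative expression, putting, e.g., control and knockdown time
courses on a scale where the knockdown time-course average is 1.
Biological replicates would be averaged *after* the transform (per
sample, then summarized); the package returns per-sample values so the
caller owns that choice.  Standard-curve efficiency
($E = 10^{-1/slope} - 1$) is a QC report with a pass band of
$E \in [0.9, 1.1]$, not a Pfaffl-style correction.

## The synthetic generators — what they emulate

`simulate_locomotor_cohort()` draws counts from an inhomogeneous Poisson
process: rate $= r_0 (1 + a\, b(\varphi))$ with $b$ a bimodal template of
two wrapped-Gaussian bumps (morning and evening, default width 2 h —
the crepuscular fly profile), $a \in [0,1]$ the modulation depth, and
$r_0 = 40$ counts/h, giving realistic daily totals on the order of
1,000–1,500 beam breaks.  The phase runs at 24 h during entrainment
(light or temperature cycle) and free-runs at $\tau$ in DD, continuing
from the projected lights-on of the last entrained day (CT0).  Masking
is multiplicative night/cryophase suppression (×0.4) plus a 2-bin
additive startle (2 × baseline) after each transition — the minimal
features that make eduction and phase readouts realistic.  Arrhythmic
flies have amplitude 0 but normal activity levels; dead or low-count
flies are a different phenomenon and are not simulated.  A
`dd_phase_shift` models the effect of a resetting light pulse as an
instantaneous phase step at DD onset.

Study conditions fixed in the shipped tests: 3 LD + 5 DD days and 16
flies per genotype for period recovery (cohort taus 23.6, 24.1, 24.8,
26.0 h — the range from short-period knockdowns through wild type to
long-period hits); 200 amplitude-zero flies for the null rate; 16
flies and 6 DD days per group for the ±2 h pulse-shift recovery; 3 LD +
7 TC days, analyzed over TC days 7–10, for the temperature-cycle
comparison.  The TC evening bumps sit mid-thermophase (control 8.0 h,
knockdown 5.5 h — a programmed 2.5 h advance, the magnitude reported
for the emulated knockdown phenotype), placed so that neither bump's
smoothed readout is confounded by transition masking; with a bump
inside the smoothing window's reach of the warm-to-cold transition the
argmax readout acquires a genotype-dependent bias of up to ~1 h, which
is a property of peak-reading under masking, not of the implementation.

What passing these tests shows: the estimators recover known parameters
from data with Poisson noise, masking, arrhythmic contamination and
batch structure, at the stated sample sizes.  What they do not show:
robustness to features the generator lacks — activity bout
autocorrelation, ultradian rhythms, gradual temperature ramps, damping
of behavioral amplitude across DD days, death during recording, or
plate spatial effects in luciferase data.  Published in-vivo numbers
(genotype periods, the ~2.5 h phase advance) are emulation targets for
the generator, not quantities the package claims to reproduce from
deposited raw data.

`simulate_screen_dataset()` builds per-fly periods as base period
(24.1 h) + collection offset + driver offset (+ 40D offset where
applicable) + injected effect + N(0, 0.5 h), with 6 flies per cross and
an 85% per-fly rhythmicity probability.  The 40D offset with the tim
driver is set to a "modest" +0.2 h (only the PDF-driver value, +0.6 h,
is constrained by the emulated screen).  `simulate_qpcr_plate()` places
the target Ct at `reference Ct + base ΔCt − log2(ratio)` so programmed
fold changes are exactly recoverable at zero noise.

## Problem sizes and runtime

The shipped test suite and the acceptance script run the full pipeline
at the sizes above (the largest single computation is 200 periodograms
over a 121-point trial-period grid) in well under a minute on one core;
these sizes were chosen because the Monte-Carlo error they leave is
already far below every tested tolerance.

## Known limitations

* Period estimates are quantized to the 0.1 h trial grid; sub-grid
  refinement of $Q_P$ peaks is deliberately not attempted because the
  screening conventions are defined on the grid.
* The periodogram's chi-squared null is asymptotic; for very short
  windows (two cycles) it is conservative rather than exact.
* The cosinor model excludes mesor damping and baseline drift unless
  `detrend = TRUE`; strongly drifting traces should be detrended.
* DAM files carry no temperature channel, so temperature-cycle protocol
  labels must be set by the caller after reading.
* The hit caller classifies one screen round; multi-round confirmation
  ("selected for repeats") is out of scope.
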