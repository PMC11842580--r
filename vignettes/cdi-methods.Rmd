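---
title: "Methods: the Combined Drought Indicator engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Combined Drought Indicator engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdi)
```

## The model

Agricultural drought is modelled as a top-down cascade: a persistent
precipitation deficit (*Watch*) depletes soil moisture (*Warning*), which
eventually stresses vegetation (*Alert*). The Combined Drought Indicator
(CDI) tracks this cascade per pixel on a regular lon/lat grid at a dekadal
(10-day) time step, combining four standardized indicators at dekad $T$
with the pixel's class at $T-1$:

* **SPI-1, SPI-3** — precipitation accumulated over ~30 and ~90 days ending
  at $T$, transformed through a per-pixel gamma fit over a 30-year baseline
  (default 1981–2010) into a standard normal deviate,
  $z = \Phi^{-1}\!\big(q + (1-q)\,G(x;k,\theta)\big)$, where $q$ is the
  probability of a zero total and $G$ the gamma CDF fitted to positive
  totals.
* **SMA** — the soil moisture anomaly: the dekadal mean of the daily soil
  moisture index $I = \sum_{n \in T}\mathrm{SMI}_n / N$ ($N$ = days in the
  dekad, SMI in $[0,1]$), z-scored against its per-pixel, per-dekad
  climatology $z = (I - \mu)/\sigma$ (baseline 1995 onward).
* **FAPAR anomaly** — the dekadal composite of 8-day FAPAR (inverse
  time-distance weighting of the closest composites), z-scored the same way
  (baseline 2012 onward).

The classifier is a decision table of eight columns (the $2^3$ combinations
of the exceedance flags) by seven rows (the class at $T-1$). The flags are

* SPI flag: $(\mathrm{SPI1} < -2) \lor (\mathrm{SPI3} < -1)$ — strict
  comparisons;
* SMA flag: $\mathrm{SMA} \le -1$; FAPAR flag:
  $\mathrm{FAPAR} \le -1$ — inclusive comparisons.

Seven classes result: No drought, the three drought stages, and three
recovery classes (Recovery, Temporary Soil Moisture Recovery, Temporary
Vegetation Recovery) that *mediate every return* from drought to
no-drought: the framework never maps a drought class directly to No
drought.

## The decision table

The table ships as data (`inst/extdata/decision_table.csv`), not code;
`validate_table()` enforces its structural constraints and `cdi_step()`
refuses an invalid table. The constrained cells are:

* columns **E, G, H** (vegetation stress concurrent with soil or
  precipitation deficit) → Alert for every previous class;
* column **B** (precipitation deficit alone) → Watch;
* column **F** (precipitation + soil deficit) → Warning;
* column **C** (soil deficit with normal SPI) → Warning, except that a
  wet-SPI spell ($\mathrm{SPI1} > 0.5 \land \mathrm{SPI3} > 0$)
  counterbalances the soil deficit when the previous class is No drought or
  Recovery, yielding No drought;
* column **A** (all normal): Watch → Recovery; Warning → Temporary Soil
  Moisture Recovery if $\mathrm{SMA} \in (-0.5, 0]$; Alert → Temporary
  Vegetation Recovery if $\mathrm{FAPAR} \in (-0.5, 0]$.

The remaining cells are design choices of this package, documented here:

* **Column A "else" branches.** A Warning/Alert pixel whose anomaly has
  risen above $-1$ but outside the partial-recovery interval maps to
  Recovery (the anomaly is above the reference threshold, the defining
  property of the recovery classes), and a recovery-class pixel whose
  anomaly has left the partial interval completes to No drought. This keeps
  the recovery dwell time finite and — importantly — keeps the set of
  classes reachable under an active snow mask free of Warning and Alert.
* **Column D (vegetation stress alone).** With no concurrent deficit and no
  drought memory (previous class No drought) the signal is not attributed
  to drought — FAPAR dips have many non-drought causes — and the pixel
  stays at No drought. With drought memory (any drought or recovery class)
  the vegetation stress is read as the cascade's delayed response and maps
  to Alert. This is what lets an Alert persist through FAPAR alone after
  SPI and SMA have recovered, and hence what the out-of-season crop mask
  visibly corrects.

## Mask reductions and versions

* **v2**: no masks.
* **v3** adds the static crop masks: a pixel is cropland when its crop
  fraction is ≥ 1% and it is not rangeland; each of the 36 dekads-of-year
  is in season when it lies in the circular interval $[SOS, EOS]$ (both
  ends inclusive; $SOS > EOS$ wraps the year end, covering winter crops).
  On cropland out of season the FAPAR flags (exceedance and partial) are
  suppressed, collapsing the framework to columns A, B, C, F. Non-crop
  pixels are never FAPAR-reduced: natural vegetation is still assessed.
* **v4** adds the dynamic snow masks: under snow, both the SMA and FAPAR
  flags are suppressed (model soil moisture is unreliable under snow, and
  vegetation stress is not meaningfully observable), collapsing the
  framework to columns A and B.

Snow masks are composited from daily NDSI (0–100): values above 10 are
snow, 0 is no snow, and 1–10 are discarded as uncertain — treated as no
snow by default, mirroring the compositing rule of the 8-day snow product
that convention comes from (configurable to missing). A pixel is snow in a
dekad when snow was observed on **at least 3 days**; the threshold is an
absolute count by default ("three days out of ten" read as a count, applied
also to 8/9/11-day dekads), with a proportional mode
($\ge \lceil 0.3N \rceil$) available. A pixel with *zero* valid
observations in a dekad inherits its $T-1$ value (one-dekad persistence;
partially cloudy dekads still count their observed snow days against the
3-day rule). At the start of an archive, with no $T-1$, the default is no
snow. Modal (most frequent value) aggregation brings fine binary masks to
the CDI grid; exact ties break toward snow — conservative, since the
mask's purpose is to suppress unreliable anomalies.

## Numerical choices

* **Gamma fitting**: maximum likelihood on the positive totals, vectorized
  over pixels (Thom's closed-form initialization, Newton refinement on the
  profile equation $\log k - \psi(k) = \log\bar x - \overline{\log x}$),
  with a moment fallback where the MLE is undefined (near-constant
  samples). Tests cross-check against an independent MLE implementation.
* **Zero totals**: mixed distribution $H(x) = q + (1-q)G(x)$; an exactly
  zero total maps through $z = \Phi^{-1}(q/2)$ (centre-of-mass convention)
  rather than $H(0) = q$, avoiding a systematic wet bias.
* **Clamping**: $|z| \le 3.5$ for the SPI, avoiding infinities in extreme
  tails.
* **Validity minima**: SPI fits need ≥ 20 usable baseline years and ≥ 10
  positive totals per pixel/dekad; z-score climatologies need ≥ 5 years
  (soil-moisture and vegetation archives are short, and short baselines
  still identify deficits usefully) and $\sigma > 10^{-6}$. Dekadal SMI
  needs ≥ 7 valid days of $N$. Pixels failing any of these are invalid,
  and an invalid SPI makes the classified pixel missing, while an invalid
  SMA/FAPAR behaves like a masked one (flags false) — consistent with the
  mask-reduction semantics.
* **SPI accumulation**: a rolling window of exactly 30/90 days ending at
  the terminal dekad's last day (default), or 1/3 complete calendar months
  (the value then shared by the month's three dekads) — both readings of a
  "~30 / ~90 day" timescale are supported.
* **FAPAR compositing**: the $k = 2$ temporally closest 8-day composites
  (the minimum that brackets a 10-day window; configurable), weights
  $\propto 1/(d + 0.5\ \mathrm{days})$ — the offset handles exact midpoint
  coincidence while preserving distance ordering — renormalized per pixel
  over valid inputs. Composites are timestamped at their period midpoint,
  dekads at theirs. Anomalies are computed after compositing and (where
  needed) bilinear resampling to the CDI grid, on the CDI grid.
* **Cold start**: the first dekad of a run has no $T-1$ map; all pixels
  start at No drought, and at least 3 dekads of spin-up are recommended
  before interpreting classes.

## The synthetic scene generator

Every input the pipeline consumes can be generated synthetically, fully
determined by one seed: zero-inflated gamma daily precipitation with a
seasonal cycle (wetter winters); a daily SMI whose dekadal state follows a
first-order autoregression on the standardized dekadal precipitation
anomaly, squashed to $[0,1]$ through a logistic; seasonal 8-day FAPAR
composites (a smooth day-of-year harmonic, mildly damped by the soil-state
deficit) with cloud quality flags; daily NDSI with a latitude-dependent
snow season and random cloud; and a crop layout with an out-of-season
winter-crop block and a rangeland strip.

Injected drought events multiply precipitation over a region and window,
and force the soil state and FAPAR over the same window lagged by the
event's `sm_lag` and `veg_lag` dekads. The lags are explicit forcings
rather than emergent dynamics by design: the classifier consumes
*z-scores*, which divide each response by its own natural variability, so
any autoregressive coupling strong enough to produce a realistic lagged
threshold crossing also crosses the threshold almost immediately. The
natural couplings are therefore kept weak — they create realistic
cross-correlation between the indicators, not threshold crossings — and
the propagation timing is owned by the event definition. For the same
reason the FAPAR seasonal baseline is continuous in day-of-year: a
dekad-stepped curve aliases leap-year shifts into spurious grid-wide
anomalies.

What the generator does **not** emulate: spatial correlation of weather
(pixels are independent draws, so spatial patterns in synthetic CDI maps
are not meaningful, only per-pixel trajectories and region aggregates);
hydrological routing and snowmelt (the soil model is a one-parameter
autoregression); sensor geometry, orbital gaps or reprojection artifacts.
Passing tests therefore demonstrate the correctness of the calendar,
standardization, masking and classification logic — not skill on real
remote-sensing archives.

A note on event-free scenes: with honestly standardized indicators the
Watch stage alone has a floor of roughly the SPI exceedance probability
($P(\mathrm{SPI3} < -1) \approx 0.16$ per pixel-dekad), so no correctly
standardized scene can be ~95% No drought; the tests assert what the
statistics actually imply — No drought is the modal class and holds a
clear majority, and every transition is legal.

## Problem sizes and I/O

Tests and the acceptance script run on small grids (1×1 to 100×100 pixels;
12×12 for the end-to-end scene) with full-length baselines (30 years for
the SPI, as the method prescribes), chosen so the whole suite completes in
well under a minute of numerical work per scenario while keeping every
baseline-length requirement honest. Rasters are exchanged as ESRI ASCII
grids (a plain-text, single-band raster format that represents the
package's cell-center-registered lon/lat grids exactly) with JSON sidecars
carrying variable names, dekad tags and — for class maps — the seven-class
legend and palette; dekads are encoded in file names as
`{var}_{YYYY}{MM}{D}` with `D` in 1..3. The package's functions are the
primary interface; a thin command-line wrapper (`inst/cli/cdi.R`) exposes
the scene generator, the end-to-end pipeline, table validation and
transition summaries.

## Known limitations

* The decision table's unconstrained cells (column D, the column A "else"
  branches) are reasoned defaults, not transcriptions of an authoritative
  table; they are deliberately stored as data so a different reading is a
  one-file change, and `validate_table()` guards the invariants any
  variant must keep.
* The engine standardizes on the analysis grid; regridding of coarser
  precipitation sources is a pre-step (`resample_bilinear()`), not an
  internal stage.
* Only geographic (EPSG:4326) grids are supported, and recovery classes
  have no maximum dwell time beyond what the partial-recovery intervals
  imply.
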