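---
title: "Methods: forecasting coastal management indices and verifying the forecasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting coastal management indices and verifying the forecasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shorecast)
```

This vignette is the package's own account of its methods: the two
management indices, how forecast ensembles are pushed through them, the
verification suite, what the synthetic-data generator does and does not
emulate, and the numerical choices made where a published description
leaves room.

## The problem

Coastal managers in the California Current use SST-derived indices to
make recurring decisions: is cool upwelling habitat compressed against
the shore (whale entanglement risk for the crab fishery)? Is the
Southern California Bight anomalously warm (loggerhead bycatch risk for
the drift gillnet fishery)? Both indices are traditionally computed from
*observed* temperature, so the decision always trails the ocean.
Seasonal forecast systems predict monthly SST up to a year ahead; if the
indices keep their skill when driven by forecasts, the same tools become
forward-looking. The package implements that substitution and, equally
important, the verification that tells a manager how far ahead each
tool can be trusted, month by month.

## The Habitat Compression Index

For calendar month $m$, the threshold $T_m$ is the mean SST over the
inner coastal band (coast to 75 km, 35–40 °N) across the climatology
years (classically 1981–2010). The index for a month is

$$\mathrm{HCI} = \frac{\#\{\text{cells in the 150 km band with } \mathrm{SST} < T_m\}}{\#\{\text{cells in the 150 km band}\}} \in [0, 1].$$

Low values mean little cool habitat: compression. A *high-compression
event* is a month with HCI **at or below** its long-term mean. Note the
two comparators are deliberately different: cell counting uses strictly
*below* the threshold, event classification uses *at or below* the mean.
The sources describing the tool phrase the two rules differently and we
honour each; both comparators are exposed as arguments
(`classify_high_compression(comparator=)`) for sensitivity checks. With
symmetric anomalies the ≤-mean rule fires about half the time, which is
the base rate the verification metrics assume for this tool.

Two invariances pin the arithmetic down and are enforced by tests:
adding a constant to both the SST field and the thresholds leaves HCI
unchanged, and raising a threshold can never lower the index. Months
where every band cell is missing propagate as `NA` — an undefined index
is never reported as 0, which would be a maximally-compressed ocean.

## The TOTAL closure indicator

TOTAL for a candidate closure month (June, July, August) is the mean
box-average SSTA over the **six months strictly preceding** it: a June
value averages December–May. The closure threshold is the *minimum*
TOTAL across the months when closures were historically enacted, so
every defining closure would itself have triggered the rule — which is
why exceedance is evaluated with ≥ (the `comparator` argument allows
strict >). The threshold is also expressed as a percentile of the
TOTAL-eligible distribution (the 6-month trailing means at every month
with a complete window over the stated period), so it can be transferred
to forecast distributions whose spread differs from the observations:
at each lead, the forecast threshold is the percentile-matching
quantile (linear interpolation, type 7) of the ensemble-mean forecast
TOTAL values at that lead.

The percentile itself is the **mid-rank** of the threshold within the
distribution — values strictly below count fully, ties count half. For
continuous data this is the ordinary empirical CDF; for tied data it
keeps a threshold that equals the distribution maximum strictly below
the 100th percentile, which is the behaviour the transfer needs.

## Forecast ensembles through the indices

Forecast systems drift: their bias grows with lead time. All
climatological quantities are therefore computed **per ensemble member
and per lead**: monthly HCI thresholds, the SSTA climatology behind
TOTAL, and the long-term mean behind event classification
(lead-specific). Anomalizing a member against its own (member, lead,
month) climatology removes the drift exactly — a linear drift of
0.15 °C/month leaves the forecast HCI centred (tested). Indices are
computed per member and then averaged, unweighted, into the ensemble
mean; members missing at a time point drop out of that point's mean.

Lead/target bookkeeping follows the mid-month convention: lead
$k + 0.5$ months targets the $k$-th calendar month after the
initialization month, so a 1 January initialization covers January
(lead 0.5) through December (lead 11.5). TOTAL forecasts need six
consecutive leads before the closure month, so from a single
initialization they exist at leads 6.5–11.5. Twice-yearly (January and
July) initializations — the schedule of dynamically downscaled systems,
whose compute budget forbids monthly starts — cannot supply all six
months from one run; the composition is encoded in a coverage table
(`total_coverage_table()`): June uses December from the *previous
July's* run (lead 5.5) plus January–May from the January run (leads
0.5–4.5); July uses January–June of the January run; August
February–July. The monthly SSTA values from that table are averaged
per member; nothing in the sources specifies a weighting across the two
runs, and uniform averaging of the listed months is the choice made
here.

Four labelled configurations reproduce the comparison design:
`Global` (full ensemble, full span), `GlobalFull` and `GlobalReduced`
(full ensemble versus a 3-member subset — by convention the 2nd, 8th
and 10th members — on the reduced span), and `Downscaled` (a separate
3-member ensemble on the January/July schedule). When the downscaled
set is involved, the global configurations are filtered to
January/July initializations so all are judged on the same footing.

## Verification

**Correlation.** Pearson correlation between observed and ensemble-mean
index values, per target month × lead. Monthly index series are
autocorrelated, so $N$ years overstate the information available. The
effective sample size is

$$N_{\mathrm{eff}} = \frac{N}{1 + 2\sum_{t=1}^{N-1}\left(1 - \tfrac{t}{N}\right) r_t^F\, r_t^O},$$

with $r^F_t, r^O_t$ the biased (1/N) sample autocorrelations of the two
series. The sum runs over symmetric lags — lag $-t$ contributes like
$+t$, hence the factor 2 — which is the version consistent with the
closed forms this correction is known for: white noise gives
$N_{\mathrm{eff}} \to N$, and paired AR(1) series with coefficient
$\rho$ give $N_{\mathrm{eff}}/N \to (1-\rho^2)/(1+\rho^2)$ (0.6 at
$\rho = 0.5$; recovered within ±0.05 at $N = 2000$ in the acceptance
suite). A non-positive denominator is flagged degenerate:
$N_{\mathrm{eff}}$ is clamped to $N$ and significance is not assessed.
The 95 % interval is Fisher-Z with standard error
$1/\sqrt{N_{\mathrm{eff}} - 3}$ and the normal quantile; skill is
significant when the lower bound exceeds zero. (Descriptions of this
test sometimes say the transform "follows a z distribution with
$N_{\mathrm{eff}}-3$ degrees of freedom"; the z distribution has no
degrees-of-freedom parameter, and the standard-error reading above is
the standard one.) On independent white-noise pairs the test fires in
≈2.5 % of replicates, the calibration the acceptance suite checks.

**Accuracy and its baseline.** Accuracy is $(TP+TN)/N$. A random
forecast issued at the event's own frequency $f$ scores
$f^2 + (1-f)^2$ in expectation, so that value — 0.5 at $f = 0.5$,
0.6152 at $f = 0.26$, 0.7048 at $f = 0.18$ — is the no-skill bar.
Printed summaries usually round such bars up to two decimals
(`accuracy_bound()`: 0.62, 0.71), the conservative direction for a bar.

**SEDI.** With hit rate $H$ and false alarm rate $F$,

$$\mathrm{SEDI} = \frac{\log F - \log H - \log(1-F) + \log(1-H)}{\log F + \log H + \log(1-F) + \log(1-H)}.$$

SEDI is non-degenerate as events become rare, base-rate robust, and
equitable — random forecasts score 0 in expectation regardless of $f$
(checked at $f \in \{0.2, 0.5\}$ to within ±0.02 over ≥2000 draws).
It is *undefined* when $H$ or $F$ is exactly 0 or 1 (e.g. a month with
no false positives); undefined values are reported as `NA`, never
coerced to 0, and appear as gaps in the heat maps.

**Bootstrap significance.** For accuracy and SEDI the null is built by
drawing random forecasts from the observed event labels (resampling
with replacement, equivalent to Bernoulli draws at the observed
frequency; a permutation variant is available) and scoring them against
the fixed observations, 1000 times by default. A score is significant
when it exceeds the null's 97.5th percentile. Two numerical notes:
when the metric is undefined in more than half the null draws the test
is not assessed (flagged, not silently passed); and because accuracy on
$n$ years is discrete, *strict* exceedance of an empirical percentile
reaches 2.5 % only from below — the calibrated false-positive rate sits
near but not above 2.5 %, which is how the calibration test brackets it.

## The synthetic ocean

The generator produces the statistical skeleton the analysis assumes,
with none of the dynamics:

- **Observed field**: latitude-linear mean (default 14 °C,
  −0.35 °C/°lat), sinusoidal seasonal cycle (default amplitude 3 °C,
  peak in August), a domain-coherent AR(1) monthly anomaly (default
  lag-1 coefficient 0.8, stationary SD 0.8 °C — values typical of
  monthly SSTA in an eastern boundary current), independent per-cell
  noise (default 0.3 °C), and optional heatwaves: constant warm
  anomalies over a window of months, emulating multi-year extremes like
  the 2014–2016 Northeast Pacific event (default analog: +2 °C,
  March 2014 – December 2016).
- **Forecast members**: at lead $L$, a member's anomaly is
  $\rho(L) \cdot a^{obs} + \sqrt{1 - \rho(L)^2} \cdot \eta$, with
  $\eta$ drawn with the same spatial structure as the observed
  anomalies (shared domain draw plus per-cell noise), plus a linear
  drift $b \cdot L$, plus the observed climatology. $\rho(L)$ decays
  multiplicatively or linearly from $\rho_0$; members are exchangeable,
  and the generating correlation is recoverable from the simulated
  ensembles within sampling error (tested). The default study
  conditions are a 73-member "global" ensemble initialized monthly
  (profile $\rho_0 = 0.85$, decay 0.93, drift 0.08 °C/month) against a
  3-member "downscaled" ensemble initialized in January and July with
  higher member skill ($\rho_0 = 0.9$, decay 0.95, drift
  0.02 °C/month), over 1981–2020 with 1981–2010 as the reduced
  climatology span.
- **Grid**: the default coastline is a meridian at the eastern domain
  edge (a stylised north–south shore); distances are haversine on a
  6371 km sphere, against a coastline sampled at a tenth of the cell
  size. Custom land masks are accepted, with the coastline taken as the
  ocean–land cell edges. Resolutions of 0.5–2° are the intended range —
  the indices aggregate over broad bands, so nothing is gained below
  that, and above ~1.3° no cell centre lies within 75 km of the coast
  and the HCI threshold band is empty (an error, by design).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: mesoscale spatial structure (anomalies are a
single domain-scale process), seasonally varying forecast skill,
non-Gaussian anomaly tails, observational error, and any
ocean dynamics (no upwelling physics, no shelf processes). The package's
claims about *real* forecast systems are limited to the arithmetic being
faithful; the synthetic worlds establish that the pipeline recovers
known parameters and orderings, not that any particular system is
skilful.

Forecast simulation accepts a `cells` argument restricting generation
to the cells an index actually reads. A full 73-member, monthly-init,
40-year gridded ensemble is large for no analytic gain — the indices
only see the coastal bands and the Bight box — so the pipeline
simulates exactly those cells by default (`restrict_cells = TRUE`).

## Replicated experiments

Two study-level properties are checked by dedicated drivers, shared
verbatim between the test suite and `scripts/acceptance.R`.

`experiment_ensemble_ordering()` (20 replicate worlds, 1981–2011,
January/July initializations, HCI correlation per target month × lead —
24 cells per world): with equal member skill ($\rho_0 = 0.5$, decay
0.9), the 73-member ensemble mean out-correlates its own 3-member
subset in well over 60 % of cells — averaging suppresses member noise.
Giving the 3 "downscaled" members sufficiently higher individual skill
($\rho_0 = 0.995$, decay 0.995) reverses the ordering. Both directions
are asserted; together they reproduce the qualitative trade-off between
ensemble size and member quality.

`experiment_heatwave_forewarning()` (one world of 1981–2012 with a
+2 °C heatwave in 2011–2012, a 5-member ensemble with
$\rho(L) \geq 0.6$ at all leads, plus an identical control world
without the heatwave): at lead 0.5, at least 80 % of in-heatwave months
are flagged high-compression, and at least one June–August closure is
recommended 6.5 or more months ahead. The control is scored with the
same rules — the heatwave world's absolute closure threshold, since a
closure-free world defines none of its own — and recommends no
closures; its HCI triggering rate is reported as the long-run event
frequency (~0.5 under the ≤-mean rule). A 24-month window of a
persistent AR(1) anomaly field is a single autocorrelated excursion,
not a rate estimator, which is precisely why the closure tool needs an
extreme-value threshold rather than a mean-exceedance rule.

## Numerical choices and degenerate inputs

- Cell membership in masks is by cell centre; bounds are closed;
  longitudes use the −180..180 convention. Empty masks are errors, not
  empty results, because an index over an empty band is undefined.
- Quantiles use R's type 7 (linear interpolation) throughout.
- Autocorrelations use the biased 1/N normalization (the convention
  under which the triangular-weighted sum is well behaved).
- `N_eff` is clamped to $(0, N]$; degenerate denominators disable
  significance rather than producing a larger-than-$N$ sample size.
- Missing values: index months with no data are `NA`; pairs with
  missing values are dropped before correlation; ensemble means use
  available members. Nothing missing is ever coerced to zero.
- Seeds: every stochastic function takes an explicit `seed`; fixed
  seeds give bit-identical outputs (tested at the tibble and at the
  written-CSV level). Derived seeds are small integer offsets of the
  caller's seed.
- netCDF I/O is CF-style (lon/lat/time, or lon/lat/lead/member/init),
  doubles, `degC` units; non-Celsius units or missing dimensions are
  schema errors, not warnings.

## Problem sizes

Tests and the acceptance script run on deliberately small worlds chosen
to make the checked quantities statistically decisive: a 7 × 3–6 cell
coastal grid at 1°, 30–40 year records, ensembles of 2–73 members, 20
replicate worlds for the ordering study, 1000 replicates for the
calibration studies, 2500 draws for SEDI equitability. The full suite
runs in about a minute; the acceptance script in well under a minute.

## Known limitations

- The synthetic coastline is a meridian; real coastline geometry (bays,
  islands) only enters through a user-supplied land mask.
- Member noise is exchangeable and Gaussian; real multi-model ensembles
  have structured inter-model differences that uniform averaging does
  not model (no model weighting is implemented, deliberately).
- The percentile transfer of the closure threshold assumes the forecast
  TOTAL distribution is well sampled at each lead; with twice-yearly
  initializations only a few values per lead exist, and the composite
  TOTAL is reported per closure month without a single well-defined
  lead (the maximum contributing lead is attached instead).
- Probabilistic verification (reliability, CRPS) is out of scope; the
  suite verifies ensemble means and binary events only.
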