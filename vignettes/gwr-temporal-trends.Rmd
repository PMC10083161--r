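---
title: "Estimating spatially varying temporal trends from rotating-panel monitoring data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spatially varying temporal trends from rotating-panel monitoring data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(gwtrends.verbose = FALSE)
```

## The problem

Status-oriented monitoring programs trade temporal resolution for spatial
coverage: a rotating-panel lake survey may cover thousands of lakes but
revisit each one only every sixth year, leaving two or three observations per
station after a decade. Station-wise trend tests (Mann–Kendall, per-station
regression) are useless on series that short, and a single national trend
model assumes away exactly the spatial differences such surveys are best
placed to reveal.

`gwtrends` resolves this by borrowing strength across space. For station $i$
with observations $j$, the model is

$$Y_{ij} = \beta_{i0} + \beta_i\, t_{ij} + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma^2),$$

with $Y$ the (centered) log10 concentration and $t$ the calendar year. The
coefficients vary by location: each station's line is fitted by weighted
least squares over *all* observations, weighted by spatial proximity. Where
trends are driven by large-scale pressures (climate, atmospheric
deposition), nearby stations share a slope, and pooling ~100 neighbouring
observations substitutes for the missing temporal depth at any single
station.

## Weights and bandwidth

Distance decay uses the bisquare kernel
$w_{ij} = \left(1 - (d_{ij}/b)^2\right)^2$ for $d_{ij} < b$ and $0$
otherwise. The support is strict: the observation exactly at distance $b$
gets weight zero. The bandwidth is adaptive, $b$ = the Euclidean distance to
the $k$-th nearest *observation* (co-located observations each occupy a
rank), so the kernel widens where the network thins. Coordinates must be
planar metres; the package refuses longitude/latitude input rather than
silently computing degrees-based distances.

The neighbourhood size $k$ is the one real tuning parameter. It is chosen by
leave-one-out cross-validation over an explicit grid
(`select_bandwidth()`): each observation is predicted from its station's
local fit with its own weight zeroed, the bandwidth ranks staying as
computed on the full set. Per-observation (rather than per-station) leave-out
is the default; `loo = "station"` removes the whole focal station, a
stricter variant that measures pure spatial interpolation. An exhaustive
grid is used instead of a line search because the CV profile need not be
convex in $k$ and is itself worth inspecting. Ties take the smaller $k$.
Larger $k$ smooths more: it suppresses noise but flattens genuinely local
trends, so results at a deliberately smaller $k$ are worth comparing
(`compare_fits()`).

## Pre-processing

Three steps precede fitting, in order:

1. **log10 transform** (`log10_transform()`): concentration data are
   right-skewed; the log stabilises variance and tames single high values.
2. **Minimum-observation filter** (`filter_min_observations()`, default 2):
   stations seen once carry no temporal information.
3. **Station-wise mean-centering** (`center_by_station()`): each station's
   mean log value is subtracted. This is the step that makes the pooled
   local regressions honest. Station levels differ persistently (catchment,
   lake type), and in a rotating design stations *enter the record in
   different years* — a window where high-level stations happen to be
   visited late manufactures a spurious upward pooled slope. Centering
   removes levels entirely; only within-station change remains. The fitted
   slope is invariant to any per-station constant, which is tested at
   1e-12.

Two diagnostics sit alongside:

- **Log-normal CV screen** (`station_summaries()`, `flag_high_cv()`):
  $CV = \sqrt{e^{s_{\ln}^2} - 1}$ with $s_{\ln} = s_{10}\ln 10$, computed
  per station. Sample SD uses denominator $n-1$ (series can be as short as
  2). A CV near 1 means the back-transformed spread rivals the mean level —
  either a suspect value or a genuinely steep trend. Flagged stations are
  not dropped automatically; the recommended protocol is refit-without and
  compare slopes, since removing steep-trend stations would bias exactly
  what is being estimated. Threshold comparisons are strict (`>`).
- **Moran's I on the crude change per year**
  (`change_per_year = (y_{last} - y_{first})/(year_{last} - year_{first})`,
  then `morans_i()`): if nearby stations change alike, a spatially varying
  model is warranted. Weights are inverse Euclidean distance with zero
  diagonal and, by default, no row standardisation; the expectation is
  $-1/(n-1)$ and the p-value is the two-sided normal approximation under the
  randomization assumption. Row standardisation is available as an option
  (`row_standardize = TRUE`) since conventions differ between
  implementations; the scheme used is recorded in the result.

## Inference

Each local fit reports the slope in log10 units per year with a standard
error from the weighted-least-squares covariance
$\sigma^2 (X'WX)^{-1} X'W^2X (X'WX)^{-1}$. The default $\sigma^2$ is a
single global estimate $RSS/\delta$ with effective degrees of freedom
$\delta = n - 2\,\mathrm{tr}(S) + \mathrm{tr}(S'S)$, $S$ the hat matrix
collecting every observation's locally fitted value — the established GWR
convention; a per-station variance is available via `sigma = "local"`.
T-statistics use $\delta$ degrees of freedom.

P-values are deliberately reported **unadjusted**. With thousands of
correlated local tests, and with temporal and residual spatial correlation
both unestimable from two or three observations per station, the p-values
understate uncertainty and should be read as a map-enhancement device:
interpret connected regions of consistent significant slopes, not single
stations. Benjamini–Hochberg and Bonferroni columns (`p_bh`,
`p_bonferroni`) are included for reporting. Significance classes
(down/none/up at `alpha`, strict inequality) drive the map colouring in
`autoplot(fit, "signif")`.

The overall adjusted $R^2$ is typically low even when the method works —
large regions with no trend contribute nothing but noise — so local $R^2$
values are the more informative fit diagnostic.

## Moving windows

A single linear slope cannot represent a trend that turns.
`moving_window_fit()` repeats the whole pipeline inside fixed-length
temporal windows (default 10 years, advancing by 1): subset, re-filter,
**re-center within the window** (window subsets would otherwise inherit the
level artifacts centering exists to remove), re-select $k$ by CV per window
(the optimal neighbourhood genuinely differs between windows), fit. Slope
fields viewed side by side expose reversals; `autoplot()` summarises the
slope distribution per window.

## The synthetic survey generator

Every estimator property is testable without external data via a generator
that emulates the rotating-panel design: `generate_network()` places
stations uniformly (or with a south-heavy linear density gradient) in a
500 × 1500 km domain; `assign_panels()` deals them round-robin (after a
seeded shuffle) into 6 panels revisited on the modular schedule, so a
2008–2021 record gives each station 2–3 visits; `simulate_observations()`
draws log10 values from smooth intercept and slope fields (constants plus
Gaussian bumps — closed-form truth for bias accounting) with i.i.d. Gaussian
noise; `inject_outliers()` shifts the temporally first observation of a
chosen fraction of stations, the failure mode where one early bad value
fakes a trend.

Default study conditions: 800 stations, 6 panels, years 2008–2021, noise SD
0.1 log10 units, and the reference `two_region_surface()` with slopes
+0.015 (west) to −0.02 (east) log10/yr — magnitudes in the range reported
for decadal lake-browning change. The analysis-side neighbourhood for this
design is taken as k = 100 observations, about 3% of the data, the same
fraction cross-validation selects on the national survey this design
mirrors. Time is centered at the survey mid-year inside the simulator only
(it decouples the two fields); the estimator is invariant to that choice.

Deliberate omissions, hence what passing tests do *not* show: the noise is
spatially and temporally independent (real residuals retain correlation, so
real-data standard errors are optimistic — one reason p-values are treated
as indicative); panel sizes are equal every year (no survey disruptions);
station levels enter only through the intercept field rather than a separate
heavy-tailed between-lake distribution; and measured covariates are absent
— the model here is time-only by design.

Determinism contract: one master seed, with fixed offsets deriving separate
streams for placement, panel shuffle, noise and outlier choice. Identical
config therefore gives byte-identical output, and changing the seed changes
the noise but not the design rows for a reused schedule.

## Numerical choices and edge cases

- Local solves center time at the weighted mean, making the 2×2 system
  effectively diagonal; coefficients and covariance are mapped back
  exactly. Fits match `lm()` at uniform weights to 1e-10 and the global OLS
  limit (uniform kernel, $k = n$) exactly.
- Singular local designs (all positively weighted observations in one year)
  are flagged per station, excluded from the hat-matrix traces, and
  warned about; in CV they are excluded from the score with a reported
  count. A zero bandwidth ($k$ co-located observations) is degenerate and
  refuses to produce weights.
- Ties: bandwidth ranks are by distance value (ties share it);
  first/last-year ties in `change_per_year` resolve by input order and are
  logged; CV ties go to the smaller $k$.
- Duplicate (station, year) rows are retained throughout — multiple
  observations per location are part of the model formulation.

## Problem sizes

The shipped tests and the acceptance script run the full recovery study at
800 stations (~1,870 observations, five seeds), bandwidth selection at 200
stations, the outlier screen at 1,000 stations, and moving windows at 100
stations — sizes at which the whole suite completes in well under a minute
while leaving the estimator's asymptotics visible. The estimator itself is
O(stations × observations) per fit and handles the ~11,000-observation
national-survey scale in minutes.

## Limitations

Linear-in-time local trends only (windows are the nonlinearity device);
bisquare kernel only; no extra covariates; no spatial-error or
spatio-temporal kernel variants; no reprojection. Edge-of-domain stations
have one-sided neighbourhoods and deserve the usual suspicion, as do small
isolated significant patches.
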