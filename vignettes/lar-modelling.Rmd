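---
title: "Modelling wheat leaf appearance as a carbon supply/demand process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wheat leaf appearance as a carbon supply/demand process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larwheat)
```

## The model and its assumptions

Wheat main-stem development is tracked as the Haun stage (HS): the number
of ligulated leaves plus the fraction of the youngest visible blade's
length relative to the youngest ligulated blade (clamped to [0, 1], since
an expanding blade can transiently overtop its reference). The package
simulates HS at a daily step,

$$HS(t+1) = HS(t) + LAR(t)\,\Delta T_t(t),$$

where $\Delta T_t$ is the daily thermal time and $LAR$ the leaf appearance
rate supplied by one of three models.

**Thermal time.** Sub-daily temperature (reference: 144 ten-minute means)
passes through a beta-shaped response between cardinal temperatures
$T_{min} < T_{opt} < T_{max}$ (defaults 0, 27.5, 40 °C for wheat leaf
initiation and growth):

$$f(T) = \max\!\big(0,\; 2x^{\alpha} - x^{2\alpha}\big),\quad
x = \frac{T - T_{min}}{T_{opt} - T_{min}},\quad
\alpha = \frac{\ln 2}{\ln[(T_{max}-T_{min})/(T_{opt}-T_{min})]},$$

and $\Delta T_t = T_{opt}\,\overline{f(T)}$, so one day contributes at
most $T_{opt}$ degree-days. The choice of $\alpha$ makes $f(T_{opt}) = 1$
and $f(T_{min}) = f(T_{max}) = 0$ exactly.

**Photothermal quotient.** $PTQ = \text{daily PAR} / \Delta T_t$
(mol m⁻² °Cd⁻¹) is the potential carbon supply per unit of
temperature-driven demand. When $\Delta T_t = 0$ the quotient is treated
as undefined (an error), not infinite: with no thermal time there is no
development to normalise by.

**The LAR models.**

* *M1*: $LAR = 1/\text{phyllochron}$, constant.
* *M2* (Sirius): a segmented-linear model — phase multipliers on the
  phyllochron for leaf ranks 1–3, 4–8 and > 8, and a sowing-date
  correction that shortens the phyllochron linearly for winter sowings
  (hemisphere-adjusted days of year 1–90, ramping toward a minimum at
  mid-summer day 196).
* *M3* (carbon supply/demand): the saturating response

  $$LAR = LAR_{min} + (LAR_{max} - LAR_{min})
  \frac{X}{PTQ_{hf} + X} \cdot \frac{S_{C/GAI}}{\overline{GAI}_{eff}},$$

  with $X$ the ratio of *intercepted* PAR to thermal time, both summed
  over a trailing window of $d$ °Cd. $LAR_{min}$ is the rate maintained
  in darkness, $LAR_{max}$ the asymptote, $PTQ_{hf}$ the half-saturation
  quotient. Interception is Beer–Lambert, $1 - e^{-k\,GAI}$. The
  effective green area index proxies whole-canopy carbon demand: below
  `ln_eff` emerged leaves it equals the juvenile floor
  $LN_{eff} \cdot A^{pot}_{juv} \cdot 10^{-4} \cdot PD$, and afterwards
  the running maximum of the thermal-time-weighted windowed mean GAI —
  so it never decreases, even under senescence.

## A structural ambiguity, resolved as a design choice

The placement of the demand scale $S_{C/GAI}/\overline{GAI}_{eff}$ admits
two unit-consistent readings. The default (`gai_form = "divisor"`)
multiplies the saturating supply term, so LAR grows without bound as GAI
approaches zero — which is why the juvenile floor exists — and doubling
$\overline{GAI}_{eff}$ exactly halves the supply-dependent excess above
$LAR_{min}$. The alternative (`gai_form = "supply"`) scales $X$ inside
the saturation instead, bounding LAR by $LAR_{max}$ at the cost of losing
that small-canopy divergence. Both are exposed; tests pin the algebraic
identities of each. Setting `pin_scale = TRUE` forces the scale to 1,
collapsing M3 onto the plain PTQ response driven by intercepted light —
the reduction exercised on every chamber scenario in the test suite.

## Parameters that matter

| Parameter | Units | Default | Role |
|---|---|---|---|
| $T_{min}, T_{opt}, T_{max}$ | °C | 0, 27.5, 40 | cardinal temperatures of $f(T)$ |
| $LAR_{min}$ | leaves °Cd⁻¹ | 0.005 | dark/zero-supply rate; the usual free parameter per site |
| $LAR_{max}$ | leaves °Cd⁻¹ | 0.022 | supply-saturated rate |
| $PTQ_{hf}$ | mol m⁻² °Cd⁻¹ | 2.0 | half-saturation quotient |
| $d$ | °Cd | 70 | carbohydrate buffering window |
| $k$ | — | 0.45 | light extinction; typical dense wheat canopies |
| $S_{C/GAI}$ | m² m⁻² | 0.6 | demand scaling |
| $LN_{eff}$ | leaves | 3.5 | juvenile floor stage (first tiller appearance) |
| $A^{pot}_{juv}$ | cm² | 10 | potential juvenile leaf area (varietal) |
| $PD$ | plants m⁻² | 150 | plant density |

The M2 phase multipliers (0.75, 1, 1.3) and the sowing-correction ramp
(maximum reduction 0.25) are calibration placeholders exposed as
arguments: the published Sirius values live in supplementary material not
reproduced here, so these defaults encode only the documented ordering
(early leaves faster, late leaves slower) and the direction of the
sowing effect.

## What the synthetic generators emulate — and what they do not

`build_chamber_weather()` reproduces controlled-environment regimes as
exact square waves (day temperature and PAR flux during the photoperiod,
night values otherwise) on the 10-minute grid, including two-pass
irradiance-swap treatments triggered at a Haun stage rather than a date.
The bundled `chamber_treatments()` table carries *measured* daily PAR,
thermal time and PTQ for each treatment; measured thermal time can differ
substantially from set-point arithmetic because apex temperature runs
below air temperature — the table is therefore treated as data, never
regenerated from set points.

`build_field_weather()` generates daily Tmin/Tmax and PAR from sinusoidal
annual cycles plus independent Gaussian noise. The `hsc-like` preset is a
hot low-desert spring-wheat site: latitude 33 °N, annual mean 22 °C with
half-amplitude 10.5 °C, diurnal range 17 °C, daily PAR 45 ± 22 mol m⁻²
d⁻¹, and — crucially — radiation peaking near the solstice (day 172)
while temperature peaks in mid-summer (day 205). That phase lag makes
spring crops bright-and-cool (high PTQ) and autumn crops dim-and-warm
(low PTQ), spanning roughly 1.5–3.5 mol m⁻² °Cd⁻¹ across eight sowings —
a > 2-fold spread overlapping the 1.2–3.8 range typical of serial-sowing
field experiments at such sites. The `nz2020-like` preset is a cool
temperate southern site (43.75 °S, phases shifted 182 days) with
late-summer to mid-autumn sowings.

Limitations to keep in mind when reading test results: the noise is
independent day to day (no synoptic autocorrelation), radiation is not
tied to cloud-temperature covariance, and no vernalisation or photoperiod
phenology is modelled. Passing tests therefore demonstrate the models'
internal behaviour under realistic forcing ranges, not predictive skill
on any particular observed dataset; the published field error statistics
for the three models are not reproducible without those datasets and are
deliberately not asserted anywhere.

## Numerical choices

* Daily-only weather is expanded to the 144-step grid with a sine course
  (minimum at 03:00, maximum at 15:00); the diurnal shape is swappable
  and only affects $\Delta T_t$ through the nonlinearity of $f$.
* The M3 window is the smallest trailing run of whole days holding at
  least $d$ °Cd (all history when younger than the window, minimum one
  day). Windowed GAI means are thermal-time weighted.
* The internal GAI trajectory grows in proportion to Haun stage
  ($GAI = c \cdot HS \cdot A^{pot}_{juv} \cdot 10^{-4} \cdot PD$,
  `gai_per_leaf` = 1): a deliberate stand-in for a full leaf-growth model
  that keeps the effective-GAI machinery exercisable; observed GAI series
  can be supplied instead.
* Emergence starts at HS 0 (configurable); model comparison statistics
  use observations above HS 1.0 only, making the pre-leaf-1 convention
  immaterial to fitting.
* The smoothing spline for observed LAR uses generalised cross-validation
  rather than a hand-tuned smoothing constant; duplicate abscissae are
  averaged. Its derivative is reported on a uniform grid and is reliable
  away from the edges (the tests exclude 5 % margins).
* The MSE decomposition regresses observed on simulated values (the
  convention under which SB + NU + LC sums exactly to MSE); when the
  simulation has zero variance the slope is undefined, NU is reported as
  0 and LC absorbs the remainder, with a flag.
* RMSRE is per-observation relative error in percent,
  $100\sqrt{\overline{((sim-obs)/obs)^2}}$.
* Parameter estimation minimises RMSRE with a seeded multi-start
  derivative-free search: uniform random starts inside the bounds,
  refined by Brent's method (one free parameter) or Nelder–Mead with
  bound clipping. With `lar_min` as the single free parameter the
  objective is smooth and unimodal in practice; multi-starts guard
  against flat stretches. Results are reproducible for a fixed
  `fit_spec` seed and invariant to observation order.
* Problem sizes used by the test and acceptance runs — 40–70-day chamber
  simulations, 160–240-day field seasons, three to eight sowings, four
  optimiser starts — were chosen as the smallest sizes at which the
  parameter-recovery and directional properties are comfortably stable.

## Known limitations

No tillering dynamics, internode/spike sinks, CO₂ response term,
senescence model or soil/canopy energy balance: apex temperature defaults
to air temperature, with optional user-supplied soil/canopy proxy series
selected by `select_temperature_source()` below/above the Haun-stage-4
switch. The M2 defaults are placeholders as noted above. The
supply/demand model inherits the identifiability caveat of all
saturating responses: narrow PTQ ranges cannot separate $LAR_{max}$ from
$PTQ_{hf}$, which `fit_lar_ptq()` flags explicitly.
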