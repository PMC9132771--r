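---
title: "Methods: pH-sensitive opal dissolution and the marine silicate pump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pH-sensitive opal dissolution and the marine silicate pump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silicatepump)
library(dplyr)
```

## The scientific question

Diatoms build cell walls of biogenic silica (opal) that dissolve chemically
in seawater as their organic coating degrades and the dead cells sink.
Opal dissolution is base-catalysed: the breaking of bridging Si–O bonds is
facilitated by deprotonated silanol groups at the particle surface, so it
slows as pH falls. Ocean acidification therefore does something
counter-intuitive: it *preserves* sinking opal, raising the Si:N ratio of
export relative to the fresh biomass that produced it, deepening the
remineralization horizon of silicon, and — on the centennial timescale of
the overturning circulation — starving the surface ocean of the silicic
acid diatoms need. This package implements the full chain of evidence for
that mechanism at desk scale: mesocosm effect-size meta-analysis, global
sediment-trap profile regression, dissolution kinetics with a 1-D sinking
column, and a reduced-complexity silicon-cycle box model.

## Mesocosm effect sizes (Fig.-1-style analysis)

Per study, mesocosms are pooled into an ambient group and an OA group
(pCO2 in 700–1000 μatm, the end-of-century range of the RCP6.0–RCP8.5
scenarios); mesocosms outside both windows are excluded and counted. The
effect size is the log response ratio of group mean export Si:N,
$\mathrm{lnRR} = \ln \bar X_{OA} - \ln \bar X_{control}$, with studies
pooled by inverse-variance weighting.

Decisions the source analysis leaves open, and what we chose:

* **Variance of lnRR.** Only "pooled standard deviations" is specified. We
  use the standard delta-method form
  $v = s^2_{OA}/(n_{OA}\bar X^2_{OA}) + s^2_{c}/(n_{c}\bar X^2_{c})$
  with normal-quantile confidence limits — the textbook meta-analysis
  convention for response ratios.
* **Replication unit.** Mesocosm time-means (not daily samples) enter the
  effect-size variance, avoiding temporal pseudo-replication. Daily values
  feed the kernel-density stage, which is the analysis branch that retains
  temporal variability by design.
* **Density comparison.** Gaussian kernel, Silverman bandwidth, no
  boundary correction (Si:N sits well away from zero at the default
  noise). Bootstrap bands are pointwise 2.5/97.5 percentiles of 1000
  resampled re-estimates computed at the original bandwidth. Two
  distributions are called different where the bands are disjoint over a
  contiguous region containing a mode — the contiguity-plus-mode rule
  guards against single-gridpoint false positives that a purely pointwise
  reading of "non-overlapping densities" would produce.
* **pCO2 regression.** The export-versus-suspended contrast regresses
  mesocosm-mean Si:N on pCO2 (the plotted predictor), not on pH.

## Trap-profile regression (Fig.-2-style analysis)

Profiles qualify with at least three depth levels of simultaneous Si and N
flux; per profile, ordinary least squares of Si:N on depth yields
ΔSi:N m⁻¹, and only profiles with a significant depth relationship
(p < 0.05, two-sided) are retained — the same significance filter the
observational analysis uses to weed out advection-dominated profiles; we
add no extra heuristic. Retained slopes are regressed on the
climatological mean pH over each profile's depth range (nearest latitude
column, depth-integrated mean, exact for linear variation), optionally
with temperature as a second predictor, reporting standardized
coefficients so the two effect sizes are directly comparable. Per-profile
regressions are unweighted, and no multiple-testing correction is applied
across profiles (none is applied in the source analysis either).

## Dissolution kinetics and the sinking column

The specific opal dissolution rate is multiplicatively separable,

$$k_{Si}(T, pH) = k_{Si,0}\; Q_{10}^{(T-T_{ref})/10}\;
  \max\!\big(0,\; 1 + s_{pH}\,(pH - pH_{ref})\big),$$

with defaults $k_{Si,0} = 0.05\,d^{-1}$, $k_{N,0} = 0.10\,d^{-1}$,
$Q_{10} = 2.05$, $pH_{ref} = 8.1$, $T_{ref} = 10\,°C$, sinking speed
$w = 100$ m d⁻¹ — conventional order-of-magnitude values, all
overridable. Two of them are anchored deliberately:

* $s_{pH} = 0.567$ per pH unit is the linear attribution of a 17 % export
  Si:N increase to a ~0.3 pH decrease (`derive_ph_sensitivity(0.17, 0.3)`),
  "57 % per unit pH". An exponential-kinetics attribution would instead
  give $\ln(1.17)/0.3 \approx 52\,\%$; we implement the linear quotient
  and note the alternative here. Chemical dissolution studies report
  60–70 % per pH unit, so the adopted value is conservative.
* $Q_{10} = 2.05$ makes the temperature factor 3.5 over a 17.5 °C
  gradient, the centre of the "three- to fourfold over 15–20 °C" anchor
  for the modern surface-to-deep contrast. N remineralization shares this
  Q10 by default (nothing in the source constrains it separately) and has
  no pH dependence.

The zero floor on the pH factor is our robustness addition; whether the
original 3-D implementation clips is unstated, and the floor never
engages above pH ≈ 6.3 at the default sensitivity.

The column integrator solves $dF/dz = -(k/w)F$ for Si and N by exponential
stepping with layer-mean rates — exact for piecewise-constant forcing,
second-order otherwise, and equal to the closed form
$F(z) = F_0 e^{-kz/w}$ for constant coefficients (tested to $10^{-6}$
relative). ΔSi:N m⁻¹ of a simulated profile is the OLS slope over all
levels, the same statistic used for trap data.

## The box-model surrogate

The published global assessment runs a 3-D Earth-system model; that is not
reproducible at desk scale, and this package deliberately substitutes an
idealized seven-box annual-step silicon cycle (three surface boxes, AAIW,
CDW, two abyssal boxes) with a mass-balanced overturning loop and two
vertical mixing exchanges. Its Δ_OA diagnostics are reported but *never*
compared with the published Earth-system magnitudes; only the qualitative
signature is asserted (surface Si loss, production decline, deep Si
trapping, scenario ordering, emergence over time, warming–pH antagonism).

Surrogate choices:

* Production is Michaelis–Menten in Si only,
  $U = v_{max} V \,[\mathrm{Si}]/([\mathrm{Si}]+K_{Si})$ with
  $K_{Si} = 4$ mmol m⁻³; iron/light limitation is folded into per-box
  $v_{max}$ (in mmol m⁻³ yr⁻¹ — the dimensionally consistent reading of a
  "maximum uptake scaling"). $v_{max} = (7, 11, 8.5)$ was tuned once so
  the preindustrial steady state spans oligotrophic (~1.4) to Southern
  Ocean (~62 mmol m⁻³) surface silicic acid, the stated realism target.
  Half of production is exported; the rest redissolves in place.
* Export dissolves along a fixed particle path with per-segment survival
  $e^{-k\tau}$; the survivor of the last segment deposits in the terminal
  box (no burial — the model is closed, and total Si is conserved to
  round-off, tested at $10^{-9}$ per step).
* The pH factor acts on the *anomaly* relative to each box's
  preindustrial pH, so the baseline spatial pH field does not enter the
  dissolution rate — only its future change does. With the effect
  disabled the factor is frozen at 1, which is the "standard model"
  configuration; Δ_OA is the paired difference.
* Spin-up: the drift criterion ($<10^{-6}$ relative yr⁻¹) governs, with a
  20,000-year cap. A fixed 3,000-year spin-up cannot meet that criterion
  from a uniform initial state (deep residence times are ~800 years);
  from uniform 85 mmol m⁻³ convergence takes ~6,300 years and the result
  seeds every scenario run (it is independent of the pH switch).
* Forcing: scenario anomalies are prescribed, not computed from carbonate
  chemistry (out of scope). Surface pH anomalies reach −0.40/−0.65
  (RCP8.5) and −0.25/−0.35 (RCP6.0) by 2100/2200 — inside the projected
  0.2–0.4 decline to 2100 — with quadratic onset after 1850 and linear
  extension to 2200; warming reaches +3.0/+4.5 and +1.5/+2.0 °C.
  Subsurface boxes feel 40 % of the surface anomaly lagged by 50 years.
  These are documented plausible interpolations, overridable, and not
  graded against anything.

## What the synthetic generators emulate — and what they do not

`gen_mesocosm_study()` reproduces the statistical skeleton of five in situ
CO2-enrichment experiments: baseline export Si:N spanning 0.08–1.8 across
biomes, a multiplicative OA effect of 1.17 on *export* Si:N only (the
suspended ratio is unaffected, encoding the finding that the effect arises
during sinking, not production), multiplicative lognormal noise of CV
10 %, 4+4 mesocosms with individual pCO2 levels, 30 sampling days. One
site is brackish (6 psu) with the effect fully suppressed below 10 psu —
the built-in null analogous to the low-salinity experiment where no OA
response was detectable. The suppression threshold and its all-or-nothing
form are placeholders: no salinity–dissolution function exists in the
source, so the attenuation lives in the generator, not in the kinetics.
The site-level effect spread is lognormal with σ = 0.02, matching the
observed cross-site consistency.

A consequence worth stating plainly: with a fully suppressed null site and
equal per-site variances, the five-site inverse-variance pool centres on
$(4/5)\ln 1.17 \approx 0.126$ (a ~13 % increase), not on $\ln 1.17 =
0.157$. The recovered percent change still falls within the reported
17 ± 6 band, but the point value 0.157 is recoverable only from the four
responsive sites. The corresponding acceptance check is left failing
rather than re-tuning the stated world around it.

`gen_trap_compilation()`'s statistical mode imposes the fitted
pH–ΔSi:N relation directly: station pH uniform on 7.7–8.15, latent slope
$0.18 - 0.0214\,pH + \mathcal N(0, 0.005^2)$ m⁻¹. The intercept keeps
latent slopes positive (0.006–0.015 m⁻¹, Si always preferentially
preserved); the noise SD follows analytically from requiring R² ≈ 0.24 at
n = 190 given the coefficient and the pH spread. Within-profile Si:N
jitter (SD 0.1) is small enough that essentially every generated profile
passes the significance filter; the residual selection at the high-pH end
attenuates the recovered coefficient by about 6 %, well inside the 20 %
acceptance band. Mechanistic mode instead runs the column integrator per
station so the pH–slope relation *emerges* from the kinetics — the
two-stage recovery test uses it to close the inferential loop. Neither
mode reproduces real station positions, seasons, mass-unit conventions,
or the 674-location inventory of the real compilation.

`gen_climatology()` is a smooth idealized field with a vertical pH drop
of 0.335 and a latitude-mean vertical temperature drop of ~16 °C — the
modern gradients over which the temperature effect on dissolution is
roughly tenfold the pH effect.

Green tests therefore establish internal consistency — that the
implemented estimators recover what the implemented generators put in, at
the stated noise — not agreement with any archived observational record.

## Numerical choices and degenerate inputs

Tolerances: closed-form column agreement $10^{-6}$ relative; grid-halving
convergence $10^{-4}$; KDE normalization $1 \pm 10^{-3}$ (trapezoid on a
1024-point grid padded by 4 bandwidths); box-model conservation $10^{-9}$
per step. Ties and degenerate cases error loudly and early: empty
treatment groups, non-positive group means, fewer than two replicates,
zero effect-size variances (with a remedial hint), fewer than three depth
levels or distinct pCO2 levels, zero depth variance, constant pH
predictor, pH–temperature collinearity beyond |r| = 0.99, non-monotone
depth grids, NaN forcing, divergent transport, negative concentrations,
and non-converged spin-up all raise classed conditions. Seeds are applied
through a local RNG scope, so generators never disturb the caller's
random stream, and identical seed plus config is bit-reproducible.

## Known limitations

* The box model is a circulation motif, not an ocean: no carbon or
  prognostic N cycle, no ballasting or aggregation, no ecological
  competition; its Δ_OA percentages (~−1 % surface Si at 2200) are an
  order of magnitude below Earth-system values because the surrogate's
  deep circulation and production feedbacks are far weaker.
* The salinity attenuation rule is a placeholder for a mechanism the
  source does not quantify.
* The linear pH attribution is a first-order convention; for effects much
  larger than ~20 % per pH unit the exponential attribution diverges from
  it materially.
* Analysis windows per experiment, GLODAP matching details (pH scale,
  version, 3-D interpolation) and flux-weighting of profile regressions
  are unspecified upstream; the choices here are documented defaults.
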