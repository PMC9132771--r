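# silicatepump

Ocean acidification slows the chemical dissolution of biogenic silica
(opal). Sinking diatom debris is therefore better preserved at lower pH:
the Si:N ratio of export rises, silicon remineralizes deeper, and — over
the timescale of the overturning circulation — the surface ocean loses the
silicic acid that diatoms need. `silicatepump` implements that chain of
evidence at desk scale, for marine biogeochemists and modellers who want a
tested, reproducible reference implementation of each analysis stage:

1. **Mesocosm meta-analysis** — log response ratios of export Si:N between
   ambient and high-CO2 (700–1000 μatm) treatment groups,
   `lnRR = ln X̄_OA − ln X̄_control`, with delta-method variances,
   inverse-variance pooling across studies, bootstrap kernel-density
   comparison of the full Si:N time series, and the export-versus-suspended
   pCO2 regression contrast.
2. **Sediment-trap profiles** — eligibility filtering (≥3 paired Si/N depth
   levels), per-profile OLS slopes of Si:N versus depth (ΔSi:N m⁻¹,
   retained at p < 0.05), climatological pH/temperature matching, and the
   regression of ΔSi:N m⁻¹ on mean pH (negative slope ⇒ stronger Si
   preservation at lower pH).
3. **Opal kinetics** — `k_Si(T, pH) = k_Si0 · Q10^((T−T_ref)/10) ·
   max(0, 1 + s_pH (pH − pH_ref))`, the linear pH-sensitivity attribution
   (17 % over ~0.3 pH units ⇒ 57 % per pH unit), and a 1-D sinking-column
   integrator for particulate Si and N fluxes.
4. **Silicate-pump box model** — an idealized seven-box silicon cycle
   forced by extended RCP scenarios to 2200, run with and without
   pH-sensitive dissolution; the paired difference (Δ_OA) shows surface
   silicic-acid loss, deep-ocean Si trapping and an opal-production
   decline.
5. **Synthetic data** — generators for mesocosm studies, trap
   compilations, climatologies and scenario forcings with the statistical
   and mechanistic structure the analyses assume, so everything is
   testable without downloads.

## Worked example

```r
library(silicatepump)
library(dplyr)

# five-biome synthetic mesocosm dataset, OA effect on export Si:N only
study <- gen_mesocosm_dataset(default_site_roster(seed = 1), seed = 1)
effects <- study |> pool_treatments() |> site_effect_sizes()
effects
#> # A tibble: 5 × 8
#>   site                 lnrr variance  ci_low ci_high  n_oa n_control significant
#>   <chr>               <dbl>    <dbl>   <dbl>   <dbl> <int>     <int> <lgl>
#> 1 arctic            1.42e-1  1.38e-4  0.119   0.165      4         4 TRUE
#> 2 baltic-transiti…  1.78e-1  3.51e-4  0.142   0.215      4         4 TRUE
#> 3 brackish         -6.31e-4  9.45e-5 -0.0197  0.0184     4         4 FALSE
#> 4 temperate-NE      1.97e-1  2.06e-4  0.169   0.225      4         4 TRUE
#> 5 upwelling         1.29e-1  3.64e-4  0.0912  0.166      4         4 TRUE
```

Four of five sites show a significant positive lnRR near ln(1.17) ≈ 0.157
— acidification raised export Si:N by ~17 % — while the brackish site is
the built-in null (the effect is suppressed below 10 psu). `glance()`
pools them by inverse variance; on this single seed the null site drags
the overall estimate to 0.100 (a 10.6 % increase; seed-averaged it is
~13 %, within the reported 17 ± 6 % band):

```r
glance(effects)
#> # A tibble: 1 × 6
#>   lnrr_overall percent_change ci_low ci_high n_studies n_significant
#>          <dbl>          <dbl>  <dbl>   <dbl>     <int>         <int>
#> 1        0.100           10.6 0.0887   0.112         5             4
```

The trap-compilation stage recovers the pH dependence of Si preservation
from 190 synthetic profiles (generating coefficient −0.0214 m⁻¹ per pH
unit):

```r
comp <- gen_trap_compilation(trap_compilation_config(), seed = 1)
slopes <- filter_profiles(comp) |> profile_slopes() |>
  left_join(comp$stations, by = "station_id")
ph_regression(slopes)
#> <ph_fit>  Delta Si:N per m regressed on: mean_ph
#>   mean_ph    slope = -0.01371  [-0.01956, -0.007864]
#>   R2 = 0.103, F = 21.4, p = 6.97e-06, n = 188
```

The kinetics close the loop between observation and mechanism:

```r
derive_ph_sensitivity(0.17, 0.3)   # 0.567: "57 % per unit pH"
prof <- integrate_column(column_config(seq(0, 2000, 100)),
                         kinetics_params(s_ph = 0))
glance(prof)
#> # A tibble: 1 × 5
#>   delta_sin_per_m si_n_surface si_n_trap si_transfer n_transfer
#>             <dbl>        <dbl>     <dbl>       <dbl>      <dbl>
#> 1        0.000847            1      2.72       0.368      0.135
```

With k_Si = 0.05 d⁻¹, k_N = 0.10 d⁻¹ and w = 100 m d⁻¹, the 2000 m column
attenuates the Si flux to e⁻¹ ≈ 0.368 of its export value while Si:N
enriches e-fold to 2.72 — slower opal dissolution relative to N
remineralization is exactly what makes the silicate pump.

Scenario runs contrast pH-sensitive and standard dissolution:

```r
st  <- spinup_state()
f85 <- gen_rcp_forcing("RCP8.5")
on  <- run_scenario(forcing = f85, ph_effect = TRUE,  init = st)
off <- run_scenario(forcing = f85, ph_effect = FALSE, init = st)
delta_oa(on, off, 2200)   # surface Si < 0, production < 0, deep Si > 0
```

Every result type has `tidy()`/`glance()` methods and an `autoplot()`
(forest plot, density bands, pH scatter with fit, column profile,
trajectories).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from freshly generated data, (i) the percent increase in
export Si:N implied by the seed-averaged overall inverse-variance lnRR of
the default five-site mesocosm dataset, and (ii) the seed-averaged fitted
slope of the ΔSi:N m⁻¹–pH regression from 190-profile trap compilations at
the documented defaults, writing both to JSON. Runtime is well under a
minute on one CPU.
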