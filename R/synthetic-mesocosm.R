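#' Configuration of one synthetic mesocosm CO2-enrichment study
#'
#' Describes a single-site in situ mesocosm experiment in which natural
#' plankton communities are enclosed under ambient and elevated pCO2 and
#' the Si, N and C content of both sinking (sediment-trap) and suspended
#' particulate matter is sampled over time.  The ocean-acidification
#' treatment acts multiplicatively on the *export* Si:N ratio
#' (`oa_export_multiplier`) but, by default, not on the suspended ratio —
#' the signature of an effect arising during particle sinking rather than
#' during biomass production.
#'
#' At brackish sites the effect is attenuated: when `salinity_attenuation`
#' is on and salinity falls below 10 psu the realized export multiplier is
#' pulled fully back to 1, building in a null site analogous to the
#' low-salinity (~6 psu) Baltic experiment where no OA effect was
#' detectable.
#'
#' @param site_name Site label.
#' @param baseline_si_n Ambient export Si:N molar ratio (> 0).
#' @param salinity Site salinity, psu.
#' @param n_ambient,n_oa Number of mesocosms per treatment group.
#' @param pco2_ambient Ambient pCO2, μatm.
#' @param pco2_oa Centre of the OA treatment, μatm (700--1000).
#' @param n_days Number of sampling days.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   observation noise (fraction, >= 0).
#' @param oa_export_multiplier Multiplicative OA effect on export Si:N (> 0).
#' @param oa_suspended_multiplier Multiplicative OA effect on suspended
#'   Si:N; default 1 (no water-column effect).
#' @param salinity_attenuation Suppress the export effect below 10 psu?
#' @return An object of class `mesocosm_site_config` (a list).
#' @seealso [gen_mesocosm_study()], [default_site_roster()]
#' @export
mesocosm_site_config <- function(site_name = "site",
                                 baseline_si_n = 1.0,
                                 salinity = 34,
                                 n_ambient = 4, n_oa = 4,
                                 pco2_ambient = 400, pco2_oa = 850,
                                 n_days = 30,
                                 noise_cv = 0.10,
                                 oa_export_multiplier = 1.17,
                                 oa_suspended_multiplier = 1,
                                 salinity_attenuation = FALSE) {
  stop_if_not_number(baseline_si_n, "baseline_si_n", lower = 0,
                     strict_lower = TRUE)
  stop_if_not_number(salinity, "salinity", lower = 0)
  stop_if_not_count(n_ambient, "n_ambient")
  stop_if_not_count(n_oa, "n_oa")
  stop_if_not_count(n_days, "n_days")
  stop_if_not_number(noise_cv, "noise_cv", lower = 0)
  stop_if_not_number(pco2_ambient, "pco2_ambient", lower = 0,
                     strict_lower = TRUE)
  stop_if_not_number(pco2_oa, "pco2_oa", lower = 700, upper = 1000)
  if (pco2_oa <= pco2_ambient) {
    abort("`pco2_oa` must exceed `pco2_ambient`.",
          class = "silicatepump_invalid_config")
  }
  stop_if_not_number(oa_export_multiplier, "oa_export_multiplier",
                     lower = 0, strict_lower = TRUE)
  stop_if_not_number(oa_suspended_multiplier, "oa_suspended_multiplier",
                     lower = 0, strict_lower = TRUE)
  structure(
    list(site_name = as.character(site_name), baseline_si_n = baseline_si_n,
         salinity = salinity, n_ambient = as.integer(n_ambient),
         n_oa = as.integer(n_oa), pco2_ambient = pco2_ambient,
         pco2_oa = pco2_oa, n_days = as.integer(n_days),
         noise_cv = noise_cv, oa_export_multiplier = oa_export_multiplier,
         oa_suspended_multiplier = oa_suspended_multiplier,
         salinity_attenuation = isTRUE(salinity_attenuation)),
    class = "mesocosm_site_config"
  )
}

# salinity threshold below which the export effect is fully suppressed
.salinity_threshold <- 10

# multiplier actually applied to the OA group's export Si:N
realized_export_multiplier <- function(config) {
  if (config$salinity_attenuation && config$salinity < .salinity_threshold) {
    1
  } else {
    config$oa_export_multiplier
  }
}

#' Default five-site mesocosm roster
#'
#' A qualitative mirror of the five-biome study design: baseline export
#' Si:N spanning <0.1 (Arctic, diatom-poor) to ~1.8 (Baltic-transition,
#' diatom-rich), with one brackish (~6 psu) site whose OA effect is
#' suppressed by the salinity-attenuation rule and therefore acts as the
#' built-in null.  Site-level export multipliers are drawn around 1.17
#' with a small lognormal spread (σ = 0.02 on the log scale), matching the
#' observed cross-site consistency of effect sizes.
#'
#' @param seed Integer seed for the site-multiplier draw.
#' @param effect Central OA export multiplier.
#' @param noise_cv Observation noise CV passed to every site.
#' @param site_sigma Lognormal spread of site multipliers (log scale).
#' @return A list of five [mesocosm_site_config()] objects.
#' @export
default_site_roster <- function(seed = 1L, effect = 1.17, noise_cv = 0.10,
                                site_sigma = 0.02) {
  sites <- tibble(
    site_name = c("arctic", "temperate-NE", "upwelling", "brackish", "baltic-transition"),
    baseline_si_n = c(0.08, 0.3, 0.6, 1.0, 1.8),
    salinity = c(34, 34, 35, 6, 26),
    salinity_attenuation = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  withr_seed(seed, {
    mult <- effect * exp(rnorm(nrow(sites), 0, site_sigma))
    purrr::map(seq_len(nrow(sites)), function(i) {
      mesocosm_site_config(
        site_name = sites$site_name[i],
        baseline_si_n = sites$baseline_si_n[i],
        salinity = sites$salinity[i],
        noise_cv = noise_cv,
        oa_export_multiplier = mult[i],
        salinity_attenuation = sites$salinity_attenuation[i]
      )
    })
  })
}

# evaluate expr with a local RNG seed, restoring the global state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic mesocosm study table
#'
#' Simulates per-mesocosm, per-day measurements of particulate Si, N and C
#' in the export (sediment trap) and suspended (water column) compartments.
#' Mesocosms receive individual pCO2 levels spread deterministically around
#' the treatment centres, so a study always contains more than two distinct
#' pCO2 levels (as in gradient-design CO2 enrichment experiments).  All
#' noise is multiplicative lognormal with the configured CV and unit mean,
#' so the OA group's export Si:N is centred on
#' `baseline_si_n * oa_export_multiplier` (attenuated at brackish sites)
#' and the suspended ratio on `baseline_si_n * oa_suspended_multiplier`.
#'
#' @param config A [mesocosm_site_config()].
#' @param seed Integer seed; identical seed and config give an identical
#'   table.
#' @return A tibble with columns `site`, `mesocosm_id`, `day`, `pco2_uatm`,
#'   `compartment` (`"export"`/`"suspended"`), `si`, `n`, `c` (molar units).
#' @examples
#' study <- gen_mesocosm_study(mesocosm_site_config(noise_cv = 0), seed = 1)
#' head(study)
#' @export
gen_mesocosm_study <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mesocosm_site_config"))
  withr_seed(seed, {
    n_meso <- config$n_ambient + config$n_oa
    # deterministic within-treatment pCO2 spread (gradient design)
    amb_spread <- seq(-30, 30, length.out = config$n_ambient)
    oa_lo <- max(700, config$pco2_oa - 120)
    oa_hi <- min(1000, config$pco2_oa + 120)
    oa_levels <- if (config$n_oa == 1L) config$pco2_oa else
      seq(oa_lo, oa_hi, length.out = config$n_oa)
    meso <- tibble(
      mesocosm_id = sprintf("M%02d", seq_len(n_meso)),
      treatment = rep(c("ambient", "oa"), c(config$n_ambient, config$n_oa)),
      pco2_uatm = c(config$pco2_ambient + amb_spread, oa_levels)
    )
    mult_export <- realized_export_multiplier(config)
    mult_susp <- config$oa_suspended_multiplier

    grid <- tidyr::expand_grid(meso, day = seq_len(config$n_days),
                               compartment = c("export", "suspended"))
    n_obs <- nrow(grid)
    # suspended standing stocks are an order of magnitude larger than the
    # daily export flux in these units
    pool <- ifelse(grid$compartment == "export", 1, 10)
    ratio_mult <- ifelse(
      grid$treatment == "oa",
      ifelse(grid$compartment == "export", mult_export, mult_susp),
      1
    )
    n_val <- pool * rlnorm_cv(n_obs, config$noise_cv)
    si_val <- config$baseline_si_n * ratio_mult * pool *
      rlnorm_cv(n_obs, config$noise_cv)
    c_val <- 6.6 * pool * rlnorm_cv(n_obs, config$noise_cv)

    dplyr::arrange(
      tibble(site = config$site_name,
             mesocosm_id = grid$mesocosm_id,
             day = grid$day,
             pco2_uatm = grid$pco2_uatm,
             compartment = grid$compartment,
             si = si_val, n = n_val, c = c_val),
      .data$mesocosm_id, .data$day, .data$compartment
    )
  })
}

#' Generate a multi-site mesocosm dataset
#'
#' Convenience wrapper binding [gen_mesocosm_study()] over a roster of site
#' configurations, with per-site seeds derived from `seed`.
#'
#' @param roster List of [mesocosm_site_config()] objects, e.g. from
#'   [default_site_roster()].
#' @param seed Integer seed.
#' @return A tibble in the mesocosm schema covering all sites.
#' @export
gen_mesocosm_dataset <- function(roster = default_site_roster(), seed = 1L) {
  purrr::list_rbind(purrr::imap(roster, function(cfg, i) {
    # derived seeds stay well below .Machine$integer.max
    gen_mesocosm_study(cfg, seed = as.integer((seed %% 2143483L) * 1000 + i))
  }))
}
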